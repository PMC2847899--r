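Package: msatpop
Title: Population Structure Analysis of Multiallelic Microsatellite Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing diploid short tandem repeat (STR) genotype
    panels sampled from multiple populations: allele frequencies and unbiased
    expected heterozygosity, exact tests of Hardy-Weinberg equilibrium
    (enumeration and Guo-Thompson Markov chain Monte Carlo), Nei's DA and
    Cavalli-Sforza chord genetic distances with bootstrap-over-loci
    resampling, neighbor-joining phylogenies with bipartition support and
    majority-rule consensus, allele-frequency principal component analysis
    with parallel-analysis significance, Mantel and partial Mantel tests
    against geographic and linguistic distance matrices, and a Gibbs sampler
    for model-based admixture clustering with correlated cluster frequencies.
    A synthetic-data module simulates hierarchically differentiated
    populations under the F-model so every pipeline stage can be exercised
    and calibrated without access to an original genotype panel.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
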