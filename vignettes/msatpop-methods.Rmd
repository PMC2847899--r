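---
title: "Population structure from microsatellite panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population structure from microsatellite panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msatpop)
```

# Scope

`msatpop` implements the complete analysis chain for a diploid short
tandem repeat (STR) survey of many populations: allele frequencies and
diversity, exact Hardy–Weinberg tests, frequency-based genetic
distances with bootstrap phylogenies, allele-frequency PCA with
parallel-analysis significance, model-based admixture clustering, and
permutation comparisons of genetic, geographic and linguistic distance
matrices. A synthetic-data module simulates panels with the same
statistical structure, so every stage is tested end to end without any
original genotype data. This vignette records the models, the defaults,
and the design decisions that were genuinely open.

# Data model and the missingness policy

A panel is a set of diploid genotypes (alleles stored as fragment sizes
in base pairs, no binning — size calling is upstream of this package),
tagged by population. Missingness is defined per genotype: a reaction
either yields both gene copies or neither, so a half-called genotype is
demoted to fully missing on construction. This choice is deliberate:
per-reaction failure is the physical failure mode, and treating one
called allele as data would bias frequency estimates toward the alleles
that amplify more readily.

Multi-locus analyses require adequately typed population–locus cells.
`subset_by_missing_policy()` applies a tolerance (default 40% missing
per cell) and produces the two standard working subsets:

* **full-loci** — all loci, dropping every population with any cell
  above tolerance (maximizes loci for tree building);
* **full-population** — all populations, dropping every locus above
  tolerance in any population (places every population).

The operation is idempotent, and both subsets are always produced by the
pipeline so results can be cross-checked between them.

# Diversity and exact Hardy–Weinberg tests

Expected heterozygosity uses the unbiased estimator
$H_E = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)$ with $n$ the typed
gene copies. The correction factor matters at the sample sizes typical
of such surveys (70–190 gene copies) and is assumed throughout.

The Hardy–Weinberg test is the conditional exact test: given the allele
counts, the probability of a genotype table is
$$P(\text{table}) = \frac{n!\,\prod_i m_i!\; 2^h}{(2n)!\,\prod_{i \le j} n_{ij}!},$$
with $h$ heterozygotes, and the p-value is the total probability of
tables no more probable than the observed one (the table-probability
ordering, not a heterozygote-count tail). Small problems are solved by
full enumeration (with an exact closed form for two alleles); larger
ones by the Guo–Thompson Markov chain with allele-swap proposals between
two random individuals and an exactly computed Hastings ratio. Defaults
are 100,000 steps after 10,000 burn-in; `hwe_scan()` sends highly
multiallelic cells straight to the chain because enumeration overflows
any budget there. The chain reports a batch-means standard error (50
batches), which guards against the autocorrelation of the
extreme-table indicator. Two calibration facts shape the tests:

* Across ~1,700 independent chains (every biallelic table with
  $n \le 20$), a fraction of order 0.5% of estimates beyond three
  standard errors is the expected behaviour of a correct sampler, so the
  agreement check requires 99% within 3 SE and everything within 6 SE;
  tables whose p-value lies below the chain's $10^{-3}$ resolution on
  both routes are counted as agreeing. Long chains ($2 \times 10^6$
  steps) converge to the enumeration values to $\sim 10^{-4}$.
* Under HWE sampling the empirical type-I error at $\alpha = 0.05$ is
  0.04–0.05: the exact test is slightly conservative because the
  conditional distribution is discrete. This is a property of the test,
  not an implementation artifact.

Significance is flagged at p < 0.05 with no multiple-testing
correction, matching the descriptive use of these scans in practice.

# Genetic distances

For populations $X, Y$ with per-locus frequencies $x_{ij}, y_{ij}$ the
package implements

$$D_A = 1 - \frac{1}{r}\sum_{j=1}^{r}\sum_i \sqrt{x_{ij} y_{ij}}, \qquad
D_C = \frac{2}{\pi r}\sum_{j=1}^{r}\sqrt{2\left(1 - \sum_i \sqrt{x_{ij} y_{ij}}\right)}.$$

The allele support per locus is the union of alleles observed in the
pair; absent alleles contribute zero. $D_A$ is linear over loci
(multilocus $D_A$ is exactly the mean of single-locus values — an
algebraic identity the tests assert), bounded by 1, and zero for
identical frequency arrays. The $D_C$ normalization keeps $1/r$ inside
the prefactor, pinned testably by the closed form
$(2/\pi)\sqrt{2} \approx 0.9003$ for a single locus with disjoint
allele sets. Bootstrap-over-loci resamples locus indices uniformly with
replacement (no stratification) and recomputes the averaged matrix;
1,000 replicates is the default.

# Phylogenies

`neighbor_joining()` is the standard Saitou–Nei agglomeration with ties
in the Q-criterion broken toward the lowest (row, column) pair —
deterministic across platforms. Negative branch lengths are retained
(the writer offers clamping for display), because silently clamping
would hide the signal that a matrix is far from additive. For any
additive matrix the unique generating topology is recovered; the test
suite verifies this against a brute-force oracle that enumerates all
unrooted topologies (10,395 at eight taxa) and least-squares-fits each.
Bipartition support annotates each internal edge with the percentage of
replicate trees containing the same leaf bipartition; the consensus is
strict-majority (splits in more than half the trees), built directly
from the laminar family of majority splits and cross-checked against
`ape::consensus`.

# PCA and parallel analysis

PCA operates on a population × (locus, allele) matrix of frequencies,
Z-scored per column. The population (divisor-$n$) standard deviation is
used; the choice only rescales all columns identically and is fixed for
reproducibility. No allele is dropped per locus: the within-locus
sum-to-one constraint merely adds a zero eigenvalue per locus, which
cannot change leading components. Zero-variance columns are dropped and
reported.

Parallel analysis draws `reps` random datasets of the same dimensions,
normalizes and decomposes them identically, and reports the
significance of an observed leading-component contribution as
$(\#\{\text{replicates} \ge \text{observed}\} + 1)/(\text{reps}+1)$.
The null is independent standard normal entries by default; because
the appropriate null for frequency data is genuinely debatable, a
column-permutation alternative (`null = "permute"`) is exposed. The
random-data contribution falls as the number of variables grows at
fixed observations, so significance thresholds must always be
recomputed for the dataset at hand rather than reused.

# Admixture model

The clustering model is the admixture model with correlated cluster
frequencies: individual $i$ carries a membership vector $Q_i \sim
\mathrm{Dir}(\alpha, \ldots, \alpha)$; each gene copy picks a cluster
of origin from $Q_i$ and an allele from that cluster's frequencies
$P_{k,l}$; under the F-model prior, $P_{k,l} \sim
\mathrm{Dir}\!\left(p^{\mathrm{anc}}_{l}\,\tfrac{1-F_k}{F_k}\right)$
with an independent drift $F_k$ per cluster. This is a
re-implementation of the model class, not of any particular program:
the ancestral frequencies are fixed at the pooled empirical frequencies
rather than sampled (a collapse that removes a poorly identified block
from the sampler while preserving the correlated-prior shrinkage), the
allele-frequency prior parameter is fixed at 1, $\alpha$ is updated by
a Metropolis random walk with a uniform(0, 10) prior, and $F_k$ by a
logit-scale walk with a uniform(0, 1) prior. Missing genotypes
contribute no likelihood terms.

$\ln\Pr(X\mid K)$ is estimated from the recorded data log-likelihood
trace as $\overline{\ell} - \mathrm{var}(\ell)/2$. `select_K()` takes
the smallest K whose median estimate over runs lies within one median
absolute deviation (at the maximizing K) of the maximum — a plateau
rule that encodes the field's convention of preferring the smallest
adequate K, since the estimator tends to drift upward slowly past the
true cluster count while its run-to-run spread grows. Run alignment is
greedy label matching on Q-column correlations; the full CLUMPP search
is unnecessary at $K \le 7$, where greedy matching recovers column
permutations exactly.

Desk-scale defaults (burn-in 2,000, run 2,000, 5 runs) keep a full K
scan in minutes; the test and calibration runs use 300–500 sweeps on
strongly differentiated panels, where recovery is insensitive to chain
length (posterior mass concentrates quickly at $F \ge 0.25$ with 15–20
loci). With ten loci of moderate drift — the regime of the motivating
kind of survey — individual memberships are noisy and only
population-level averages are interpretable.

# External distance matrices

Linguistic distances come from a dated language tree supplied as a YAML
config: the distance between two populations is the age (years BP) of
the most recent common ancestor of their language-group leaves, which
makes the matrix an exact ultrametric. The shipped default encodes
three dated nodes — Chinese/Tibeto-Burman at 7,000 yr BP,
Mongolic/Turkic at 8,000 yr BP, and a root at 50,000 yr BP joining
those clades with Tai-Kadai, Mon-Khmer and Iranian — with all finer
structure collapsed onto the nearest dated ancestor and a within-group
distance of 0 (configurable), since no finer dates are defensible.
Geographic distances are haversine great-circle arcs on a 6,371 km
sphere, deliberately untransformed: a logarithm would map co-located
populations to $-\infty$ and distort nothing useful. Arc lengths ignore
landform barriers; where mountains channel gene flow this understates
effective distance, which is a known limitation of any coordinate-only
measure.

# Mantel machinery

`mantel()` correlates the upper off-diagonal vectors after aligning
matrices by label (never by position), and permutes row-and-column
order jointly. The partial (3-way) test residualizes both matrices on
the control by linear regression and permutes the residualized first
matrix (Smouse–Long–Sokal). P-values use the add-one convention
$(\#\{r_\pi \ge r\} + 1)/(B+1)$, one-tailed positive by default
(two-tailed available): an exact zero p-value is not a reproducible
claim, so the smallest reportable value is $1/(B+1)$. Under the null
(independent random point sets) the p-values are uniform, which the
suite checks by a KS test over 500 pairs. The
leave-one-language-group-out analysis reruns all 2-way and 3-way tests
on the complement of each group, flagging (rather than computing) rows
whose exclusion leaves fewer than four populations.

# Synthetic-data generator

The generator is the F-model itself, hierarchically: ancestral
frequencies per locus are symmetric Dirichlet (shape 1) over 5–12
alleles, whose allele labels are plausible dinucleotide fragment sizes
so file I/O paths are exercised realistically; clade frequencies drift
from the ancestor with $F_{\mathrm{between}}$ (default 0.08) and
population frequencies from their clade with $F_{\mathrm{within}}$
(default 0.05); genotypes are random unions of gametes
($F_{IS} = 0$ exact HWE sampling, with an autozygosity mixture for
$F_{IS} > 0$). The F-model was chosen over coalescent simulation
because it matches the correlated-frequencies prior of the clustering
module, giving clean parameter-recovery semantics; stepwise-mutation
realism is irrelevant here because all statistics downstream are
frequency-based.

The default panel reproduces the survey design the package's analyses
are calibrated against: 30 populations in 3 clades, sample sizes 37–95
with median 50 summing to 1,538 individuals, 10 loci, and a missingness
design with 5% background plus five cells at 75% concentrated in 4
populations and 2 loci — the pattern that makes the 40% tolerance drop
exactly those 4 populations from the full-loci subset and those 2 loci
from the full-population subset. The 75% rate (rather than a value just
above 60%) keeps realized per-cell rates decisively above the
tolerance at sample sizes of 37–50, where binomial noise on a 65% rate
would occasionally dip below 60%.

What the generator does **not** emulate: mutation processes (allele
identity carries no size homoplasy), linkage, selection, spatially
continuous isolation by distance (geography mirrors the clades, with
Gaussian scatter), or realistic within-clade linguistic structure (the
synthetic language tree hangs each clade directly off the root).
Passing tests therefore demonstrate correctness of the estimators and
calibration of the tests under the model's own assumptions — not that
real panels satisfy those assumptions.

# Numerical choices

* Frequency vectors must sum to 1 within $10^{-9}$; distance matrices
  must be symmetric within $10^{-12}$ with an exactly zero diagonal.
* Enumeration p-values carry a $10^{-9}$ tie tolerance on log
  probabilities; the chain uses $10^{-7}$, which also absorbs the
  drift of incremental log-probability updates over $10^5$ steps.
* Degenerate cases: monomorphic loci test as p = 1 with a flag;
  zero-variance PCA inputs error (all columns) or are dropped and
  reported (some columns); populations with zero typed copies at a
  locus yield an *absent* frequency vector, never a zero-filled one.
* All stochastic components take explicit seeds; reruns of the pipeline
  with an identical configuration are bit-identical, and the run
  manifest records a hash of the analysis settings.

# Problem sizes used in the shipped analyses

The numbered scripts under `analysis/` run the full chain on the
default synthetic panel with B = 1,000 bootstrap replicates, 5,000
Mantel permutations, 10,000 parallel-analysis replicates, and a
K = 2–5 admixture scan at 1,000 + 1,000 sweeps × 5 runs; the whole
sequence completes in under ten minutes on one core. The test suite
uses smaller replicate counts (200–1,000) and shorter chains on
strongly differentiated fixtures, sizes at which the checked properties
are already sharp.
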