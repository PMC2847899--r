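#!/usr/bin/env Rscript
# Allele-frequency PCA with Z-score normalization, parallel-analysis
# significance of the leading components, and the Mantel comparison of
# PC-score distances against geography.

library(msatpop)

ds <- read_genotypes("results/fixture/genotypes.str", "structure")
pm <- read_population_meta("results/fixture/populations.csv")
sub <- subset_by_missing_policy(ds, 0.40)$full_loci

ft <- allele_frequencies(sub)
z <- normalize_frequencies(ft)
res <- pca(z)
write_pca_report(res, "results", "full_loci_pca")
cat(sprintf("PC1 %.2f%%, PC2 %.2f%% of variance (%d populations x %d allele variables)\n",
            res$percent_variance[1], res$percent_variance[2],
            nrow(z), ncol(z)))

pa <- parallel_analysis(nrow(z), ncol(z), reps = 10000, seed = 31,
                        observed = res$percent_variance[1:2])
write.csv(pa$summary, "results/full_loci_parallel_analysis.csv",
          row.names = FALSE)
cat(sprintf("random-data PC1 reaches %.2f%% (+- %.2f), max %.2f%% over %d replicates\n",
            pa$summary$mean[1], pa$summary$sd[1], pa$summary$max[1],
            pa$reps))
cat(sprintf("significance of observed PC1, PC2: %.2g, %.2g\n",
            pa$significance[1], pa$significance[2]))

coords <- pm[pm$population %in% rownames(z), ]
geo <- geographic_distance_matrix(coords)
pcd <- pc_score_distances(res, k = 2)
mt <- mantel(pcd[coords$population, coords$population], geo,
             permutations = 5000, seed = 32)
cat(sprintf("PC-distance vs geography: Mantel r = %.3f, p = %.4f\n",
            mt$r, mt$p_value))
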