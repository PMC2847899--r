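test_that("DA and DC closed-form cases hold to 1e-12", {
  x <- freqs_single_locus(c("150" = 1.0, "152" = 0.0))
  y <- freqs_single_locus(c("150" = 0.25, "152" = 0.75))
  same <- freqs_single_locus(c("150" = 0.3, "152" = 0.7))
  disj1 <- freqs_single_locus(c("150" = 0.5, "152" = 0.5))
  disj2 <- freqs_single_locus(c("160" = 0.5, "162" = 0.5))

  expect_equal(da_distance(same, same), 0, tolerance = 1e-12)
  expect_equal(dc_distance(same, same), 0, tolerance = 1e-12)
  expect_equal(da_distance(disj1, disj2), 1, tolerance = 1e-12)
  expect_equal(dc_distance(disj1, disj2), 2 / pi * sqrt(2),
               tolerance = 1e-12)
  expect_equal(da_distance(x, y), 0.5, tolerance = 1e-12)
  expect_equal(dc_distance(x, y), 2 / pi * sqrt(2 * 0.5),
               tolerance = 1e-12)
  expect_error(da_distance(x, list(L9 = c("1" = 1))), "shared")
})

test_that("distances are symmetric and invariant to allele relabeling", {
  set.seed(4)
  for (i in 1:20) {
    k <- sample(3:8, 1)
    px <- as.vector(msatpop:::rdirichlet(1, rep(1, k)))
    py <- as.vector(msatpop:::rdirichlet(1, rep(1, k)))
    names(px) <- names(py) <- as.character(seq_len(k))
    x <- freqs_single_locus(px); y <- freqs_single_locus(py)
    expect_equal(da_distance(x, y), da_distance(y, x), tolerance = 1e-12)
    expect_equal(dc_distance(x, y), dc_distance(y, x), tolerance = 1e-12)
    perm <- sample(k)
    xp <- freqs_single_locus(setNames(px[perm], as.character(seq_len(k))))
    yp <- freqs_single_locus(setNames(py[perm], as.character(seq_len(k))))
    expect_equal(da_distance(xp, yp), da_distance(x, y),
                 tolerance = 1e-12)
    expect_lte(da_distance(x, y), 1)
    expect_lte(dc_distance(x, y), 2 / pi * sqrt(2) + 1e-12)
  }
})

test_that("multilocus DA is the mean of single-locus DA values", {
  truth <- generator_truth(n_pops = 4, n_loci = 6, groups = 2, seed = 9)
  gf <- generate_frequencies(truth)
  ds <- generate_genotypes(gf$freqs, rep(40, 4), seed = 9)
  ft <- allele_frequencies(ds)
  multi <- pairwise_matrix(ft, "DA")
  singles <- lapply(ft$loci, function(l) pairwise_matrix(ft, "DA", loci = l))
  avg <- Reduce(`+`, singles) / length(singles)
  expect_equal(unclass(multi), unclass(avg), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("pairwise matrices satisfy distance-matrix invariants", {
  df <- rbind(
    data.frame(population = "A", locus = "L1", allele = 1:2,
               frequency = c(0.5, 0.5), n_genes = 10),
    data.frame(population = "B", locus = "L1", allele = 1:2,
               frequency = c(0.5, 0.5), n_genes = 10))
  m <- pairwise_matrix(freq_table_from_long(df), "DA")
  expect_equal(unname(m), matrix(0, 2, 2), ignore_attr = TRUE)
  expect_error(pairwise_matrix(freq_table_from_long(df), "DA",
                               loci = "L9"), "lacks|L9")
})

test_that("generated clades order distances: within < between", {
  hits <- 0
  for (s in 1:20) {
    truth <- generator_truth(n_pops = 6, n_loci = 8, groups = 2,
                             F_between = 0.1, F_within = 0.02,
                             seed = 200 + s)
    gf <- generate_frequencies(truth)
    ds <- generate_genotypes(gf$freqs, rep(50, 6), seed = 200 + s)
    da <- pairwise_matrix(allele_frequencies(ds), "DA")
    grp <- truth$group[rownames(da)]
    same <- outer(grp, grp, `==`)[upper.tri(da)]
    v <- da[upper.tri(da)]
    if (mean(v[same]) < mean(v[!same])) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("bootstrap-over-loci is seeded, consistent, and degenerate at r = 1", {
  truth <- generator_truth(n_pops = 4, n_loci = 5, groups = 2, seed = 12)
  gf <- generate_frequencies(truth)
  ds <- generate_genotypes(gf$freqs, rep(40, 4), seed = 12)
  ft <- allele_frequencies(ds)

  b1 <- bootstrap_over_loci(ft, "DA", B = 50, seed = 7)
  b2 <- bootstrap_over_loci(ft, "DA", B = 50, seed = 7)
  expect_identical(b1$replicates, b2$replicates)
  expect_identical(b1$resampled_loci, b2$resampled_loci)
  expect_error(bootstrap_over_loci(ft, "DA", B = 0), "B")

  # r = 1: every replicate equals the single-locus matrix
  ft1 <- subset_freq_table(ft, loci = ft$loci[1])
  br <- bootstrap_over_loci(ft1, "DA", B = 10, seed = 1)
  base <- pairwise_matrix(ft1, "DA")
  for (m in br$replicates) expect_equal(m, base, tolerance = 1e-12)

  # bootstrap mean approaches the all-loci matrix
  bb <- bootstrap_over_loci(ft, "DA", B = 1000, seed = 3)
  arr <- simplify2array(lapply(bb$replicates, unclass))
  boot_mean <- apply(arr, c(1, 2), mean)
  boot_se <- apply(arr, c(1, 2), sd) / sqrt(1000)
  full <- pairwise_matrix(ft, "DA")
  off <- upper.tri(full)
  expect_true(all(abs(boot_mean[off] - full[off]) <=
                    3 * boot_se[off] + 1e-12))
})

test_that("PHYLIP square matrices round-trip", {
  m <- random_point_matrix(5, seed = 2, labels = paste0("pop", 1:5))
  path <- tempfile()
  write_phylip_matrix(m, path, digits = 10)
  back <- read_phylip_matrix(path)
  expect_equal(unclass(back), unclass(m), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(rownames(back), rownames(m))
})
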