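test_that("generators are bit-reproducible from the seed", {
  f1 <- generate_study_fixture(seed = 4)
  f2 <- generate_study_fixture(seed = 4)
  expect_identical(f1$ds$alleles, f2$ds$alleles)
  expect_identical(f1$freqs, f2$freqs)
  f3 <- generate_study_fixture(seed = 5)
  expect_false(identical(f1$ds$alleles, f3$ds$alleles))
})

test_that("vanishing drift reproduces the ancestral frequencies", {
  # one effective level of drift at F = 1e-4: per-allele sd is at most
  # sqrt(0.25e-4) = 0.005, so the worst deviation stays under 0.01
  truth <- generator_truth(n_pops = 2, n_loci = 4, groups = 1,
                           F_between = 1e-4, F_within = 1e-7, seed = 41)
  gf <- generate_frequencies(truth)
  dev <- max(unlist(lapply(truth$populations, function(p)
    lapply(truth$loci, function(l)
      max(abs(gf$freqs[[p]][[l]] - truth$ancestral[[l]]))))))
  expect_lt(dev, 0.01)
  expect_error(generator_truth(F_between = 1.5), "F_between")
})

test_that("F-model frequency variance matches the Dirichlet closed form", {
  # single level of drift F: Var(x) = p (1 - p) F
  truth <- generator_truth(n_pops = 1, n_loci = 400, groups = 1,
                           F_between = 0.5, F_within = 1e-6, seed = 43,
                           allele_range = c(4L, 4L))
  gf <- generate_frequencies(truth)
  # group draw carries the F = 0.5 drift; population adds ~nothing,
  # so mean (x - p)^2 over the allele draws ~ mean p(1-p) F within 10%
  obs <- mean(unlist(lapply(truth$loci, function(l)
    (gf$freqs$Pop01[[l]] - truth$ancestral[[l]])^2)))
  expected <- mean(unlist(lapply(truth$loci, function(l) {
    anc <- truth$ancestral[[l]]
    anc * (1 - anc) * 0.5
  })))
  expect_lt(abs(obs - expected) / expected, 0.1)
})

test_that("sibling populations are closer than cousins on average", {
  closer <- 0
  for (s in 1:100) {
    truth <- generator_truth(n_pops = 4, n_loci = 6, groups = 2,
                             F_between = 0.1, F_within = 0.03,
                             seed = 300 + s)
    gf <- generate_frequencies(truth)
    # Pop01/Pop02 share group G1; Pop03/Pop04 share G2
    d_sib <- da_distance(gf$freqs$Pop01, gf$freqs$Pop02)
    d_cous <- da_distance(gf$freqs$Pop01, gf$freqs$Pop03)
    if (d_sib < d_cous) closer <- closer + 1
  }
  expect_gt(closer, 75)
})

test_that("HWE sampling gives the expected heterozygosity", {
  truth <- generator_truth(n_pops = 1, n_loci = 8, groups = 1, seed = 47)
  gf <- generate_frequencies(truth)
  ds <- generate_genotypes(gf$freqs, c(Pop01 = 600), f_is = 0, seed = 47)
  for (l in seq_along(ds$loci)) {
    p <- gf$freqs$Pop01[[ds$loci[l]]]
    h_exp <- 1 - sum(p^2)
    a1 <- ds$alleles[, 2 * l - 1]; a2 <- ds$alleles[, 2 * l]
    h_obs <- mean(a1 != a2)
    se <- sqrt(h_exp * (1 - h_exp) / 600)
    expect_lt(abs(h_obs - h_exp), 3 * se + 1e-9)
  }
  expect_error(generate_genotypes(gf$freqs, c(Pop01 = 10), f_is = 1),
               "f_is")
})

test_that("inbreeding is detected by the exact test at high power", {
  truth <- generator_truth(n_pops = 1, n_loci = 8, groups = 1, seed = 53)
  gf <- generate_frequencies(truth)
  rejections <- 0; total <- 0
  for (s in 1:6) {
    ds <- generate_genotypes(gf$freqs, c(Pop01 = 50), f_is = 0.5,
                             seed = 530 + s)
    scan <- hwe_scan(ds, chain_steps = 2e4, burn_in = 2e3, seed = s)
    rejections <- rejections + sum(scan$departure)
    total <- total + nrow(scan)
  }
  expect_gt(rejections / total, 0.8)
})

test_that("study sample sizes match the design", {
  sizes <- study_sample_sizes(30)
  expect_equal(sum(sizes), 1538L)
  expect_equal(range(sizes), c(37L, 95L))
  expect_equal(median(sizes), 50)
})

test_that("missingness injection honors the design matrix", {
  ds <- toy_dataset()
  expect_identical(inject_missing(ds, 0, seed = 1)$alleles, ds$alleles)
  design <- matrix(c(1, 0, 0, 0), 2, 2,
                   dimnames = list(c("popA", "popB"), c("LOC1", "LOC2")))
  ds2 <- inject_missing(ds, design, seed = 1)
  expect_equal(missing_rates(ds2)["popA", "LOC1"], 1)
  expect_equal(missing_rates(ds2)["popB", "LOC1"], 0)
  expect_error(inject_missing(ds, 1.5), "rates")
})

test_that("admixed genotypes follow the membership mixture", {
  truth <- generator_truth(n_pops = 2, n_loci = 10, groups = 2,
                           F_between = 0.4, F_within = 0.01, seed = 59)
  gf <- generate_frequencies(truth)
  parents <- gf$freqs
  # Q = (1, 0): indistinguishable from parent-1 sampling
  q1 <- matrix(c(1, 0), 200, 2, byrow = TRUE)
  adm <- generate_admixed(parents, q1, seed = 60)
  ft <- allele_frequencies(adm$ds)
  for (l in truth$loci) {
    p_true <- parents$Pop01[[l]]
    for (a in names(p_true)) {
      est <- ft$freq$Admixed[[l]]
      est_a <- if (a %in% names(est)) est[[a]] else 0
      se <- sqrt(p_true[[a]] * (1 - p_true[[a]]) / 400)
      expect_lt(abs(est_a - p_true[[a]]), 4 * se + 0.01)
    }
  }
  # Q = (0.5, 0.5): heterozygosity reflects the mixed gene pool
  qh <- matrix(0.5, 300, 2)
  admh <- generate_admixed(parents, qh, seed = 61)
  fth <- allele_frequencies(admh$ds)
  for (l in truth$loci[1:3]) {
    mix <- 0.5 * merge_freq(parents$Pop01[[l]], parents$Pop02[[l]])$x +
      0.5 * merge_freq(parents$Pop01[[l]], parents$Pop02[[l]])$y
    h_mix <- 1 - sum(mix^2)
    h_obs <- expected_heterozygosity(fth$freq$Admixed[[l]],
                                     fth$n_genes["Admixed", l])
    expect_lt(abs(h_obs - h_mix), 0.08)
    h_parents <- c(1 - sum(parents$Pop01[[l]]^2),
                   1 - sum(parents$Pop02[[l]]^2))
    expect_gte(h_mix + 1e-9, min(h_parents))
  }
  expect_error(generate_admixed(parents, matrix(c(0.5, 0.4), 1)), "sum")
})
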