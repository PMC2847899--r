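test_that("structure-format files parse, with explicit missing handling", {
  path <- toy_structure_file()
  ds <- read_genotypes(path, "structure")
  expect_equal(ds$loci, "LOC1")
  expect_equal(nrow(ds$ind), 2L)
  expect_equal(unname(ds$alleles[1, ]), c(150L, 152L))
  expect_true(all(is.na(ds$alleles[2, ])))

  # malformed rows are rejected with the offending line
  bad <- tempfile()
  writeLines(c("LOC1", "ind1 popA 150"), bad)
  expect_error(read_genotypes(bad, "structure"), "line 2")
  writeLines(c("LOC1", "ind1 popA 150 -5"), bad)
  expect_error(read_genotypes(bad, "structure"), "missing code")
})

test_that("write/read round-trips are identical in both dialects", {
  ds <- toy_dataset()
  for (dialect in c("structure", "csv")) {
    path <- tempfile()
    write_genotypes(ds, path, dialect)
    back <- read_genotypes(path, dialect)
    expect_identical(back$alleles, ds$alleles)
    expect_identical(back$ind$id, ds$ind$id)
    expect_identical(back$ind$population, ds$ind$population)
    expect_identical(back$loci, ds$loci)
  }
})

test_that("half-missing genotypes are demoted to fully missing", {
  ind <- data.frame(id = "i1", population = "p")
  al <- matrix(c(150L, NA), 1)
  ds <- str_dataset(ind, "L1", al)
  expect_true(all(is.na(ds$alleles)))
})

test_that("study-scale fixture has the designed dimensions", {
  fx <- generate_study_fixture(seed = 1)
  expect_equal(nrow(fx$ds$ind), 1538L)
  expect_equal(length(populations(fx$ds)), 30L)
  expect_equal(length(fx$ds$loci), 10L)
  # round-trip through the structure writer preserves the panel
  path <- tempfile()
  write_genotypes(fx$ds, path, "structure")
  back <- read_genotypes(path, "structure")
  expect_identical(back$alleles, fx$ds$alleles)
})

test_that("missing rates are exact fractions of population size", {
  ds <- toy_dataset()
  mr <- missing_rates(ds)
  expect_equal(mr["popA", "LOC1"], 0)
  expect_equal(mr["popA", "LOC2"], 1 / 3)
  expect_equal(mr["popB", "LOC2"], 0)

  # injected missingness at designed cells is recovered within
  # binomial error, and always exceeds the subsetting tolerance
  fx <- generate_study_fixture(seed = 2)
  mr <- missing_rates(fx$ds)
  bad <- which(fx$design > 0.6, arr.ind = TRUE)
  expect_equal(nrow(bad), 5L)
  n_bad <- sample_sizes(fx$ds)[rownames(bad)]
  se <- sqrt(0.75 * 0.25 / n_bad)
  expect_true(all(abs(mr[bad] - 0.75) < 3 * se))
  expect_true(all(mr[bad] > 0.4))
  expect_true(all(mr[fx$design <= 0.6] < 0.4))

  # at larger samples the injected rate pins the realized rate above 0.6
  truth <- generator_truth(n_pops = 1, n_loci = 2, groups = 1, seed = 3)
  big <- generate_genotypes(generate_frequencies(truth)$freqs,
                            c(Pop01 = 400), seed = 3)
  design <- matrix(c(0.65, 0), 1, 2,
                   dimnames = list("Pop01", big$loci))
  mr_big <- missing_rates(inject_missing(big, design, seed = 3))
  expect_gt(mr_big["Pop01", big$loci[1]], 0.6)
  expect_equal(mr_big[["Pop01", big$loci[2]]], 0)
})

test_that("missing-policy subsetting matches the designed pattern and is idempotent", {
  fx <- generate_study_fixture(seed = 1)
  sub <- subset_by_missing_policy(fx$ds, 0.40)
  expect_equal(sort(sub$dropped_populations),
               sort(unique(rownames(which(fx$design > 0.6,
                                          arr.ind = TRUE)))))
  expect_equal(length(populations(sub$full_loci)), 26L)
  expect_equal(length(sub$full_population$loci), 8L)
  expect_equal(sort(sub$dropped_loci),
               sort(unique(colnames(fx$design)[which(fx$design > 0.6,
                                                     arr.ind = TRUE)[, 2]])))
  # idempotent: reapplying to its own outputs changes nothing
  again <- subset_by_missing_policy(sub$full_loci, 0.40)
  expect_identical(again$full_loci$alleles, sub$full_loci$alleles)
  expect_identical(again$full_population$loci, sub$full_loci$loci)

  # clean data pass through unchanged
  ds <- toy_dataset()
  clean <- subset_individuals_keep_all <- subset_by_missing_policy(ds, 0.5)
  expect_identical(clean$full_loci$alleles, ds$alleles)
  expect_identical(clean$full_population$alleles, ds$alleles)

  # a fully missing cell always drops its population from full_loci
  ds2 <- inject_missing(ds, matrix(c(0, 0, 1, 0), 2, 2,
                                   dimnames = list(c("popA", "popB"),
                                                   c("LOC1", "LOC2"))),
                        seed = 1)
  sub2 <- subset_by_missing_policy(ds2, 0.4)
  expect_false("popA" %in% populations(sub2$full_loci))
  expect_error(subset_by_missing_policy(ds, 1.2), "tolerance")
})

test_that("allele frequencies count typed gene copies only", {
  ds <- toy_dataset()
  ft <- allele_frequencies(ds)
  # popA LOC1: genotypes 150/150, 150/152, 152/152 -> 3 and 3 copies
  expect_equal(ft$freq$popA$LOC1, c("150" = 0.5, "152" = 0.5))
  expect_equal(ft$n_genes["popA", "LOC1"], 6L)
  # popA LOC2 has 1 missing genotype: 4 typed copies
  expect_equal(ft$n_genes["popA", "LOC2"], 4L)
  expect_equal(sum(ft$freq$popA$LOC2), 1)
  # gene-copy accounting: n_genes + 2 * missing = 2 * sample size
  mr <- missing_rates(ds)
  ss <- sample_sizes(ds)
  for (p in populations(ds)) for (l in ds$loci)
    expect_equal(unname(ft$n_genes[p, l] + 2 * mr[p, l] * ss[p]),
                 2 * ss[[p]])

  # all-missing locus yields an absent vector, not zeros
  ind <- data.frame(id = c("a", "b"), population = "p")
  al <- matrix(NA_integer_, 2, 2)
  ft2 <- allele_frequencies(str_dataset(ind, "L1", al))
  expect_null(ft2$freq$p$L1)
  expect_equal(ft2$n_genes["p", "L1"], 0L)
})

test_that("simple {150/150, 150/152} example gives 0.75/0.25", {
  ind <- data.frame(id = c("a", "b"), population = "p")
  al <- rbind(c(150L, 150L), c(150L, 152L))
  ft <- allele_frequencies(str_dataset(ind, "L1", al))
  expect_equal(ft$freq$p$L1, c("150" = 0.75, "152" = 0.25))
  expect_equal(ft$n_genes["p", "L1"], 4L)
})

test_that("sample frequencies converge to generator truth", {
  truth <- generator_truth(n_pops = 1, n_loci = 4, groups = 1, seed = 31)
  gf <- generate_frequencies(truth)
  ds <- generate_genotypes(gf$freqs, c(Pop01 = 500), seed = 31)
  ft <- allele_frequencies(ds)
  for (l in truth$loci) {
    p_true <- gf$freqs$Pop01[[l]]
    p_hat <- ft$freq$Pop01[[l]]
    for (a in names(p_true)) {
      se <- sqrt(p_true[a] * (1 - p_true[a]) / 1000)
      est <- if (a %in% names(p_hat)) p_hat[[a]] else 0
      expect_lt(abs(est - p_true[[a]]), 3 * se + 1e-9)
    }
    expect_equal(sum(p_hat), 1, tolerance = 1e-12)
  }
})
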