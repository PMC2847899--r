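# ---------------------------------------------------------------------------
# Expected heterozygosity and exact tests of Hardy-Weinberg equilibrium

#' Unbiased expected heterozygosity
#'
#' H_E = n/(n-1) * (1 - sum p_i^2), with n the number of typed gene copies.
#' The n/(n-1) factor removes the downward bias of the plug-in estimator in
#' finite samples.
#'
#' @param freqs numeric vector of allele frequencies summing to 1.
#' @param n_genes number of successfully typed gene copies (>= 2).
#' @return H_E in [0, 1).
#' @export
expected_heterozygosity <- function(freqs, n_genes) {
  if (n_genes < 2) stop("n_genes must be >= 2")
  if (abs(sum(freqs) - 1) > 1e-6) stop("frequencies must sum to 1")
  he <- n_genes / (n_genes - 1) * (1 - sum(freqs^2))
  max(he, 0)
}

#' Heterozygosity summary over a frequency table
#'
#' @param ft a `freq_table`.
#' @return List with `he` (populations x loci matrix of H_E, `NA` where a
#'   population has no typed copies), `per_locus` (data.frame of mean and
#'   sample sd across populations; sd is `NA` with a single population) and
#'   `percentiles` (10th/50th/90th percentile of the pooled H_E values).
#' @export
heterozygosity_summary <- function(ft) {
  he <- matrix(NA_real_, length(ft$populations), length(ft$loci),
               dimnames = list(ft$populations, ft$loci))
  for (p in ft$populations) for (l in names(ft$freq[[p]])) {
    ng <- ft$n_genes[p, l]
    if (ng >= 2) he[p, l] <- expected_heterozygosity(ft$freq[[p]][[l]], ng)
  }
  per_locus <- data.frame(
    locus = ft$loci,
    mean = apply(he, 2, function(x) mean(x, na.rm = TRUE)),
    sd = apply(he, 2, function(x) if (sum(!is.na(x)) < 2) NA_real_
               else sd(x, na.rm = TRUE)),
    row.names = NULL)
  pooled <- he[!is.na(he)]
  list(he = he, per_locus = per_locus,
       percentiles = quantile(pooled, c(0.1, 0.5, 0.9), names = TRUE))
}

# ---------------------------------------------------------------------------
# Exact HWE test (Guo & Thompson)

#' Genotype count table for one population-locus cell
#'
#' @param ds an [str_dataset()].
#' @param population population label.
#' @param locus locus name.
#' @return Symmetric k x k matrix of genotype counts (counts stored on the
#'   upper triangle including the diagonal), dimnames = allele sizes.
#' @export
genotype_counts <- function(ds, population, locus) {
  j <- match(locus, ds$loci)
  if (is.na(j)) stop("unknown locus: ", locus)
  rows <- ds$ind$population == population
  a1 <- ds$alleles[rows, 2L * j - 1L]
  a2 <- ds$alleles[rows, 2L * j]
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  tab <- matrix(0L, k, k, dimnames = list(alleles, alleles))
  i1 <- match(pmin(a1, a2), alleles)
  i2 <- match(pmax(a1, a2), alleles)
  for (g in seq_along(i1)) tab[i1[g], i2[g]] <- tab[i1[g], i2[g]] + 1L
  tab
}

# log conditional probability of a genotype table given its allele counts:
# log [ n! prod(m_i!) 2^h / ( (2n)! prod(n_ij!) ) ]
log_table_prob_r <- function(tab) {
  k <- nrow(tab)
  tab <- as_upper_table(tab)
  n <- sum(tab)
  m <- allele_counts_from_table(tab)
  h <- sum(tab[upper.tri(tab)])
  lgamma(n + 1) + sum(lgamma(m + 1)) + h * log(2) -
    lgamma(2 * n + 1) - sum(lgamma(tab[upper.tri(tab, diag = TRUE)] + 1))
}

as_upper_table <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab)) stop("genotype table must be square")
  out <- tab + t(tab)
  diag(out) <- diag(tab)
  out[lower.tri(out)] <- 0
  storage.mode(out) <- "integer"
  out
}

allele_counts_from_table <- function(tab) {
  k <- nrow(tab)
  vapply(seq_len(k), function(i)
    sum(tab[i, i:k]) + sum(tab[seq_len(i), i]), numeric(1))
}

# Exact p by full enumeration of tables with the observed allele counts.
# Returns NULL if the number of tables would exceed `max_tables`.
hwe_enumerate <- function(tab, max_tables = 2e5) {
  tab <- as_upper_table(tab)
  m <- as.integer(allele_counts_from_table(tab))
  k <- length(m)
  if (k == 2L) {
    if (length(seq(m[1] %% 2L, min(m), by = 2L)) > max_tables)
      return(NULL)
    return(hwe_enumerate_biallelic(tab, m))
  }
  lp_obs <- log_table_prob_r(tab)
  n <- sum(tab)
  count <- 0L
  p_sum <- 0
  total <- 0
  cur <- matrix(0L, k, k)
  const <- lgamma(n + 1) + sum(lgamma(m + 1)) - lgamma(2 * n + 1)
  overflow <- FALSE
  rec <- function(i, rem) {
    # distribute rem[i] gene copies of allele i over cells (i,i), (i,j>i)
    if (overflow) return()
    if (i > k) {
      count <<- count + 1L
      if (count > max_tables) { overflow <<- TRUE; return() }
      h <- sum(cur[upper.tri(cur)])
      lp <- const + h * log(2) -
        sum(lgamma(cur[upper.tri(cur, diag = TRUE)] + 1))
      pr <- exp(lp)
      total <<- total + pr
      if (lp <= lp_obs + 1e-9) p_sum <<- p_sum + pr
      return()
    }
    fill <- function(j, left) {
      if (overflow) return()
      if (j > k) { if (left == 0L) rec(i + 1L, rem) ; return() }
      if (j == i) {
        for (d in 0:(left %/% 2L)) {
          cur[i, i] <<- d
          fill(j + 1L, left - 2L * d)
        }
        cur[i, i] <<- 0L
      } else {
        hi <- min(left, rem[j])
        for (d in 0:hi) {
          cur[i, j] <<- d
          rem[j] <<- rem[j] - d
          fill(j + 1L, left - d)
          rem[j] <<- rem[j] + d
        }
        cur[i, j] <<- 0L
      }
    }
    fill(i, rem[i])
  }
  env <- environment()
  rem <- m
  rec(1L, rem)
  if (overflow) return(NULL)
  # `total` should be 1 up to floating error; normalize defensively
  list(p_value = min(p_sum / total, 1), n_tables = count, total_prob = total)
}

hwe_enumerate_biallelic <- function(tab, m) {
  n <- sum(tab)
  h_obs <- tab[1, 2]
  hs <- seq(m[1] %% 2L, min(m), by = 2L)
  lp <- lgamma(n + 1) + sum(lgamma(m + 1)) - lgamma(2 * n + 1) +
    hs * log(2) - lgamma((m[1] - hs) / 2 + 1) -
    lgamma((m[2] - hs) / 2 + 1) - lgamma(hs + 1)
  pr <- exp(lp)
  lp_obs <- lp[match(h_obs, hs)]
  list(p_value = min(sum(pr[lp <= lp_obs + 1e-9]) / sum(pr), 1),
       n_tables = length(hs), total_prob = sum(pr))
}

#' Exact test of Hardy-Weinberg equilibrium (Guo-Thompson)
#'
#' Conditional exact test of HW genotype proportions given the observed
#' allele counts. The p-value is the total conditional probability of
#' genotype tables no more probable than the observed one. Small problems
#' are solved by full enumeration of tables; larger ones by the
#' Guo-Thompson Markov chain Monte Carlo with allele-swap proposals.
#'
#' @param counts square genotype-count matrix (rows/cols = alleles; the
#'   matrix may carry counts on either or both triangles, they are summed).
#' @param max_enumeration largest number of genotype tables enumerated
#'   before switching to Monte Carlo.
#' @param chain_steps total Markov chain steps.
#' @param burn_in discarded initial steps.
#' @param seed optional integer seed.
#' @return List with `p_value`, `method` (`"enumeration"` or
#'   `"monte_carlo"`), `se` (Monte Carlo batch-means standard error, `NA`
#'   for enumeration), `chain_length`, and `degenerate` (TRUE for a
#'   monomorphic locus, where `p_value` is 1 by convention).
#' @export
hwe_exact_test <- function(counts, max_enumeration = 2e4,
                           chain_steps = 1e5, burn_in = 1e4, seed = NULL) {
  tab <- as_upper_table(counts)
  if (any(tab < 0)) stop("genotype counts must be nonnegative")
  if (sum(tab) < 1) stop("need at least one genotype")
  k <- nrow(tab)
  m <- allele_counts_from_table(tab)
  if (sum(m > 0) < 2L)
    return(list(p_value = 1, method = "degenerate", se = NA_real_,
                chain_length = 0L, degenerate = TRUE))
  enum <- hwe_enumerate(tab, max_tables = max_enumeration)
  if (!is.null(enum))
    return(list(p_value = enum$p_value, method = "enumeration",
                se = NA_real_, chain_length = 0L, degenerate = FALSE,
                n_tables = enum$n_tables))
  if (!is.null(seed)) set.seed(seed)
  res <- gt_chain(tab, as.integer(chain_steps), as.integer(burn_in))
  list(p_value = res$p_value, method = "monte_carlo", se = res$se,
       chain_length = res$steps, degenerate = FALSE)
}

#' HWE scan over every population-locus cell
#'
#' @param ds an [str_dataset()].
#' @param alpha significance threshold used for the `departure` flag (no
#'   multiple-testing correction is applied).
#' @param max_enumeration per-cell enumeration budget; scans keep this
#'   small because highly multiallelic cells overflow any budget and are
#'   better sent straight to Monte Carlo.
#' @param ... passed to [hwe_exact_test()].
#' @return data.frame with columns `population`, `locus`, `p_value`,
#'   `method`, `departure`.
#' @export
hwe_scan <- function(ds, alpha = 0.05, max_enumeration = 500, ...) {
  pops <- populations(ds)
  grid <- expand.grid(population = pops, locus = ds$loci,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(r) {
    tab <- genotype_counts(ds, grid$population[r], grid$locus[r])
    if (sum(tab) == 0L)
      return(data.frame(p_value = NA_real_, method = "absent"))
    h <- hwe_exact_test(tab, max_enumeration = max_enumeration, ...)
    data.frame(p_value = h$p_value, method = h$method)
  })
  out <- cbind(grid, do.call(rbind, res))
  out$departure <- !is.na(out$p_value) & out$p_value < alpha
  out
}

#' Write an HWE scan report as a population x locus CSV of p-values
#' @param scan output of [hwe_scan()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hwe_report <- function(scan, path) {
  wide <- reshape_wide(scan, "population", "locus", "p_value")
  write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

reshape_wide <- function(df, row_var, col_var, val_var) {
  rows <- unique(df[[row_var]]); cols <- unique(df[[col_var]])
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  for (r in seq_len(nrow(df)))
    m[df[[row_var]][r], df[[col_var]][r]] <- df[[val_var]][r]
  data.frame(setNames(list(rows), row_var), m, check.names = FALSE,
             row.names = NULL)
}
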