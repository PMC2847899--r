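# ---------------------------------------------------------------------------
# Mantel and partial Mantel tests between distance matrices

offdiag_vector <- function(m) m[upper.tri(m)]

align_matrices <- function(a, b) {
  la <- rownames(a); lb <- rownames(b)
  if (!setequal(la, lb))
    stop("matrices are on different label sets")
  b <- b[la, la, drop = FALSE]
  list(a = a, b = b, labels = la)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the vectorized upper off-diagonal entries,
#' with a permutation p-value obtained by jointly permuting the row and
#' column order of the second matrix. Matrices are aligned by label, not
#' position. The p-value uses the add-one convention
#' `(count + 1) / (permutations + 1)` and so is never exactly 0.
#'
#' @param a,b labeled distance matrices on the same label set.
#' @param permutations number of permutations.
#' @param seed integer seed.
#' @param alternative `"greater"` (default, one-tailed positive) or
#'   `"two.sided"`.
#' @return List of class `mantel_result`: `r`, `p_value`, `permutations`,
#'   `alternative`, `n` (number of labels).
#' @export
mantel <- function(a, b, permutations = 5000, seed = 1,
                   alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  al <- align_matrices(a, b)
  va <- offdiag_vector(al$a)
  if (sd(va) == 0 || sd(offdiag_vector(al$b)) == 0)
    stop("constant distance matrix: correlation undefined")
  n <- length(al$labels)
  r_obs <- cor(va, offdiag_vector(al$b))
  set.seed(seed)
  r_perm <- vapply(seq_len(permutations), function(i) {
    p <- sample.int(n)
    cor(va, offdiag_vector(al$b[p, p]))
  }, numeric(1))
  p <- perm_pvalue(r_obs, r_perm, alternative)
  structure(list(r = r_obs, p_value = p, permutations = permutations,
                 alternative = alternative, n = n, controlled = NULL),
            class = "mantel_result")
}

perm_pvalue <- function(obs, perm, alternative) {
  if (alternative == "greater")
    (sum(perm >= obs) + 1) / (length(perm) + 1)
  else
    (sum(abs(perm) >= abs(obs)) + 1) / (length(perm) + 1)
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.4f, p = %.4g (%d permutations%s)\n",
              x$r, x$p_value, x$permutations,
              if (!is.null(x$controlled))
                paste0(", controlling ", x$controlled) else ""))
  invisible(x)
}

#' Partial (3-way) Mantel test
#'
#' Correlation of the residuals of `a` and `b` after linear regression of
#' their off-diagonal vectors on those of `control`; the permutation
#' p-value follows the Smouse-Long-Sokal scheme, permuting the
#' residualized first matrix.
#'
#' @param a,b,control labeled distance matrices on the same label set.
#' @inheritParams mantel
#' @return A `mantel_result` with `controlled` set.
#' @export
partial_mantel <- function(a, b, control, permutations = 5000, seed = 1,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  al1 <- align_matrices(a, b)
  al2 <- align_matrices(a, control)
  labels <- al1$labels
  n <- length(labels)
  resid_mat <- function(m, ctrl_v) {
    v <- offdiag_vector(m)
    r <- stats::residuals(stats::lm(v ~ ctrl_v))
    out <- matrix(0, n, n, dimnames = list(labels, labels))
    out[upper.tri(out)] <- r
    out + t(out)
  }
  cv <- offdiag_vector(al2$b)
  if (sd(cv) == 0) stop("constant control matrix")
  ra <- resid_mat(al1$a, cv)
  rb <- resid_mat(al1$b, cv)
  r_obs <- cor(offdiag_vector(ra), offdiag_vector(rb))
  set.seed(seed)
  vb <- offdiag_vector(rb)
  r_perm <- vapply(seq_len(permutations), function(i) {
    p <- sample.int(n)
    cor(offdiag_vector(ra[p, p]), vb)
  }, numeric(1))
  p <- perm_pvalue(r_obs, r_perm, alternative)
  structure(list(r = r_obs, p_value = p, permutations = permutations,
                 alternative = alternative, n = n,
                 controlled = deparse(substitute(control))),
            class = "mantel_result")
}

#' Leave-one-language-group-out Mantel analysis
#'
#' For each language group, restricts the genetic, geographic and
#' linguistic matrices to the populations *outside* that group and reruns
#' all 2-way tests and the 3-way tests of genetics against geography
#' (controlling linguistics) and genetics against linguistics (controlling
#' geography). The row with an empty excluded group is the full-data
#' analysis.
#'
#' @param gen,geo,ling labeled distance matrices on the same populations.
#' @param groups named character vector or list mapping population ->
#'   language group; must cover every label.
#' @param permutations permutations per test.
#' @param seed integer seed.
#' @param min_populations rows whose exclusion leaves fewer than this many
#'   populations are flagged (`computed = FALSE`) instead of tested.
#' @return data.frame with one row per (excluded group x test) giving
#'   `excluded`, `test`, `type`, `r`, `p_value`, `n`, `computed`.
#' @export
exclusion_analysis <- function(gen, geo, ling, groups, permutations = 5000,
                               seed = 1, min_populations = 4) {
  labels <- rownames(gen)
  groups <- unlist(groups)
  if (!all(labels %in% names(groups)))
    stop("groups must cover every population")
  excl_levels <- c("none", unique(unname(groups[labels])))
  out <- list()
  for (g in excl_levels) {
    keep <- if (g == "none") labels else labels[groups[labels] != g]
    tag <- if (g == "none") "full" else paste0("non-", g)
    if (length(keep) < min_populations) {
      out[[length(out) + 1L]] <- data.frame(
        excluded = tag, test = NA, type = NA, r = NA_real_,
        p_value = NA_real_, n = length(keep), computed = FALSE)
      next
    }
    sub <- function(m) m[keep, keep, drop = FALSE]
    g2 <- list(
      GEN_GEO = mantel(sub(gen), sub(geo), permutations, seed),
      GEN_LING = mantel(sub(gen), sub(ling), permutations, seed),
      LING_GEO = mantel(sub(ling), sub(geo), permutations, seed))
    g3 <- list(
      GEN_GEO = partial_mantel(sub(gen), sub(geo), sub(ling),
                               permutations, seed),
      GEN_LING = partial_mantel(sub(gen), sub(ling), sub(geo),
                                permutations, seed))
    for (nm in names(g2))
      out[[length(out) + 1L]] <- data.frame(
        excluded = tag, test = nm, type = "2-way", r = g2[[nm]]$r,
        p_value = g2[[nm]]$p_value, n = length(keep), computed = TRUE)
    for (nm in names(g3))
      out[[length(out) + 1L]] <- data.frame(
        excluded = tag, test = nm, type = "3-way", r = g3[[nm]]$r,
        p_value = g3[[nm]]$p_value, n = length(keep), computed = TRUE)
  }
  do.call(rbind, out)
}
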