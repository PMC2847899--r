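# ---------------------------------------------------------------------------
# Allele-frequency PCA with Z-score normalization and parallel analysis

#' Population x allele-variable matrix of Z-scored frequencies
#'
#' Builds one column per (locus, allele) pair observed in the chosen
#' populations (alleles absent from a population enter as frequency 0),
#' then centers and scales each column to mean 0 and standard deviation 1
#' (population sd, divisor n). Zero-variance columns are dropped and
#' reported in the `dropped` attribute.
#'
#' @param ft a `freq_table`.
#' @param populations population subset (default: all; >= 2 required).
#' @return Numeric matrix (populations x variables) with attribute
#'   `dropped` listing zero-variance variables removed.
#' @export
normalize_frequencies <- function(ft, populations = NULL) {
  pops <- populations %||% ft$populations
  if (length(pops) < 2L) stop("need at least 2 populations")
  cols <- list()
  for (l in ft$loci) {
    alleles <- sort(unique(unlist(lapply(pops, function(p)
      names(ft$freq[[p]][[l]])))))
    for (a in alleles) {
      v <- vapply(pops, function(p) {
        f <- ft$freq[[p]][[l]]
        if (is.null(f))
          stop("population ", p, " has no frequencies at locus ", l)
        unname(f[a]) %|na|% 0
      }, numeric(1))
      cols[[paste(l, a, sep = ".")]] <- v
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- pops
  mu <- colMeans(m)
  sdev <- sqrt(colMeans(sweep(m, 2, mu)^2))   # population sd, divisor n
  keep <- sdev > 1e-12
  if (!any(keep)) stop("all variables have zero variance")
  z <- sweep(sweep(m[, keep, drop = FALSE], 2, mu[keep]), 2, sdev[keep],
             `/`)
  attr(z, "dropped") <- colnames(m)[!keep]
  z
}

`%|na|%` <- function(a, b) if (is.na(a)) b else a

#' Principal component analysis of a normalized matrix
#'
#' Eigendecomposition of the column covariance of the (already
#' normalized) matrix via singular value decomposition; components are
#' ordered by decreasing variance and the percent variance shares sum
#' to 100.
#'
#' @param m numeric matrix, observations x variables.
#' @return List of class `pca_result`: `scores` (observations x
#'   components), `loadings` (variables x components), `percent_variance`,
#'   `variable_names`.
#' @export
pca <- function(m) {
  if (nrow(m) < 2L || ncol(m) < 2L) stop("need >= 2 rows and columns")
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  lambda <- pc$sdev^2
  tot <- sum(lambda)
  pv <- if (tot > 0) 100 * lambda / tot else rep(0, length(lambda))
  structure(list(scores = pc$x, loadings = pc$rotation,
                 percent_variance = pv,
                 variable_names = colnames(m),
                 degenerate = tot <= 0),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(5L, length(x$percent_variance))
  cat("pca_result:", nrow(x$scores), "observations,",
      length(x$variable_names), "variables\n")
  cat("  leading percent variance:",
      paste(sprintf("%.2f", x$percent_variance[seq_len(k)]),
            collapse = " "), "\n")
  invisible(x)
}

#' Parallel analysis of PCA component contributions
#'
#' Draws random datasets of the same dimension as the observed one
#' (independent standard normal entries by default, or column-wise
#' permutations of supplied real data), applies the same column
#' normalization and PCA, and records the percent variance of the leading
#' components. The significance of an observed leading-component
#' contribution is `(count of replicates with a first-component
#' contribution >= observed + 1) / (reps + 1)`.
#'
#' @param n_obs,n_vars dimensions of the random datasets.
#' @param reps number of random datasets.
#' @param seed integer seed.
#' @param observed optional vector of observed percent contributions; if
#'   given, a significance is reported for each against the matching
#'   component.
#' @param n_components number of leading components recorded.
#' @param null `"normal"` for iid standard normal entries, or
#'   `"permute"` to shuffle each column of `data` independently.
#' @param data real matrix, required for `null = "permute"`.
#' @return List of class `parallel_analysis`: `replicate_contributions`
#'   (reps x components), `summary` (mean/sd/max per component),
#'   `significance`.
#' @export
parallel_analysis <- function(n_obs, n_vars, reps = 10000, seed = 1,
                              observed = NULL, n_components = 2,
                              null = c("normal", "permute"), data = NULL) {
  null <- match.arg(null)
  if (reps < 1) stop("reps must be >= 1")
  if (n_obs < 2 || n_vars < 2) stop("need n_obs >= 2 and n_vars >= 2")
  if (null == "permute" && is.null(data))
    stop("null = 'permute' requires `data`")
  set.seed(seed)
  n_components <- min(n_components, n_obs - 1L, n_vars)
  contrib <- matrix(NA_real_, reps, n_components)
  for (b in seq_len(reps)) {
    x <- if (null == "normal") {
      matrix(rnorm(n_obs * n_vars), n_obs, n_vars)
    } else {
      apply(data, 2, sample)
    }
    mu <- colMeans(x)
    sdev <- sqrt(colMeans(sweep(x, 2, mu)^2))
    keep <- sdev > 1e-12
    z <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2,
               sdev[keep], `/`)
    lambda <- svd(scale(z, center = TRUE, scale = FALSE), nu = 0, nv = 0)$d^2
    pv <- 100 * lambda / sum(lambda)
    contrib[b, ] <- pv[seq_len(n_components)]
  }
  summ <- data.frame(component = seq_len(n_components),
                     mean = colMeans(contrib),
                     sd = apply(contrib, 2, sd),
                     max = apply(contrib, 2, max))
  signif <- NULL
  if (!is.null(observed)) {
    kk <- min(length(observed), n_components)
    signif <- vapply(seq_len(kk), function(k)
      (sum(contrib[, 1] >= observed[k]) + 1) / (reps + 1), numeric(1))
  }
  structure(list(replicate_contributions = contrib, summary = summ,
                 significance = signif, reps = reps, seed = seed,
                 null = null),
            class = "parallel_analysis")
}

#' Euclidean distances between population PC scores
#'
#' @param result a `pca_result`.
#' @param k number of leading components used.
#' @return Labeled distance matrix of kind `"pc_score"`.
#' @export
pc_score_distances <- function(result, k = 2) {
  if (k > ncol(result$scores)) stop("k exceeds available components")
  s <- result$scores[, seq_len(k), drop = FALSE]
  m <- as.matrix(dist(s))
  dist_matrix(m, kind = "pc_score")
}

#' Write PCA scores, loadings and the contribution report
#' @param result a `pca_result`.
#' @param dir output directory.
#' @param prefix filename prefix.
#' @return Character vector of paths, invisibly.
#' @export
write_pca_report <- function(result, dir, prefix = "pca") {
  p1 <- file.path(dir, paste0(prefix, "_scores.csv"))
  p2 <- file.path(dir, paste0(prefix, "_loadings.csv"))
  p3 <- file.path(dir, paste0(prefix, "_contributions.csv"))
  write.csv(data.frame(population = rownames(result$scores),
                       result$scores, check.names = FALSE), p1,
            row.names = FALSE)
  write.csv(data.frame(variable = rownames(result$loadings),
                       result$loadings, check.names = FALSE), p2,
            row.names = FALSE)
  write.csv(data.frame(component = seq_along(result$percent_variance),
                       percent_variance = result$percent_variance), p3,
            row.names = FALSE)
  invisible(c(p1, p2, p3))
}
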