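# ---------------------------------------------------------------------------
# Model-based admixture clustering (Gibbs sampler), lnPr(X|K) estimation,
# K selection, and CLUMPP-style alignment of runs.

#' Fit the admixture model by Gibbs sampling
#'
#' Each individual's genome is modeled as a mixture over K clusters with
#' membership vector Q; each gene copy's cluster of origin and the
#' cluster allele frequencies P are sampled by Gibbs updates. Under the
#' correlated-frequencies prior (F-model), cluster frequencies are drawn
#' around shared ancestral frequencies (fixed here at the pooled empirical
#' frequencies) with a per-cluster drift parameter F_k updated by
#' Metropolis steps. The Dirichlet concentration `alpha` of Q is sampled
#' with a uniform(0, 10) prior. Missing genotypes contribute no
#' likelihood terms.
#'
#' @param ds an [str_dataset()] with at least one polymorphic locus.
#' @param K number of clusters (>= 1).
#' @param burn_in,run_length discarded and recorded sweeps.
#' @param seed integer seed.
#' @param correlated_frequencies use the F-model prior (default TRUE);
#'   otherwise a flat Dirichlet(`lambda`) prior.
#' @param lambda Dirichlet parameter of the uncorrelated prior.
#' @param alpha initial admixture concentration.
#' @param sample_alpha update alpha by Metropolis (default TRUE).
#' @return Object of class `admixture_result`: `Q` (individual x K,
#'   posterior means, rows sum to 1), `P` (per-locus list of K x alleles
#'   frequency matrices), `loglik_trace`, `lnP` (via [estimate_lnP()]),
#'   `mean_membership` (population x K), `K`, `seed`.
#' @export
fit_admixture <- function(ds, K, burn_in = 2000, run_length = 2000,
                          seed = 1, correlated_frequencies = TRUE,
                          lambda = 1.0, alpha = 1.0, sample_alpha = TRUE) {
  if (K < 1) stop("K must be >= 1")
  enc <- encode_genotypes(ds)
  if (all(enc$n_alleles < 2L)) stop("no polymorphic locus")
  n <- nrow(enc$geno)
  if (K == 1L) {
    ll <- loglik_k1(enc)
    res <- list(Q = matrix(1, n, 1), P = matrix(enc$p_anc, 1),
                loglik_trace = rep(ll, run_length))
  } else {
    set.seed(seed)
    res <- admixture_gibbs(enc$geno, enc$n_alleles, enc$p_anc,
                           enc$offsets, as.integer(K),
                           as.integer(burn_in), as.integer(run_length),
                           correlated_frequencies, lambda, alpha,
                           sample_alpha)
  }
  Q <- res$Q / rowSums(res$Q)
  rownames(Q) <- ds$ind$id
  P <- split_P(res$P, enc)
  mm <- rowsum(Q, ds$ind$population)
  mm <- mm / rowSums(mm)
  mm <- mm[populations(ds), , drop = FALSE]
  structure(list(Q = Q, P = P, loglik_trace = res$loglik_trace,
                 lnP = estimate_lnP(res$loglik_trace),
                 mean_membership = mm, K = K, seed = seed,
                 populations = populations(ds)),
            class = "admixture_result")
}

encode_genotypes <- function(ds) {
  L <- length(ds$loci)
  n <- nrow(ds$alleles)
  geno <- matrix(-1L, n, 2L * L)
  n_alleles <- integer(L)
  offsets <- integer(L)
  labels <- vector("list", L)
  p_anc <- numeric(0)
  off <- 0L
  for (l in seq_len(L)) {
    cols <- c(2L * l - 1L, 2L * l)
    obs <- ds$alleles[, cols]
    al <- sort(unique(as.vector(obs[!is.na(obs)])))
    labels[[l]] <- al
    n_alleles[l] <- length(al)
    offsets[l] <- off
    idx <- match(obs, al) - 1L
    idx[is.na(idx)] <- -1L
    geno[, cols] <- idx
    cnt <- tabulate(match(as.vector(obs[!is.na(obs)]), al),
                    nbins = length(al))
    p_anc <- c(p_anc, cnt / max(sum(cnt), 1L))
    off <- off + length(al)
  }
  list(geno = geno, n_alleles = n_alleles, offsets = offsets,
       labels = labels, p_anc = p_anc, loci = ds$loci)
}

split_P <- function(Pflat, enc) {
  out <- vector("list", length(enc$loci))
  names(out) <- enc$loci
  for (l in seq_along(enc$loci)) {
    cols <- enc$offsets[l] + seq_len(enc$n_alleles[l])
    m <- Pflat[, cols, drop = FALSE]
    m <- m / rowSums(m)
    colnames(m) <- enc$labels[[l]]
    out[[l]] <- m
  }
  out
}


loglik_k1 <- function(enc) {
  ll <- 0
  for (l in seq_along(enc$loci)) {
    cols <- c(2L * l - 1L, 2L * l)
    a <- as.vector(enc$geno[, cols])
    a <- a[a >= 0L]
    p <- enc$p_anc[enc$offsets[l] + a + 1L]
    ll <- ll + sum(log(pmax(p, 1e-300)))
  }
  ll
}

#' @export
print.admixture_result <- function(x, ...) {
  cat(sprintf("admixture_result: K = %d, %d individuals, lnP = %.1f\n",
              x$K, nrow(x$Q), x$lnP))
  invisible(x)
}

#' Estimate lnPr(X|K) from a log-likelihood trace
#'
#' `mean(trace) - var(trace) / 2`, the standard model-probability
#' estimator applied to the recorded data log-likelihoods.
#'
#' @param trace numeric vector, length >= 2 (a constant trace of length
#'   1+ returns its value).
#' @return Scalar lnPr(X|K) estimate.
#' @export
estimate_lnP <- function(trace) {
  if (length(trace) < 2L) return(trace[1])
  mean(trace) - var(trace) / 2
}

#' Choose the number of clusters from per-K run batches
#'
#' Summarizes lnPr(X|K) over runs for each K and picks the smallest K
#' whose median lies within one median absolute deviation (of the runs at
#' the maximizing K) of the maximum median; ties therefore break toward
#' smaller K.
#'
#' @param results named list: one element per K, each a list of
#'   `admixture_result` runs.
#' @return List with `K` (chosen), `summary` (data.frame of per-K median,
#'   IQR and run count).
#' @export
select_K <- function(results) {
  if (length(results) == 0L) stop("no results supplied")
  Ks <- vapply(results, function(rs) rs[[1]]$K, numeric(1))
  med <- vapply(results, function(rs)
    median(vapply(rs, function(r) r$lnP, numeric(1))), numeric(1))
  spread <- vapply(results, function(rs) {
    v <- vapply(rs, function(r) r$lnP, numeric(1))
    if (length(v) < 2) 0 else mad(v)
  }, numeric(1))
  best <- which.max(med)
  tolerance <- spread[best]
  ok <- med >= med[best] - tolerance
  chosen <- min(Ks[ok])
  list(K = chosen,
       summary = data.frame(K = Ks, median_lnP = med, mad_lnP = spread,
                            runs = vapply(results, length, integer(1)),
                            row.names = NULL))
}

#' Align admixture runs by greedy cluster-label matching
#'
#' Cluster labels are arbitrary per run; this permutes each run's Q (and
#' P, mean membership) columns to maximize, greedily, the summed
#' correlation with the first run's Q columns.
#'
#' @param results list of `admixture_result`s with identical K and
#'   individuals.
#' @return List of aligned `admixture_result`s (first run unchanged).
#' @export
align_runs <- function(results) {
  if (length(results) < 2L) return(results)
  K <- results[[1]]$K
  for (r in results) if (r$K != K) stop("runs have different K")
  ref <- results[[1]]$Q
  out <- results
  for (j in seq_along(results)[-1]) {
    Q <- results[[j]]$Q
    if (nrow(Q) != nrow(ref)) stop("runs have different individuals")
    cc <- suppressWarnings(cor(ref, Q))
    cc[is.na(cc)] <- 0
    perm <- integer(K)
    for (step in seq_len(K)) {
      idx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      perm[idx[1]] <- idx[2]
      cc[idx[1], ] <- -Inf
      cc[, idx[2]] <- -Inf
    }
    out[[j]] <- permute_result(results[[j]], perm)
  }
  out
}

permute_result <- function(res, perm) {
  res$Q <- res$Q[, perm, drop = FALSE]
  res$mean_membership <- res$mean_membership[, perm, drop = FALSE]
  res$P <- lapply(res$P, function(m) m[perm, , drop = FALSE])
  res
}

#' Pairwise similarity of two membership matrices
#'
#' Mean over individuals of 1 minus half the L1 distance between Q rows;
#' 1 for identical matrices.
#'
#' @param q1,q2 individual x K membership matrices.
#' @return Scalar in [0, 1].
#' @export
membership_similarity <- function(q1, q2) {
  1 - mean(rowSums(abs(q1 - q2))) / 2
}

#' Write admixture results in columnar text form
#' @param res an `admixture_result`.
#' @param ds the [str_dataset()] it was fitted on.
#' @param path output path for the per-individual Q table.
#' @param mean_path optional path for the per-population mean membership
#'   CSV.
#' @return `path`, invisibly.
#' @export
write_q_matrix <- function(res, ds, path, mean_path = NULL) {
  df <- data.frame(individual = ds$ind$id, population = ds$ind$population,
                   res$Q, check.names = FALSE)
  names(df)[-(1:2)] <- paste0("Q", seq_len(res$K))
  write.table(df, path, row.names = FALSE, quote = FALSE, sep = "\t")
  if (!is.null(mean_path)) {
    mm <- data.frame(population = rownames(res$mean_membership),
                     res$mean_membership, check.names = FALSE)
    names(mm)[-1] <- paste0("Q", seq_len(res$K))
    write.csv(mm, mean_path, row.names = FALSE)
  }
  invisible(path)
}
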