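# ---------------------------------------------------------------------------
# Population-pair genetic distances from allele frequencies
#
# D_A  = 1 - (1/r) sum_j sum_i sqrt(x_ij y_ij)
# D_C  = (2 / (pi r)) sum_j sqrt(2 (1 - sum_i sqrt(x_ij y_ij)))
#
# The Bhattacharyya affinity sum_i sqrt(x y) is taken over the union of
# alleles observed in the two populations; an allele absent from one side
# contributes 0.

bhattacharyya <- function(x, y) {
  alleles <- union(names(x), names(y))
  xv <- ifelse(alleles %in% names(x), x[alleles], 0)
  yv <- ifelse(alleles %in% names(y), y[alleles], 0)
  sum(sqrt(xv * yv))
}

pair_affinities <- function(fx, fy, loci) {
  vapply(loci, function(l) {
    x <- fx[[l]]; y <- fy[[l]]
    if (is.null(x) || is.null(y))
      stop("no frequency vector at locus ", l)
    bhattacharyya(x, y)
  }, numeric(1))
}

#' Nei's DA distance between two populations
#'
#' `1 - mean over loci of the Bhattacharyya affinity`; 0 for identical
#' frequency arrays, 1 when the two populations share no alleles at any
#' locus used.
#'
#' @param fx,fy per-locus frequency-vector lists (named numeric vectors,
#'   names = allele labels), e.g. `ft$freq[[pop]]`.
#' @param loci character vector of loci to use (default: loci present in
#'   both populations).
#' @return DA in [0, 1].
#' @export
da_distance <- function(fx, fy, loci = NULL) {
  if (is.null(loci)) loci <- intersect(names(fx), names(fy))
  if (length(loci) == 0L) stop("no shared loci")
  aff <- pair_affinities(fx, fy, loci)
  max(1 - mean(aff), 0)
}

#' Cavalli-Sforza & Edwards chord distance between two populations
#'
#' `(2 / (pi r)) * sum_j sqrt(2 (1 - affinity_j))` with r the number of
#' loci; for a single locus with disjoint allele sets the value is
#' `(2/pi) sqrt(2)`.
#'
#' @inheritParams da_distance
#' @return Nonnegative chord distance.
#' @export
dc_distance <- function(fx, fy, loci = NULL) {
  if (is.null(loci)) loci <- intersect(names(fx), names(fy))
  if (length(loci) == 0L) stop("no shared loci")
  aff <- pair_affinities(fx, fy, loci)
  2 / (pi * length(loci)) * sum(sqrt(2 * pmax(1 - aff, 0)))
}

#' Pairwise genetic distance matrix
#'
#' @param ft a `freq_table`.
#' @param measure `"DA"` or `"DC"`.
#' @param loci locus subset (default: all loci of the table). Every
#'   requested locus must be present in every population.
#' @return Labeled symmetric matrix with zero diagonal; attribute `kind`
#'   records the measure.
#' @export
pairwise_matrix <- function(ft, measure = c("DA", "DC"), loci = NULL) {
  measure <- match.arg(measure)
  if (is.null(loci)) loci <- ft$loci
  for (p in ft$populations) {
    absent <- setdiff(loci, names(ft$freq[[p]]))
    if (length(absent))
      stop("population ", p, " lacks frequencies at: ",
           paste(absent, collapse = ", "))
  }
  fun <- if (measure == "DA") da_distance else dc_distance
  pops <- ft$populations
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_len(i - 1L)) {
    d <- fun(ft$freq[[pops[i]]], ft$freq[[pops[j]]], loci)
    m[i, j] <- d; m[j, i] <- d
  }
  dist_matrix(m, kind = measure)
}

#' Label a symmetric matrix as a distance matrix
#'
#' Validates symmetry, zero diagonal and nonnegativity and records the
#' matrix kind (`"DA"`, `"DC"`, `"geographic"`, `"linguistic"`,
#' `"pc_score"`, ...).
#'
#' @param m labeled square numeric matrix.
#' @param kind character tag.
#' @return The matrix with attribute `kind`.
#' @export
dist_matrix <- function(m, kind = "distance") {
  m <- as.matrix(m)
  if (is.null(rownames(m))) stop("distance matrix needs labels")
  if (max(abs(m - t(m))) > 1e-12) stop("matrix is not symmetric")
  if (any(diag(m) != 0)) stop("diagonal must be exactly 0")
  if (any(m < 0)) stop("distances must be nonnegative")
  attr(m, "kind") <- kind
  m
}

#' Bootstrap-over-loci resampling of a distance matrix
#'
#' Each replicate resamples the locus set with replacement and recomputes
#' the locus-averaged distance matrix, quantifying the sensitivity of the
#' matrix (and any tree built from it) to locus sampling.
#'
#' @param ft a `freq_table` with at least 2 loci.
#' @param measure `"DA"` or `"DC"`.
#' @param B number of replicates.
#' @param seed integer seed (resampling is reproducible given the seed).
#' @return List of class `bootstrap_set`: `replicates` (list of distance
#'   matrices), `resampled_loci` (list of locus vectors), `seed`, `B`.
#' @export
bootstrap_over_loci <- function(ft, measure = c("DA", "DC"), B = 1000,
                                seed = 1) {
  measure <- match.arg(measure)
  if (B < 1) stop("B must be >= 1")
  r <- length(ft$loci)
  set.seed(seed)
  resampled <- lapply(seq_len(B), function(b)
    ft$loci[sample.int(r, r, replace = TRUE)])
  reps <- lapply(resampled, function(loci)
    pairwise_matrix(ft, measure, loci = loci))
  structure(list(replicates = reps, resampled_loci = resampled,
                 seed = seed, B = B, measure = measure),
            class = "bootstrap_set")
}

# ---------------------------------------------------------------------------
# Interchange formats

#' Write a distance matrix in PHYLIP square format
#' @param m labeled distance matrix.
#' @param path output path.
#' @param digits significant digits written.
#' @return `path`, invisibly.
#' @export
write_phylip_matrix <- function(m, path, digits = 6) {
  labels <- rownames(m)
  lines <- c(sprintf("%5d", nrow(m)),
             vapply(seq_len(nrow(m)), function(i)
               paste(formatC(labels[i], width = -12),
                     paste(formatC(m[i, ], digits = digits, format = "g"),
                           collapse = " ")), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#' @param path file path.
#' @param kind matrix kind tag.
#' @return Labeled distance matrix.
#' @export
read_phylip_matrix <- function(path, kind = "distance") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1]))
  fields <- strsplit(trimws(lines[-1]), "[ \t]+")
  if (length(fields) != n) stop("expected ", n, " matrix rows")
  labels <- vapply(fields, `[[`, character(1), 1L)
  m <- t(vapply(fields, function(f) as.numeric(f[-1]), numeric(n)))
  dimnames(m) <- list(labels, labels)
  m <- (m + t(m)) / 2            # absorb formatting round-off
  diag(m) <- 0
  dist_matrix(m, kind = kind)
}

#' Write distances in long CSV format
#' @param m labeled distance matrix.
#' @param path output path.
#' @param locus_set description of the locus set used.
#' @return `path`, invisibly.
#' @export
write_dist_long <- function(m, path, locus_set = "all") {
  labs <- rownames(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  df <- data.frame(pop1 = labs[idx[, 1]], pop2 = labs[idx[, 2]],
                   locus_set = locus_set,
                   measure = attr(m, "kind") %||% "distance",
                   value = m[idx])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
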