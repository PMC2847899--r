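# Small in-code fixtures shared across test files.

# two individuals, one locus: one typed genotype, one missing
toy_structure_file <- function(path = tempfile(fileext = ".str")) {
  writeLines(c("LOC1",
               "ind1 popA 150 152",
               "ind2 popA -9 -9"), path)
  path
}

# hand-built dataset: 2 populations x 2 loci
toy_dataset <- function() {
  ind <- data.frame(id = sprintf("i%d", 1:6),
                    population = rep(c("popA", "popB"), each = 3))
  alleles <- rbind(
    c(150L, 150L, 200L, 202L),
    c(150L, 152L, 200L, 200L),
    c(152L, 152L, NA, NA),
    c(150L, 150L, 204L, 204L),
    c(150L, 150L, 204L, 202L),
    c(150L, 152L, 202L, 202L))
  str_dataset(ind, c("LOC1", "LOC2"), alleles)
}

# frequency lists for distance closed forms
freqs_single_locus <- function(p, locus = "L1") {
  out <- list(p)
  names(out) <- locus
  out
}

# brute-force least-squares tree oracle: enumerate every unrooted
# topology on the given labels, fit branch lengths by ordinary least
# squares on path indicators, and return all topologies achieving
# (near-)zero residual against the distance matrix
enumerate_topologies <- function(labels) {
  # sequential taxon insertion on every edge of every partial tree;
  # tips are 1..n, internal nodes numbered above n
  n <- length(labels)
  trees <- list(list(edge = cbind(n + 1L, c(1L, 2L, 3L))))
  if (n < 4L) return(trees)
  for (tip in 4:n) {
    new_trees <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edge))) {
        edge <- tr$edge
        a <- edge[e, 1]; b <- edge[e, 2]
        v <- max(c(edge)) + 1L
        new_edge <- rbind(edge[-e, , drop = FALSE],
                          c(a, v), c(v, b), c(v, tip))
        new_trees[[length(new_trees) + 1L]] <- list(edge = new_edge)
      }
    }
    trees <- new_trees
  }
  trees
}

# path-incidence least squares fit of a topology to a distance matrix;
# returns max abs residual (and the fitted lengths)
ls_fit_topology <- function(edge, d) {
  n <- nrow(d)
  nodes <- sort(unique(c(edge)))
  adj <- lapply(seq_len(max(nodes)), function(i) integer(0))
  for (e in seq_len(nrow(edge))) {
    a <- edge[e, 1]; b <- edge[e, 2]
    adj[[a]] <- c(adj[[a]], e); adj[[b]] <- c(adj[[b]], e)
  }
  other_end <- function(e, v) if (edge[e, 1] == v) edge[e, 2] else edge[e, 1]
  # paths between tips by DFS
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  A <- matrix(0, nrow(pairs), nrow(edge))
  for (r in seq_len(nrow(pairs))) {
    from <- pairs[r, 1]; to <- pairs[r, 2]
    # DFS
    stack <- list(list(v = from, path = integer(0), prev = 0L))
    while (length(stack)) {
      s <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (s$v == to) { A[r, s$path] <- 1; break }
      for (e in adj[[s$v]]) {
        w <- other_end(e, s$v)
        if (w != s$prev)
          stack[[length(stack) + 1L]] <- list(v = w,
                                              path = c(s$path, e),
                                              prev = s$v)
      }
    }
  }
  y <- d[upper.tri(d)]
  fit <- qr.solve(crossprod(A), crossprod(A, y))
  resid <- A %*% fit - y
  list(max_resid = max(abs(resid)), lengths = fit)
}

# tip-to-tip path-length matrix of a phylo tree
coph <- function(tree) {
  n <- length(tree$tip.label)
  m <- ape::dist.nodes(tree)[seq_len(n), seq_len(n)]
  dimnames(m) <- list(tree$tip.label, tree$tip.label)
  m
}

# additive distance matrix from a random unrooted binary tree (ape)
random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.5, 2)
  list(tree = tr, d = coph(tr))
}

# unordered bipartition set of a phylo tree (via the package's own
# canonicalization)
split_set <- function(tree) {
  sort(msatpop:::tree_bipartitions(tree, sort(tree$tip.label)))
}

# random labeled distance matrix from scattered points (Mantel tests)
random_point_matrix <- function(n, seed, labels = as.character(seq_len(n))) {
  set.seed(seed)
  m <- as.matrix(stats::dist(matrix(stats::rnorm(2 * n), n)))
  dimnames(m) <- list(labels, labels)
  dist_matrix(m)
}

# genotype count table from simulated HWE draws
simulated_genotype_table <- function(p, n) {
  k <- length(p)
  a1 <- sample.int(k, n, TRUE, p)
  a2 <- sample.int(k, n, TRUE, p)
  tab <- matrix(0L, k, k)
  for (g in seq_len(n)) {
    i <- min(a1[g], a2[g]); j <- max(a1[g], a2[g])
    tab[i, j] <- tab[i, j] + 1L
  }
  tab
}

# align two named frequency vectors on the union of their alleles
merge_freq <- function(x, y) {
  al <- sort(unique(c(names(x), names(y))))
  xs <- setNames(rep(0, length(al)), al); xs[names(x)] <- x
  ys <- setNames(rep(0, length(al)), al); ys[names(y)] <- y
  list(x = xs, y = ys)
}
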