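# ---------------------------------------------------------------------------
# Neighbor-joining, bootstrap bipartition support, majority-rule consensus.
#
# Trees are ape "phylo" objects, kept unrooted (basal trifurcation).
# Support values are stored as node labels (percent, internal nodes only).

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: repeatedly join the pair minimizing the
#' Q-criterion, with ties broken deterministically toward the lowest
#' (row, column) index pair. Branch lengths follow the standard NJ length
#' formulas and may be negative; see `clamp` in [write_newick()] for
#' display. For an additive (tree-metric) input the unique generating
#' topology is recovered exactly.
#'
#' @param m labeled symmetric distance matrix, >= 3 taxa.
#' @return Unrooted `phylo` tree with a basal trifurcation.
#' @export
neighbor_joining <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) stop("distance matrix needs labels")
  if (max(abs(m - t(m))) > 1e-9) stop("distance matrix must be symmetric")
  n_tip <- nrow(m)
  if (n_tip < 3L) stop("need at least 3 taxa")
  labels <- rownames(m)

  # active node ids: 1..n_tip are tips, internals numbered upward
  active <- seq_len(n_tip)
  next_id <- n_tip + 1L
  d <- m
  edges <- matrix(integer(0), 0, 2)
  lens <- numeric(0)

  while (length(active) > 3L) {
    n <- length(active)
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    # deterministic tie-break: lowest (row, col) with row < col
    qmin <- min(q)
    cand <- which(q <= qmin + 0, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- d[i, j] - bi
    u <- next_id; next_id <- next_id + 1L
    edges <- rbind(edges, c(u, active[i]), c(u, active[j]))
    lens <- c(lens, bi, bj)
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    active <- c(active[keep], u)
  }

  # final 3-way join
  root <- next_id
  a <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  c3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  edges <- rbind(edges, c(root, active[1]), c(root, active[2]),
                 c(root, active[3]))
  lens <- c(lens, a, b, c3)

  renumber_phylo(edges, lens, labels, root)
}

# convert an edge list with arbitrary internal ids into a valid phylo
# object (root = ntip + 1, internals in preorder)
renumber_phylo <- function(edges, lens, labels, root) {
  n_tip <- length(labels)
  n_node <- nrow(edges) - n_tip + 1L
  children <- split(seq_len(nrow(edges)), edges[, 1])
  new_id <- integer(max(edges))
  new_id[root] <- n_tip + 1L
  counter <- n_tip + 1L
  edge_out <- matrix(0L, nrow(edges), 2)
  len_out <- numeric(nrow(edges))
  k <- 0L
  visit <- function(node) {
    for (e in children[[as.character(node)]]) {
      child <- edges[e, 2]
      if (child <= n_tip) new_id[child] <<- child
      else { counter <<- counter + 1L; new_id[child] <<- counter }
      k <<- k + 1L
      edge_out[k, ] <<- c(new_id[node], new_id[child])
      len_out[k] <<- lens[e]
      if (child > n_tip) visit(child)
    }
  }
  visit(root)
  structure(list(edge = edge_out, edge.length = len_out,
                 tip.label = labels, Nnode = n_node),
            class = "phylo", order = "cladewise")
}

# ---------------------------------------------------------------------------
# Bipartitions

# canonical string keys for the non-trivial leaf bipartitions of a tree;
# the side not containing the alphabetically first label is named, sorted
tree_bipartitions <- function(tree, leaf_universe = NULL) {
  tips <- tree$tip.label
  if (is.null(leaf_universe)) leaf_universe <- sort(tips)
  anchor <- leaf_universe[1]
  n_tip <- length(tips)
  desc <- descendant_tips(tree)
  internal <- setdiff(unique(tree$edge[, 2]), seq_len(n_tip))
  keys <- character(0)
  for (node in internal) {
    side <- tips[desc[[node]]]
    if (anchor %in% side) side <- setdiff(leaf_universe, side)
    if (length(side) < 2L || length(side) > length(leaf_universe) - 2L) next
    keys <- c(keys, paste(sort(side), collapse = "\r"))
  }
  unique(keys)
}

descendant_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  desc <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  children <- split(tree$edge[, 2], tree$edge[, 1])
  rec <- function(node) {
    if (node <= n_tip) return(node)
    out <- integer(0)
    for (ch in children[[as.character(node)]]) out <- c(out, rec(ch))
    desc[[node]] <<- out
    out
  }
  rec(n_tip + 1L)
  desc
}

#' Annotate a reference tree with bootstrap bipartition support
#'
#' Each internal edge of the reference tree is labeled with the percentage
#' of replicate trees containing the same leaf bipartition.
#'
#' @param reference a `phylo` tree.
#' @param boot list of `phylo` trees on the same leaf set.
#' @param threshold supports below this percentage are blanked in the node
#'   labels (the tree keeps its topology); default 0 shows all.
#' @return The reference tree with percent supports as `node.label`
#'   (`NA` for the basal node).
#' @export
bipartition_support <- function(reference, boot, threshold = 0) {
  universe <- sort(reference$tip.label)
  for (t in boot)
    if (!identical(sort(t$tip.label), universe))
      stop("replicate tree has a different leaf set")
  counts <- new.env(hash = TRUE)
  for (t in boot)
    for (key in tree_bipartitions(t, universe))
      assign(key, (get0(key, envir = counts) %||% 0) + 1, envir = counts)
  n_tip <- length(reference$tip.label)
  desc <- descendant_tips(reference)
  tips <- reference$tip.label
  anchor <- universe[1]
  node_lab <- rep(NA_character_, reference$Nnode)
  support <- rep(NA_real_, reference$Nnode)
  for (node in (n_tip + 1L):(n_tip + reference$Nnode)) {
    side <- tips[desc[[node]]]
    if (anchor %in% side) side <- setdiff(universe, side)
    if (length(side) < 2L || length(side) > length(universe) - 2L) next
    key <- paste(sort(side), collapse = "\r")
    pct <- 100 * (get0(key, envir = counts) %||% 0) / length(boot)
    support[node - n_tip] <- pct
    node_lab[node - n_tip] <-
      if (pct >= threshold) formatC(pct, format = "fg", digits = 3) else ""
  }
  reference$node.label <- node_lab
  attr(reference, "support") <- support
  reference
}

#' Majority-rule consensus tree
#'
#' Contains exactly the bipartitions occurring in more than half of the
#' input trees, annotated with their percent frequency; such splits are
#' pairwise compatible by construction.
#'
#' @param trees nonempty list of `phylo` trees on a shared leaf set.
#' @return A `phylo` tree with frequency labels on internal nodes.
#' @export
majority_rule_consensus <- function(trees) {
  if (length(trees) == 0L) stop("need at least one tree")
  universe <- sort(trees[[1]]$tip.label)
  for (t in trees)
    if (!identical(sort(t$tip.label), universe))
      stop("trees have different leaf sets")
  counts <- new.env(hash = TRUE)
  for (t in trees)
    for (key in tree_bipartitions(t, universe))
      assign(key, (get0(key, envir = counts) %||% 0) + 1, envir = counts)
  n <- length(trees)
  keys <- ls(counts)
  freq <- vapply(keys, function(k) get(k, envir = counts), numeric(1))
  keep <- keys[freq > n / 2]
  splits <- lapply(keep, function(k) strsplit(k, "\r", fixed = TRUE)[[1]])
  pct <- 100 * freq[match(keep, keys)] / n
  # laminar family -> nested newick
  ord <- order(-lengths(splits))
  splits <- splits[ord]; pct <- pct[ord]
  build <- function(members, avail) {
    # avail: indices of splits fully inside `members`, largest first
    parts <- list(); labs <- character(0)
    left <- members
    i <- 1
    while (i <= length(avail)) {
      s <- splits[[avail[i]]]
      if (all(s %in% left)) {
        sub_avail <- avail[vapply(avail, function(a)
          a != avail[i] && all(splits[[a]] %in% s), logical(1))]
        parts[[length(parts) + 1L]] <-
          paste0(build(s, sub_avail),
                 sprintf("%s", formatC(pct[avail[i]], format = "fg",
                                       digits = 3)))
        left <- setdiff(left, s)
      }
      i <- i + 1
    }
    parts <- c(parts, as.list(left))
    paste0("(", paste(unlist(parts), collapse = ","), ")")
  }
  nwk <- paste0(build(universe, seq_along(splits)), ";")
  ape::read.tree(text = nwk)
}

# ---------------------------------------------------------------------------
# Newick I/O (thin wrappers over ape)

#' Write a tree in Newick format
#' @param tree a `phylo` object.
#' @param path output path (if `NULL`, the Newick string is returned).
#' @param clamp_negative set negative branch lengths to 0 for display.
#' @return The path (or Newick string) invisibly.
#' @export
write_newick <- function(tree, path = NULL, clamp_negative = FALSE) {
  if (clamp_negative && !is.null(tree$edge.length))
    tree$edge.length <- pmax(tree$edge.length, 0)
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read a Newick tree
#' @param path file path or connection.
#' @return A `phylo` object (internal-node labels preserved as support).
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Neighbor-joining trees for every replicate of a bootstrap set
#' @param boot a `bootstrap_set` from [bootstrap_over_loci()].
#' @return List of `phylo` trees.
#' @export
bootstrap_trees <- function(boot) lapply(boot$replicates, neighbor_joining)
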