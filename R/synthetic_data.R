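# ---------------------------------------------------------------------------
# Synthetic STR panel generator (F-model)
#
# Emulates the statistical structure of a multi-population microsatellite
# survey: ancestral allele frequencies per locus, hierarchical drift along
# a population tree (Dirichlet F-model), HWE or inbred genotype sampling,
# and a configurable missingness design.  Defaults reproduce the study
# design the package's analyses are calibrated against: 30 populations,
# sample sizes 37-95 with median 50 (1,538 individuals), 10 multiallelic
# loci with expected heterozygosity ~0.6-0.9, and 5 population-locus
# cells with >60% missingness concentrated in 4 populations and 2 loci.

rdirichlet <- function(n, shape) {
  x <- matrix(rgamma(n * length(shape), shape = shape), n, byrow = TRUE)
  x / rowSums(x)
}

#' Default generator truth for a study-like panel
#'
#' @param n_pops number of populations.
#' @param n_loci number of loci.
#' @param groups number of top-level clades in the population tree.
#' @param F_between drift from the ancestral pool to each clade.
#' @param F_within drift from a clade to each population.
#' @param seed integer seed (used for ancestral frequency draws).
#' @param allele_range number of alleles per locus is drawn uniformly
#'   from this range.
#' @param dirichlet_shape symmetric Dirichlet parameter of the ancestral
#'   frequencies; the default 2 puts per-locus expected heterozygosity
#'   in roughly 0.6-0.9 for 5-12 alleles after drift.
#' @return List of class `generator_truth` with the tree (group labels),
#'   drift parameters, ancestral frequencies and allele labels.
#' @export
generator_truth <- function(n_pops = 30, n_loci = 10, groups = 3,
                            F_between = 0.08, F_within = 0.05, seed = 1,
                            allele_range = c(5L, 12L),
                            dirichlet_shape = 2) {
  stopifnot(F_between > 0, F_between < 1, F_within > 0, F_within < 1)
  set.seed(seed)
  loci <- sprintf("L%02d", seq_len(n_loci))
  n_alleles <- sample(allele_range[1]:allele_range[2], n_loci,
                      replace = TRUE)
  ancestral <- lapply(seq_len(n_loci), function(l) {
    # allele labels are plausible fragment sizes: dinucleotide ladder
    f <- as.vector(rdirichlet(1, rep(dirichlet_shape, n_alleles[l])))
    names(f) <- as.character(120L + 30L * l + 2L * seq_len(n_alleles[l]))
    f
  })
  names(ancestral) <- loci
  pops <- sprintf("Pop%02d", seq_len(n_pops))
  group_of <- rep(sprintf("G%d", seq_len(groups)), length.out = n_pops)
  group_of <- sort(group_of)
  names(group_of) <- pops
  structure(list(populations = pops, loci = loci, group = group_of,
                 F_between = F_between, F_within = F_within,
                 ancestral = ancestral, seed = seed),
            class = "generator_truth")
}

#' Draw population allele frequencies under the hierarchical F-model
#'
#' Clade frequencies are drawn Dirichlet(ancestral * (1-F_between) /
#' F_between), then each population's frequencies Dirichlet(clade *
#' (1-F_within)/F_within): expected allele-frequency variance around p is
#' p(1-p)F at each level.
#'
#' @param truth a [generator_truth()].
#' @param seed integer seed.
#' @return List: `ft` (a `freq_table` whose n_genes are set to `Inf`
#'   surrogates until genotypes are drawn -- use the returned `freqs`
#'   for sampling), `freqs` (nested population -> locus -> named
#'   frequency vectors), `group_freqs`.
#' @export
generate_frequencies <- function(truth, seed = truth$seed) {
  set.seed(seed + 1L)
  groups <- unique(truth$group)
  draw_child <- function(parent, drift) {
    shape <- parent * (1 - drift) / drift
    f <- as.vector(rdirichlet(1, shape))
    names(f) <- names(parent)
    f
  }
  group_freqs <- lapply(groups, function(g)
    lapply(truth$ancestral, draw_child, drift = truth$F_between))
  names(group_freqs) <- groups
  freqs <- lapply(truth$populations, function(p)
    lapply(group_freqs[[truth$group[p]]], draw_child,
           drift = truth$F_within))
  names(freqs) <- truth$populations
  list(freqs = freqs, group_freqs = group_freqs, truth = truth)
}

#' Study-like sample sizes
#'
#' `n_pops` sizes between 37 and 95 with median 50; with 30 populations
#' the total is pinned to 1,538 individuals.
#'
#' @param n_pops number of populations.
#' @param seed integer seed.
#' @return Integer vector of sizes.
#' @export
study_sample_sizes <- function(n_pops = 30, seed = 1) {
  if (n_pops == 30L) {
    # deterministic design: min 37, max 95, median 50, total 1538
    sizes <- c(37L, 38L, 39L, 40L, 40L, 41L, 41L, 42L, 42L, 43L,
               43L, 44L, 45L, 45L, 50L, 50L, 51L, 52L, 53L, 54L,
               55L, 56L, 57L, 58L, 60L, 62L, 65L, 68L, 72L, 95L)
    stopifnot(sum(sizes) == 1538L, median(sizes) == 50)
    return(sizes)
  }
  set.seed(seed)
  pmin(pmax(round(rnorm(n_pops, 52, 12)), 37L), 95L)
}

#' Draw diploid genotypes from population allele frequencies
#'
#' With inbreeding coefficient `f_is = 0`, genotypes are exact HWE draws
#' (random union of gametes). With `f_is > 0`, a fraction `f_is` of
#' genotypes are autozygous: allele-pair probabilities are
#' `p_i^2 + p_i (1 - p_i) f_is` on the diagonal and
#' `2 p_i p_j (1 - f_is)` off it.
#'
#' @param freqs nested population -> locus -> named frequency vectors
#'   (e.g. `generate_frequencies(truth)$freqs`).
#' @param sizes named (or positional) per-population sample sizes.
#' @param f_is inbreeding coefficient in [0, 1).
#' @param seed integer seed.
#' @return An [str_dataset()].
#' @export
generate_genotypes <- function(freqs, sizes, f_is = 0, seed = 1) {
  if (f_is < 0 || f_is >= 1) stop("f_is must be in [0, 1)")
  if (any(sizes < 1)) stop("sizes must be >= 1")
  set.seed(seed + 2L)
  pops <- names(freqs)
  if (is.null(names(sizes))) names(sizes) <- pops
  loci <- names(freqs[[1]])
  ids <- character(0); popcol <- character(0)
  blocks <- list()
  for (p in pops) {
    n <- sizes[[p]]
    block <- matrix(NA_integer_, n, 2L * length(loci))
    for (l in seq_along(loci)) {
      f <- freqs[[p]][[loci[l]]]
      al <- as.integer(names(f))
      a1 <- al[sample.int(length(f), n, replace = TRUE, prob = f)]
      a2 <- al[sample.int(length(f), n, replace = TRUE, prob = f)]
      if (f_is > 0) {
        auto <- runif(n) < f_is
        a2[auto] <- a1[auto]
      }
      block[, 2L * l - 1L] <- a1
      block[, 2L * l] <- a2
    }
    blocks[[p]] <- block
    ids <- c(ids, sprintf("%s_%03d", p, seq_len(n)))
    popcol <- c(popcol, rep(p, n))
  }
  str_dataset(data.frame(id = ids, population = popcol,
                         stringsAsFactors = FALSE),
              loci, do.call(rbind, blocks))
}

#' Inject missing genotypes by a per-cell rate design
#'
#' @param ds an [str_dataset()].
#' @param design populations x loci matrix of missing rates in [0, 1]
#'   (dimnames must match), or a single rate applied everywhere.
#' @param seed integer seed.
#' @return The dataset with genotypes independently knocked out at the
#'   design rates.
#' @export
inject_missing <- function(ds, design, seed = 1) {
  if (length(design) == 1L) {
    design <- matrix(design, length(populations(ds)), length(ds$loci),
                     dimnames = list(populations(ds), ds$loci))
  }
  if (any(design < 0 | design > 1)) stop("rates must be in [0, 1]")
  set.seed(seed + 3L)
  al <- ds$alleles
  for (p in populations(ds)) {
    rows <- which(ds$ind$population == p)
    for (l in seq_along(ds$loci)) {
      rate <- design[p, ds$loci[l]]
      if (rate <= 0) next
      hit <- rows[runif(length(rows)) < rate]
      al[hit, c(2L * l - 1L, 2L * l)] <- NA_integer_
    }
  }
  str_dataset(ds$ind, ds$loci, al, ds$markers, ds$pop_meta)
}

#' Study-like missingness design
#'
#' Low background missingness everywhere, plus 5 population-locus cells
#' with rates above 60%, concentrated in 4 populations and 2 loci (one
#' population is bad at both loci) -- the pattern that makes the
#' tolerance-based subsetting drop exactly those populations from the
#' full-loci set and those loci from the full-population set.
#'
#' @param populations,loci label vectors.
#' @param background baseline missing rate.
#' @param bad_rate rate at the 5 bad cells.
#' @return Rate matrix usable with [inject_missing()].
#' @export
study_missing_design <- function(populations, loci, background = 0.05,
                                 bad_rate = 0.75) {
  if (length(populations) < 4L || length(loci) < 2L)
    stop("need >= 4 populations and >= 2 loci")
  design <- matrix(background, length(populations), length(loci),
                   dimnames = list(populations, loci))
  bad_pops <- populations[seq_len(4L)]
  bad_loci <- loci[c(2L, length(loci))]
  design[bad_pops[1], bad_loci[1]] <- bad_rate
  design[bad_pops[2], bad_loci[1]] <- bad_rate
  design[bad_pops[3], bad_loci[2]] <- bad_rate
  design[bad_pops[4], bad_loci[2]] <- bad_rate
  design[bad_pops[1], bad_loci[2]] <- bad_rate   # 5th bad cell
  design
}

#' Draw genotypes for admixed individuals
#'
#' Each gene copy's parental population is drawn from the individual's
#' row of `Q_truth`; the allele is then drawn from that parent's
#' frequencies.
#'
#' @param parents nested parent -> locus -> named frequency vectors (K
#'   parents).
#' @param Q_truth individuals x K matrix of true memberships, rows on the
#'   simplex.
#' @param seed integer seed.
#' @param population_labels optional per-individual population tags
#'   (default "Admixed").
#' @return List: `ds` (an [str_dataset()]) and `Q_truth`.
#' @export
generate_admixed <- function(parents, Q_truth, seed = 1,
                             population_labels = NULL) {
  K <- length(parents)
  Q_truth <- as.matrix(Q_truth)
  if (ncol(Q_truth) != K) stop("Q_truth columns must match parents")
  if (max(abs(rowSums(Q_truth) - 1)) > 1e-9)
    stop("Q_truth rows must sum to 1")
  set.seed(seed + 4L)
  n <- nrow(Q_truth)
  loci <- names(parents[[1]])
  al <- matrix(NA_integer_, n, 2L * length(loci))
  for (i in seq_len(n)) {
    for (l in seq_along(loci)) {
      for (c in 0:1) {
        k <- sample.int(K, 1, prob = Q_truth[i, ])
        f <- parents[[k]][[loci[l]]]
        al[i, 2L * l - 1L + c] <-
          as.integer(names(f))[sample.int(length(f), 1, prob = f)]
      }
    }
  }
  labs <- population_labels %||% rep("Admixed", n)
  ds <- str_dataset(data.frame(id = sprintf("adm_%03d", seq_len(n)),
                               population = labs,
                               stringsAsFactors = FALSE), loci, al)
  list(ds = ds, Q_truth = Q_truth)
}

#' Language tree for a synthetic panel
#'
#' Maps each generator clade to a language-group leaf hanging directly
#' off a 50,000-year root, so linguistic structure mirrors the genetic
#' clades (within-group distance 0, between-group the root age).
#'
#' @param truth a [generator_truth()].
#' @return A `language_tree`.
#' @export
synthetic_language_tree <- function(truth) {
  pops <- truth$populations
  paths <- lapply(pops, function(p) 1L)
  ages <- lapply(pops, function(p) 50000)
  names(paths) <- names(ages) <- pops
  structure(list(paths = paths, ages = ages,
                 leaf = truth$group[pops],
                 within_leaf_age = 0, root_age = 50000),
            class = "language_tree")
}

#' Generate the full study-like input bundle
#'
#' One call producing everything the pipeline consumes: genotypes with
#' the study-like missingness design, population metadata with synthetic
#' coordinates arranged so that geography mirrors the population tree,
#' and lineage labels pointing into the default language tree.
#'
#' @param seed integer seed.
#' @param n_pops,n_loci panel dimensions.
#' @param dir optional directory; when given, the bundle is written as
#'   `genotypes.str`, `populations.csv` and `truth.yaml`.
#' @return List: `ds` (dataset with metadata), `truth`, `freqs`, `paths`
#'   (when written).
#' @export
generate_study_fixture <- function(seed = 1, n_pops = 30, n_loci = 10,
                                   dir = NULL) {
  truth <- generator_truth(n_pops = n_pops, n_loci = n_loci, seed = seed)
  gf <- generate_frequencies(truth)
  sizes <- study_sample_sizes(n_pops, seed = seed)
  names(sizes) <- truth$populations
  ds <- generate_genotypes(gf$freqs, sizes, f_is = 0, seed = seed)
  design <- study_missing_design(truth$populations, truth$loci)
  ds <- inject_missing(ds, design, seed = seed)
  # synthetic coordinates: clades occupy distinct regions, populations
  # scatter within them
  set.seed(seed + 5L)
  groups <- unique(truth$group)
  centers <- data.frame(lat = seq(20, 45, length.out = length(groups)),
                        lon = seq(95, 115, length.out = length(groups)))
  pm <- data.frame(
    population = truth$populations,
    latitude = centers$lat[match(truth$group, groups)] +
      rnorm(n_pops, 0, 2),
    longitude = centers$lon[match(truth$group, groups)] +
      rnorm(n_pops, 0, 2),
    lineage = paste("Root", truth$group, truth$populations, sep = ";"),
    stringsAsFactors = FALSE)
  ds$pop_meta <- pm
  out <- list(ds = ds, truth = truth, freqs = gf$freqs, design = design,
              language_tree = synthetic_language_tree(truth))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p1 <- file.path(dir, "genotypes.str")
    p2 <- file.path(dir, "populations.csv")
    p3 <- file.path(dir, "truth.yaml")
    write_genotypes(ds, p1, "structure")
    write.csv(pm, p2, row.names = FALSE)
    yaml::write_yaml(list(seed = seed, n_pops = n_pops, n_loci = n_loci,
                          F_between = truth$F_between,
                          F_within = truth$F_within,
                          group = as.list(truth$group)), p3)
    out$paths <- c(genotypes = p1, populations = p2, truth = p3)
  }
  out
}
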