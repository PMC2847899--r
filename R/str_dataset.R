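#' @useDynLib msatpop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor sd var rnorm runif rbinom rbeta rgamma prcomp
#'   quantile median mad ks.test pnorm dist lm residuals setNames
#' @importFrom utils read.csv read.table write.csv write.table
NULL

# ---------------------------------------------------------------------------
# str_dataset: diploid microsatellite genotype panel
#
# Representation: individuals x (2 * n_loci) integer matrix of allele
# fragment sizes (bp), NA = missing.  A genotype is missing as a unit: a
# half-called genotype (one allele NA) is demoted to fully missing on
# construction, since a single failed gene copy comes from one failed
# reaction.

#' Construct a diploid STR genotype dataset
#'
#' Bundles genotype calls with individual, marker and population metadata.
#' Alleles are integer fragment sizes in base pairs; missing genotypes are
#' `NA` for both gene copies (a genotype with one missing allele is treated
#' as fully missing).
#'
#' @param ind data.frame with columns `id` and `population`; one row per
#'   individual.
#' @param loci character vector of locus names.
#' @param alleles integer matrix, `nrow(ind)` rows and `2 * length(loci)`
#'   columns (two adjacent columns per locus), `NA` for missing.
#' @param markers optional data.frame with columns `name`, `map_position`
#'   (cM) and `chromosome`, one row per locus.
#' @param pop_meta optional data.frame with columns `population`, `latitude`,
#'   `longitude`, `lineage` (semicolon-joined path through the language
#'   tree).
#' @return An object of class `str_dataset`.
#' @export
str_dataset <- function(ind, loci, alleles, markers = NULL, pop_meta = NULL) {
  stopifnot(is.data.frame(ind), all(c("id", "population") %in% names(ind)))
  loci <- as.character(loci)
  if (anyDuplicated(loci)) stop("locus names must be unique")
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (ncol(alleles) != 2L * length(loci))
    stop("allele matrix must have two columns per locus")
  if (nrow(alleles) != nrow(ind))
    stop("allele matrix rows must match individuals")
  if (any(alleles <= 0L, na.rm = TRUE))
    stop("allele fragment sizes must be positive integers")
  # demote half-missing genotypes to fully missing
  for (j in seq_along(loci)) {
    cols <- c(2L * j - 1L, 2L * j)
    bad <- xor(is.na(alleles[, cols[1]]), is.na(alleles[, cols[2]]))
    if (any(bad)) alleles[bad, cols] <- NA_integer_
  }
  colnames(alleles) <- paste0(rep(loci, each = 2L), c("_1", "_2"))
  if (!is.null(markers)) {
    stopifnot(all(c("name", "map_position") %in% names(markers)))
    if (any(markers$map_position < 0)) stop("map positions must be >= 0")
    if (anyDuplicated(markers$name)) stop("marker names must be unique")
  }
  if (!is.null(pop_meta)) validate_pop_meta(pop_meta)
  ind$id <- as.character(ind$id)
  ind$population <- as.character(ind$population)
  structure(list(ind = ind, loci = loci, alleles = alleles,
                 markers = markers, pop_meta = pop_meta),
            class = "str_dataset")
}

validate_pop_meta <- function(pm) {
  stopifnot(is.data.frame(pm), "population" %in% names(pm))
  if (!is.null(pm$latitude) &&
      any(pm$latitude < -90 | pm$latitude > 90, na.rm = TRUE))
    stop("latitude out of range [-90, 90]")
  if (!is.null(pm$longitude) &&
      any(pm$longitude < -180 | pm$longitude > 180, na.rm = TRUE))
    stop("longitude out of range [-180, 180]")
  invisible(pm)
}

#' @export
print.str_dataset <- function(x, ...) {
  cat("str_dataset:", nrow(x$ind), "individuals,",
      length(unique(x$ind$population)), "populations,",
      length(x$loci), "loci\n")
  mr <- mean(is.na(x$alleles[, seq(1, ncol(x$alleles), by = 2), drop = FALSE]))
  cat(sprintf("  overall missing genotype rate: %.3f\n", mr))
  invisible(x)
}

#' Population names of a dataset
#' @param ds `str_dataset`.
#' @return Character vector of population labels in order of first appearance.
#' @export
populations <- function(ds) unique(ds$ind$population)

#' Per-population sample sizes
#' @param ds `str_dataset`.
#' @return Named integer vector.
#' @export
sample_sizes <- function(ds) {
  tab <- table(ds$ind$population)
  out <- as.integer(tab[populations(ds)])
  names(out) <- populations(ds)
  out
}

# ---------------------------------------------------------------------------
# I/O

#' Read a genotype file
#'
#' Two dialects are supported. `"structure"` is whitespace-delimited text in
#' the one-row-per-individual convention of the STRUCTURE program: a header
#' row of locus names, then per individual an id column, a population column
#' and two adjacent allele columns per locus, missing coded `-9`. `"csv"` is
#' long format with columns `individual`, `population`, `locus`, `allele1`,
#' `allele2` (empty fields = missing).
#'
#' @param path file path.
#' @param dialect `"structure"` or `"csv"`.
#' @return An [str_dataset()].
#' @export
read_genotypes <- function(path, dialect = c("structure", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "structure") read_genotypes_structure(path)
  else read_genotypes_csv(path)
}

read_genotypes_structure <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("genotype file needs a header and data rows")
  loci <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  ncol_expected <- 2L + 2L * length(loci)
  n <- length(lines) - 1L
  ids <- character(n); pops <- character(n)
  alleles <- matrix(NA_integer_, n, 2L * length(loci))
  for (i in seq_len(n)) {
    fields <- strsplit(trimws(lines[i + 1L]), "[ \t]+")[[1]]
    if (length(fields) != ncol_expected)
      stop(sprintf("line %d: expected %d fields, found %d",
                   i + 1L, ncol_expected, length(fields)))
    ids[i] <- fields[1]; pops[i] <- fields[2]
    vals <- suppressWarnings(as.integer(fields[-(1:2)]))
    if (anyNA(vals))
      stop(sprintf("line %d: non-integer allele field", i + 1L))
    if (any(vals <= 0L & vals != -9L))
      stop(sprintf("line %d: unknown missing code %d", i + 1L,
                   vals[which(vals <= 0L & vals != -9L)[1]]))
    vals[vals == -9L] <- NA_integer_
    alleles[i, ] <- vals
  }
  str_dataset(data.frame(id = ids, population = pops,
                         stringsAsFactors = FALSE), loci, alleles)
}

read_genotypes_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(individual = "character",
                                population = "character",
                                locus = "character"))
  need <- c("individual", "population", "locus", "allele1", "allele2")
  if (!all(need %in% names(df)))
    stop("csv dialect requires columns: ", paste(need, collapse = ", "))
  to_int <- function(x) {
    x[x %in% c("", "NA")] <- NA
    v <- suppressWarnings(as.integer(x))
    if (any(is.na(v) & !is.na(x) & x != ""))
      stop("non-integer allele value in csv")
    v
  }
  df$allele1 <- to_int(as.character(df$allele1))
  df$allele2 <- to_int(as.character(df$allele2))
  loci <- unique(df$locus)
  key <- paste(df$individual, df$population, sep = "\r")
  ukey <- unique(key)
  ids <- sub("\r.*$", "", ukey)
  pops <- sub("^.*\r", "", ukey)
  alleles <- matrix(NA_integer_, length(ukey), 2L * length(loci))
  row_idx <- match(key, ukey)
  col_idx <- match(df$locus, loci)
  for (r in seq_len(nrow(df))) {
    alleles[row_idx[r], 2L * col_idx[r] - 1L] <- df$allele1[r]
    alleles[row_idx[r], 2L * col_idx[r]] <- df$allele2[r]
  }
  str_dataset(data.frame(id = ids, population = pops,
                         stringsAsFactors = FALSE), loci, alleles)
}

#' Write a genotype file
#'
#' Inverse of [read_genotypes()]; `read_genotypes(write_genotypes(ds))`
#' returns an identical dataset.
#'
#' @param ds an [str_dataset()].
#' @param path output path.
#' @param dialect `"structure"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(ds, path, dialect = c("structure", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "structure") {
    al <- ds$alleles
    al[is.na(al)] <- -9L
    lines <- c(paste(ds$loci, collapse = " "),
               vapply(seq_len(nrow(al)), function(i)
                 paste(c(ds$ind$id[i], ds$ind$population[i], al[i, ]),
                       collapse = " "), character(1)))
    writeLines(lines, path)
  } else {
    rows <- do.call(rbind, lapply(seq_along(ds$loci), function(j) {
      data.frame(individual = ds$ind$id, population = ds$ind$population,
                 locus = ds$loci[j],
                 allele1 = ds$alleles[, 2L * j - 1L],
                 allele2 = ds$alleles[, 2L * j],
                 stringsAsFactors = FALSE)
    }))
    ord <- order(match(rows$individual, ds$ind$id), match(rows$locus, ds$loci))
    write.csv(rows[ord, ], path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read population metadata
#'
#' CSV with columns `population`, `latitude`, `longitude`, `lineage`
#' (semicolon-joined node path from language phylum to population).
#'
#' @param path file path.
#' @return data.frame, validated.
#' @export
read_population_meta <- function(path) {
  pm <- read.csv(path, stringsAsFactors = FALSE)
  validate_pop_meta(pm)
  pm
}

# ---------------------------------------------------------------------------
# Missingness and subsetting

#' Per population-locus missing genotype rates
#'
#' @param ds an [str_dataset()].
#' @return Numeric matrix, populations x loci, each entry the fraction of
#'   the population's individuals with a missing genotype at that locus.
#' @export
missing_rates <- function(ds) {
  if (nrow(ds$ind) == 0L) stop("empty dataset")
  pops <- populations(ds)
  miss <- is.na(ds$alleles[, seq(1, ncol(ds$alleles), by = 2), drop = FALSE])
  out <- matrix(NA_real_, length(pops), length(ds$loci),
                dimnames = list(pops, ds$loci))
  for (p in pops) {
    rows <- ds$ind$population == p
    out[p, ] <- colMeans(miss[rows, , drop = FALSE])
  }
  out
}

subset_individuals <- function(ds, keep) {
  str_dataset(ds$ind[keep, , drop = FALSE], ds$loci,
              ds$alleles[keep, , drop = FALSE], ds$markers,
              ds$pop_meta)
}

#' Subset populations to a label set
#' @param ds an [str_dataset()].
#' @param pops population labels to keep.
#' @return An [str_dataset()] restricted to those populations.
#' @export
subset_populations <- function(ds, pops) {
  missing_pops <- setdiff(pops, populations(ds))
  if (length(missing_pops))
    stop("unknown populations: ", paste(missing_pops, collapse = ", "))
  pm <- ds$pop_meta
  if (!is.null(pm)) pm <- pm[pm$population %in% pops, , drop = FALSE]
  out <- subset_individuals(ds, ds$ind$population %in% pops)
  out$pop_meta <- pm
  out
}

#' Subset loci to a name set
#' @param ds an [str_dataset()].
#' @param loci locus names to keep.
#' @return An [str_dataset()] restricted to those loci.
#' @export
subset_loci <- function(ds, loci) {
  j <- match(loci, ds$loci)
  if (anyNA(j)) stop("unknown loci: ",
                     paste(loci[is.na(j)], collapse = ", "))
  cols <- as.vector(rbind(2L * j - 1L, 2L * j))
  mk <- ds$markers
  if (!is.null(mk)) mk <- mk[mk$name %in% loci, , drop = FALSE]
  str_dataset(ds$ind, ds$loci[j], ds$alleles[, cols, drop = FALSE],
              mk, ds$pop_meta)
}

#' Split a dataset by the missing-rate tolerance policy
#'
#' Multi-locus analyses need population-locus cells that are adequately
#' typed. Given a tolerance on the per-cell missing rate, this produces the
#' two standard working subsets: a *full-loci* dataset that keeps every
#' locus and drops each population with any locus above tolerance, and a
#' *full-population* dataset that keeps every population and drops each
#' locus above tolerance in any population.
#'
#' @param ds an [str_dataset()].
#' @param tolerance maximum acceptable missing-rate fraction, in (0, 1).
#' @return List with elements `full_loci` and `full_population`, both
#'   [str_dataset()]s, plus `dropped_populations` and `dropped_loci`.
#' @export
subset_by_missing_policy <- function(ds, tolerance = 0.40) {
  if (!(tolerance > 0 && tolerance < 1)) stop("tolerance must be in (0, 1)")
  mr <- missing_rates(ds)
  bad <- mr > tolerance
  drop_pops <- rownames(mr)[rowSums(bad) > 0L]
  drop_loci <- colnames(mr)[colSums(bad) > 0L]
  keep_pops <- setdiff(populations(ds), drop_pops)
  keep_loci <- setdiff(ds$loci, drop_loci)
  if (length(keep_pops) == 0L)
    stop("no population passes tolerance ", tolerance,
         "; raise the tolerance")
  if (length(keep_loci) == 0L)
    stop("no locus passes tolerance ", tolerance, "; raise the tolerance")
  list(full_loci = subset_populations(ds, keep_pops),
       full_population = subset_loci(ds, keep_loci),
       dropped_populations = drop_pops,
       dropped_loci = drop_loci)
}

# ---------------------------------------------------------------------------
# Allele frequencies

#' Per population-locus allele frequencies
#'
#' Frequencies are computed over successfully typed gene copies only.
#' A population with zero typed copies at a locus gets `NULL` (absent)
#' rather than a zero-filled vector.
#'
#' @param ds an [str_dataset()].
#' @return Object of class `freq_table`: list with `freq` (nested list
#'   `[[population]][[locus]]` of named frequency vectors, names = allele
#'   sizes), `n_genes` (populations x loci matrix of typed gene-copy
#'   counts), `populations`, `loci`, `sample_sizes`.
#' @export
allele_frequencies <- function(ds) {
  pops <- populations(ds)
  freq <- vector("list", length(pops)); names(freq) <- pops
  n_genes <- matrix(0L, length(pops), length(ds$loci),
                    dimnames = list(pops, ds$loci))
  for (p in pops) {
    rows <- ds$ind$population == p
    fl <- list()
    for (j in seq_along(ds$loci)) {
      g <- c(ds$alleles[rows, 2L * j - 1L], ds$alleles[rows, 2L * j])
      g <- g[!is.na(g)]
      if (length(g) == 0L) next  # absent vector: locus omitted entirely
      tab <- table(g)
      fl[[ds$loci[j]]] <- as.numeric(tab) / length(g)
      names(fl[[ds$loci[j]]]) <- names(tab)
      n_genes[p, j] <- length(g)
    }
    freq[[p]] <- fl
  }
  structure(list(freq = freq, n_genes = n_genes, populations = pops,
                 loci = ds$loci, sample_sizes = sample_sizes(ds)),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat("freq_table:", length(x$populations), "populations x",
      length(x$loci), "loci\n")
  invisible(x)
}

#' Build a frequency table directly from long-format data
#'
#' For workflows starting from published allele-frequency tables rather
#' than genotypes.
#'
#' @param df data.frame with columns `population`, `locus`, `allele`,
#'   `frequency`, `n_genes`.
#' @return A `freq_table`.
#' @export
freq_table_from_long <- function(df) {
  need <- c("population", "locus", "allele", "frequency", "n_genes")
  if (!all(need %in% names(df)))
    stop("need columns: ", paste(need, collapse = ", "))
  pops <- unique(df$population); loci <- unique(df$locus)
  freq <- lapply(pops, function(p) {
    sub <- df[df$population == p, , drop = FALSE]
    fl <- list()
    for (l in unique(sub$locus)) {
      s2 <- sub[sub$locus == l, , drop = FALSE]
      v <- s2$frequency; names(v) <- as.character(s2$allele)
      tot <- sum(v)
      if (abs(tot - 1) > 1e-6)
        stop(sprintf("frequencies for %s/%s sum to %.6f, not 1", p, l, tot))
      fl[[l]] <- v / tot
    }
    fl
  })
  names(freq) <- pops
  n_genes <- matrix(0L, length(pops), length(loci),
                    dimnames = list(pops, loci))
  for (r in seq_len(nrow(df)))
    n_genes[df$population[r], df$locus[r]] <- as.integer(df$n_genes[r])
  structure(list(freq = freq, n_genes = n_genes, populations = pops,
                 loci = loci, sample_sizes = NULL), class = "freq_table")
}

#' Write a frequency table as long-format CSV
#' @param ft a `freq_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_freq_table <- function(ft, path) {
  rows <- list()
  for (p in ft$populations) for (l in names(ft$freq[[p]])) {
    v <- ft$freq[[p]][[l]]
    rows[[length(rows) + 1L]] <- data.frame(
      population = p, locus = l, allele = as.integer(names(v)),
      frequency = as.numeric(v), n_genes = ft$n_genes[p, l],
      stringsAsFactors = FALSE)
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Restrict a frequency table to populations and/or loci
#' @param ft a `freq_table`.
#' @param populations,loci labels to keep (default: all).
#' @return A `freq_table`.
#' @export
subset_freq_table <- function(ft, populations = NULL, loci = NULL) {
  pops <- if (is.null(populations)) ft$populations else populations
  lcs <- if (is.null(loci)) ft$loci else loci
  stopifnot(all(pops %in% ft$populations), all(lcs %in% ft$loci))
  freq <- lapply(ft$freq[pops], function(fl) fl[intersect(lcs, names(fl))])
  structure(list(freq = freq,
                 n_genes = ft$n_genes[pops, lcs, drop = FALSE],
                 populations = pops, loci = lcs,
                 sample_sizes = ft$sample_sizes[pops]),
            class = "freq_table")
}
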