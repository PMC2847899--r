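# ---------------------------------------------------------------------------
# Orchestration: genotype file -> report bundle

#' Build an analysis configuration
#'
#' All tunables of the full workflow with their defaults; every stage's
#' seed is explicit so reruns are bit-identical.
#'
#' @param genotypes path to a genotype file, or an [str_dataset()].
#' @param dialect genotype file dialect (see [read_genotypes()]).
#' @param population_meta path to a population metadata CSV (or a
#'   data.frame); optional if the dataset already carries metadata.
#' @param language_tree path to a language-tree YAML, or a
#'   `language_tree` object (default: the shipped tree).
#' @param out_dir output directory.
#' @param tolerance missing-rate tolerance for subsetting.
#' @param measures genetic distance measures to compute.
#' @param bootstrap_B bootstrap-over-loci replicates.
#' @param permutations Mantel permutations.
#' @param pca_components components for PC-score distances.
#' @param parallel_reps parallel-analysis replicates.
#' @param K_range cluster counts for the admixture scan.
#' @param admixture_runs independent restarts per K.
#' @param burn_in,run_length admixture sweeps.
#' @param hwe_chain_steps,hwe_burn_in,hwe_max_enumeration exact-test
#'   settings passed to [hwe_exact_test()] by the HWE stage.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param stages character vector of stages to run (any of
#'   "diversity", "hwe", "distance", "tree", "pca", "admixture",
#'   "mantel").
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(genotypes, dialect = "structure",
                            population_meta = NULL, language_tree = NULL,
                            out_dir = "msatpop_results",
                            tolerance = 0.40, measures = c("DA", "DC"),
                            bootstrap_B = 1000, permutations = 5000,
                            pca_components = 2, parallel_reps = 10000,
                            K_range = 2:7, admixture_runs = 5,
                            burn_in = 2000, run_length = 2000,
                            hwe_chain_steps = 1e5, hwe_burn_in = 1e4,
                            hwe_max_enumeration = 2e4, seed = 1,
                            stages = c("diversity", "hwe", "distance",
                                       "tree", "pca", "admixture",
                                       "mantel")) {
  structure(as.list(environment()), class = "analysis_config")
}

stage_seed <- function(cfg, stage) {
  offsets <- c(diversity = 11L, hwe = 23L, distance = 37L, tree = 41L,
               pca = 53L, admixture = 67L, mantel = 79L)
  ((cfg$seed %% 1000000L) * 1000L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full analysis workflow
#'
#' Executes, in order: allele frequencies and H_E summaries; the HWE
#' scan; per-locus DA matrices with the inter-locus Mantel grid;
#' multilocus DA/DC matrices; NJ trees with bootstrap-over-loci supports
#' and the consensus of replicate trees; PCA with parallel analysis and
#' the PC-distance vs geography Mantel test; the admixture scan over K
#' with run alignment; and the genetic/geographic/linguistic Mantel table
#' with language-exclusion rows. Both the full-loci and full-population
#' subsets are produced and processed. All products are plain
#' CSV/Newick/YAML files under `cfg$out_dir`; a manifest records the
#' config, a config hash, per-stage seeds and timings.
#'
#' @param cfg an [analysis_config()].
#' @return Invisibly, a list with the in-memory products and the manifest.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()
  products <- list()
  tick <- function(stage, expr) {
    s <- Sys.time()
    v <- force(expr)
    timings[[stage]] <<- round(as.numeric(Sys.time() - s, units = "secs"),
                               3)
    v
  }

  ds <- if (inherits(cfg$genotypes, "str_dataset")) cfg$genotypes
        else read_genotypes(cfg$genotypes, cfg$dialect)
  pm <- cfg$population_meta
  if (is.character(pm)) pm <- read_population_meta(pm)
  if (is.null(pm)) pm <- ds$pop_meta
  ltree <- if (inherits(cfg$language_tree, "language_tree"))
             cfg$language_tree
           else if (is.null(cfg$language_tree)) default_language_tree()
           else read_language_tree(cfg$language_tree)

  subsets <- subset_by_missing_policy(ds, cfg$tolerance)
  products$subsets <- subsets
  out <- function(...) file.path(cfg$out_dir, paste0(...))

  for (sub_name in c("full_loci", "full_population")) {
    sub <- subsets[[sub_name]]
    ft <- allele_frequencies(sub)
    write_freq_table(ft, out(sub_name, "_frequencies.csv"))

    if ("diversity" %in% cfg$stages) {
      hs <- tick(paste0(sub_name, "/diversity"), heterozygosity_summary(ft))
      write.csv(hs$per_locus, out(sub_name, "_heterozygosity.csv"),
                row.names = FALSE)
      products[[sub_name]]$heterozygosity <- hs
    }

    if ("hwe" %in% cfg$stages) {
      hw <- tick(paste0(sub_name, "/hwe"),
                 hwe_scan(sub, seed = stage_seed(cfg, "hwe"),
                          chain_steps = cfg$hwe_chain_steps,
                          burn_in = cfg$hwe_burn_in,
                          max_enumeration = cfg$hwe_max_enumeration))
      write_hwe_report(hw, out(sub_name, "_hwe.csv"))
      products[[sub_name]]$hwe <- hw
    }

    if ("distance" %in% cfg$stages) {
      dm <- tick(paste0(sub_name, "/distance"), {
        per_locus <- lapply(sub$loci, function(l)
          pairwise_matrix(ft, "DA", loci = l))
        names(per_locus) <- sub$loci
        multi <- lapply(cfg$measures, function(m) pairwise_matrix(ft, m))
        names(multi) <- cfg$measures
        list(per_locus = per_locus, multi = multi)
      })
      for (m in names(dm$multi)) {
        write_phylip_matrix(dm$multi[[m]], out(sub_name, "_", m, ".phylip"))
        write_dist_long(dm$multi[[m]], out(sub_name, "_", m, ".csv"))
      }
      # inter-locus Mantel grid (locus-congruence check)
      grid <- interlocus_mantel(dm$per_locus,
                                permutations = min(cfg$permutations, 999),
                                seed = stage_seed(cfg, "mantel"))
      write.csv(grid, out(sub_name, "_locus_mantel.csv"),
                row.names = FALSE)
      products[[sub_name]]$distance <- dm
      products[[sub_name]]$locus_mantel <- grid
    }

    if ("tree" %in% cfg$stages && "distance" %in% cfg$stages) {
      tr <- tick(paste0(sub_name, "/tree"), {
        da <- products[[sub_name]]$distance$multi$DA
        nj <- neighbor_joining(da)
        boot <- bootstrap_over_loci(ft, "DA", B = cfg$bootstrap_B,
                                    seed = stage_seed(cfg, "tree"))
        btrees <- bootstrap_trees(boot)
        list(nj = bipartition_support(nj, btrees),
             consensus = majority_rule_consensus(btrees))
      })
      write_newick(tr$nj, out(sub_name, "_nj_DA.nwk"))
      write_newick(tr$consensus, out(sub_name, "_consensus_DA.nwk"))
      products[[sub_name]]$tree <- tr
    }

    if ("pca" %in% cfg$stages) {
      pc <- tick(paste0(sub_name, "/pca"), {
        z <- normalize_frequencies(ft)
        res <- pca(z)
        pa <- parallel_analysis(nrow(z), ncol(z),
                                reps = cfg$parallel_reps,
                                seed = stage_seed(cfg, "pca"),
                                observed = res$percent_variance[1:2])
        list(z = z, pca = res, parallel = pa)
      })
      write_pca_report(pc$pca, cfg$out_dir, paste0(sub_name, "_pca"))
      write.csv(pc$parallel$summary,
                out(sub_name, "_parallel_analysis.csv"),
                row.names = FALSE)
      products[[sub_name]]$pca <- pc
    }

    if ("admixture" %in% cfg$stages) {
      ad <- tick(paste0(sub_name, "/admixture"), {
        per_k <- lapply(cfg$K_range, function(K) {
          runs <- lapply(seq_len(cfg$admixture_runs), function(r)
            fit_admixture(sub, K, burn_in = cfg$burn_in,
                          run_length = cfg$run_length,
                          seed = stage_seed(cfg, "admixture") + 100L * K + r))
          align_runs(runs)
        })
        names(per_k) <- paste0("K", cfg$K_range)
        list(per_k = per_k, selection = select_K(per_k))
      })
      for (Kn in names(ad$per_k)) {
        best <- which.max(vapply(ad$per_k[[Kn]], function(r) r$lnP,
                                 numeric(1)))
        write_q_matrix(ad$per_k[[Kn]][[best]], sub,
                       out(sub_name, "_", Kn, "_Q.txt"),
                       out(sub_name, "_", Kn, "_mean_membership.csv"))
      }
      write.csv(ad$selection$summary, out(sub_name, "_lnP_by_K.csv"),
                row.names = FALSE)
      products[[sub_name]]$admixture <- ad
    }

    if ("mantel" %in% cfg$stages && "distance" %in% cfg$stages &&
        !is.null(pm)) {
      mt <- tick(paste0(sub_name, "/mantel"), {
        keep <- pm$population %in% populations(sub)
        coords <- pm[keep, , drop = FALSE]
        geo <- geographic_distance_matrix(coords)
        ling <- linguistic_distance_matrix(ltree, coords$population)
        gen <- products[[sub_name]]$distance$multi$DA
        gen <- gen[coords$population, coords$population]
        groups <- language_groups(ltree, coords$population)
        tab <- exclusion_analysis(gen, geo, ling, groups,
                                  permutations = cfg$permutations,
                                  seed = stage_seed(cfg, "mantel"))
        pcd <- NULL
        if (!is.null(products[[sub_name]]$pca)) {
          pcd <- pc_score_distances(products[[sub_name]]$pca$pca,
                                    cfg$pca_components)
          pcd <- mantel(pcd[coords$population, coords$population], geo,
                        permutations = cfg$permutations,
                        seed = stage_seed(cfg, "mantel"))
        }
        list(table = tab, geo = geo, ling = ling, pca_vs_geo = pcd)
      })
      write.csv(mt$table, out(sub_name, "_mantel_table.csv"),
                row.names = FALSE)
      write_phylip_matrix(mt$geo, out(sub_name, "_geographic.phylip"))
      write_phylip_matrix(mt$ling, out(sub_name, "_linguistic.phylip"))
      products[[sub_name]]$mantel <- mt
    }
  }

  cfg_for_hash <- cfg
  cfg_for_hash$genotypes <- NULL     # data identity, not a parameter
  cfg_for_hash$out_dir <- NULL       # hash covers analysis settings only
  manifest <- list(
    config = lapply(cfg_for_hash, function(x)
      if (is.atomic(x) || is.null(x)) x else "object"),
    config_hash = config_hash(cfg_for_hash),
    stage_seconds = timings,
    files = list.files(cfg$out_dir),
    total_seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "run_manifest.yaml"))
  invisible(list(products = products, manifest = manifest))
}

config_hash <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  # small stable polynomial hash, avoids a digest dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Inter-locus Mantel congruence grid
#'
#' Mantel tests between the single-locus DA matrices of every locus
#' pair; positive correlations indicate the loci capture a shared
#' population structure and can be combined.
#'
#' @param per_locus named list of single-locus distance matrices.
#' @param permutations,seed passed to [mantel()].
#' @return data.frame with columns `locus1`, `locus2`, `r`, `p_value`.
#' @export
interlocus_mantel <- function(per_locus, permutations = 999, seed = 1) {
  loci <- names(per_locus)
  out <- list()
  for (i in seq_along(loci)) for (j in seq_len(i - 1L)) {
    mt <- mantel(per_locus[[i]], per_locus[[j]],
                 permutations = permutations, seed = seed)
    out[[length(out) + 1L]] <- data.frame(
      locus1 = loci[j], locus2 = loci[i], r = mt$r,
      p_value = mt$p_value)
  }
  do.call(rbind, out)
}
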