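# ---------------------------------------------------------------------------
# The chromosome-3 marker panel

#' The shipped chromosome-3 STR marker panel
#'
#' Ten dinucleotide STR markers spanning chromosome 3, with genetic-map
#' positions (cM), the across-population mean and sd of expected
#' heterozygosity, and the CEPH reference heterozygosities from the
#' typing panel's documentation.
#'
#' @return data.frame with columns `name`, `chromosome`,
#'   `map_position_cM`, `mean_he`, `sd_he`, `ceph_he`.
#' @export
marker_panel <- function() {
  read.csv(system.file("extdata", "markers_chr3.csv",
                       package = "msatpop", mustWork = TRUE),
           stringsAsFactors = FALSE)
}

#' Distances between adjacent markers on the genetic map
#'
#' Markers are sorted by map position; the gaps between neighbours
#' summarize how independently the loci segregate (large gaps mean
#' linkage disequilibrium between panel markers is negligible).
#'
#' @param markers data.frame with columns `name` and `map_position_cM`
#'   (default: the shipped panel).
#' @return List with `gaps` (named numeric vector of adjacent distances
#'   in cM), `mean` and `min`.
#' @export
adjacent_map_distances <- function(markers = marker_panel()) {
  ord <- order(markers$map_position_cM)
  pos <- markers$map_position_cM[ord]
  gaps <- diff(pos)
  names(gaps) <- paste(markers$name[ord][-length(pos)],
                       markers$name[ord][-1], sep = "-")
  list(gaps = gaps, mean = mean(gaps), min = min(gaps))
}
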