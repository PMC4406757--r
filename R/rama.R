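#' Ramachandran region maps
#'
#' Residue backbone conformations are classified into seven regions of the
#' Ramachandran plot; the region index is the "environment" used by the
#' environment-specific substitution score. The package ships a default map
#' of rectangular (phi, psi) boxes covering the whole torus:
#' 1 core-helical, 2 broad-helical, 3 core-strand, 4 broad-strand,
#' 5 polyproline-II, 6 left-handed-helical, 7 other (catch-all). The map is
#' user-replaceable: any file in the same format may be supplied.
#'
#' The file format is plain text, one box per line:
#' `index label phi_min phi_max psi_min psi_max`, comment lines start with
#' `#`. A point belongs to the first box (in file order) that contains it;
#' boxes are half-open `[min, max)` except that `max = 180` is inclusive, so
#' the lowest-index region wins on shared boundaries and the torus is fully
#' covered.
#'
#' @param path path to a region-map file; default is the packaged map.
#' @return a `data.frame` with columns `region`, `label`, `phi_min`,
#'   `phi_max`, `psi_min`, `psi_max`.
#' @export
read_rama_regions <- function(path = system.file("extdata", "rama_regions.txt",
                                                 package = "fraglib")) {
  rg <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("region", "label", "phi_min",
                                        "phi_max", "psi_min", "psi_max"),
                          stringsAsFactors = FALSE)
  if (nrow(rg) == 0L) stop("empty region map: ", path)
  if (!setequal(unique(rg$region), 1:7))
    stop("region map must define exactly regions 1..7")
  rg
}

.rama_cache <- new.env(parent = emptyenv())

default_rama_regions <- function() {
  if (is.null(.rama_cache$regions))
    .rama_cache$regions <- read_rama_regions()
  .rama_cache$regions
}

#' Classify backbone torsions into Ramachandran regions
#'
#' Total function on the (phi, psi) torus: every defined angle pair maps to
#' exactly one of seven region indices. Points on a shared boundary go to
#' the lowest region index (deterministic tie-break). Undefined angles
#' (`NA`, e.g. chain termini) map to `NA`.
#'
#' @param phi,psi angles in degrees in (-180, 180] (vectors recycle).
#' @param regions a region map as returned by [read_rama_regions()].
#' @return integer vector of region indices 1..7 (or `NA`).
#' @export
classify_rama_region <- function(phi, psi, regions = default_rama_regions()) {
  n <- max(length(phi), length(psi))
  phi <- rep_len(wrap_angle(phi), n)
  psi <- rep_len(wrap_angle(psi), n)
  out <- rep(NA_integer_, n)
  ok <- !is.na(phi) & !is.na(psi)
  if (!any(ok)) return(out)
  res <- rep(NA_integer_, sum(ok))
  p <- phi[ok]; q <- psi[ok]
  inbox <- function(x, lo, hi) x >= lo & (x < hi | (hi == 180 & x == 180))
  for (k in seq_len(nrow(regions))) {
    hit <- is.na(res) &
      inbox(p, regions$phi_min[k], regions$phi_max[k]) &
      inbox(q, regions$psi_min[k], regions$psi_max[k])
    res[hit] <- regions$region[k]
  }
  out[ok] <- res
  out
}

# character view used in template entries: '1'..'7', '-' for undefined
rama_string <- function(region) {
  paste(ifelse(is.na(region), "-", as.character(region)), collapse = "")
}
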