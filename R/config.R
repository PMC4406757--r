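#' Pipeline configuration
#'
#' All tunable parameters of the extraction pipeline with their default
#' values: 5000 random draws per position, fragment lengths 6-20,
#' top 1000 fragments per position from exhaustive search, 20 fragments
#' per position after torsion ranking, an enrichment pool of the 500
#' top-torsion fragments with a 0.5 Angstrom RMSD inclusion threshold, a
#' threading cap of 20 fragments per position and a homolog probability
#' threshold of 99.5 percent.
#'
#' @param n_random random draws scored per target position.
#' @param len_range fragment length range (min, max).
#' @param top_k fragments kept per position by exhaustive extraction.
#' @param lib20_size fragments kept per position after torsion ranking.
#' @param pool_size torsion-ranked pool searched by the enrichment step.
#' @param enrich_rmsd RMSD threshold (Angstroms, strict `<`) for enrichment.
#' @param enrich_pool `"pool"` (the `pool_size` top-torsion fragments,
#'   default) or `"lib3000"` (the whole merged library).
#' @param min_overlap minimum shared window span for cross-length RMSD.
#' @param threading_cap maximum threading fragments per position.
#' @param homolog_prob homolog probability threshold (percent).
#' @param cutoffs per-SS-class acceptance cutoffs for random extraction:
#'   a list with elements `alpha`, `beta`, `loop`, `other`, each
#'   `c(rama = ..., ss = ...)` on the per-residue score scale.
#' @param per_residue rank fragments of mixed lengths by per-residue
#'   scores (`TRUE`, default) or raw sums (`FALSE`, strict-replication).
#' @param seed integer seed for the random-extraction draws.
#' @return a `flib_config` list.
#' @export
flib_config <- function(n_random = 5000L,
                        len_range = c(6L, 20L),
                        top_k = 1000L,
                        lib20_size = 20L,
                        pool_size = 500L,
                        enrich_rmsd = 0.5,
                        enrich_pool = c("pool", "lib3000"),
                        min_overlap = 4L,
                        threading_cap = 20L,
                        homolog_prob = 99.5,
                        cutoffs = default_cutoffs(),
                        per_residue = TRUE,
                        seed = 1L) {
  enrich_pool <- match.arg(enrich_pool)
  cfg <- list(n_random = as.integer(n_random),
              len_range = as.integer(len_range),
              top_k = as.integer(top_k),
              lib20_size = as.integer(lib20_size),
              pool_size = as.integer(pool_size),
              enrich_rmsd = enrich_rmsd,
              enrich_pool = enrich_pool,
              min_overlap = as.integer(min_overlap),
              threading_cap = as.integer(threading_cap),
              homolog_prob = homolog_prob,
              cutoffs = cutoffs,
              per_residue = isTRUE(per_residue),
              seed = as.integer(seed))
  validate_config_values(cfg)
  structure(cfg, class = "flib_config")
}

validate_config_values <- function(cfg) {
  pos <- c("n_random", "top_k", "lib20_size", "pool_size", "min_overlap",
           "threading_cap")
  for (nm in pos)
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop("config field '", nm, "' must be a positive integer")
  if (length(cfg$len_range) != 2L || cfg$len_range[1] < 2L ||
      cfg$len_range[1] > cfg$len_range[2])
    stop("config field 'len_range' must be an increasing pair of lengths")
  if (!is.numeric(cfg$enrich_rmsd) || cfg$enrich_rmsd <= 0)
    stop("config field 'enrich_rmsd' must be > 0")
  if (cfg$homolog_prob < 0 || cfg$homolog_prob > 100)
    stop("config field 'homolog_prob' must be a percentage")
  cls <- c("alpha", "beta", "loop", "other")
  if (!all(cls %in% names(cfg$cutoffs)))
    stop("config field 'cutoffs' needs entries alpha/beta/loop/other")
  for (cl in cls)
    if (!all(c("rama", "ss") %in% names(cfg$cutoffs[[cl]])))
      stop("cutoffs for class '", cl, "' need 'rama' and 'ss' values")
  invisible(cfg)
}

#' Default per-class acceptance cutoffs
#'
#' Per-residue (score / length) acceptance thresholds for the random
#' extraction stage, one pair (Ramachandran-sequence score, SS score) per
#' SS class. Helical and strand windows use stricter cutoffs than loop and
#' "other" windows, whose conformational variability is far higher. Values
#' were calibrated with [calibrate_cutoffs()] on the package's synthetic
#' fixture conditions; users working with real structures should
#' recalibrate on their own training targets.
#'
#' @return named list of `c(rama = ..., ss = ...)` per class.
#' @export
default_cutoffs <- function() {
  list(alpha = c(rama = -2, ss = 2),
       beta  = c(rama = -2, ss = 1),
       loop  = c(rama = -2, ss = -1),
       other = c(rama = -2, ss = 1))
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML key-value file, applies [flib_config()] defaults for
#' absent keys, and rejects unknown keys and out-of-range values.
#'
#' @param path YAML configuration file.
#' @return a `flib_config`.
#' @export
validate_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(flib_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(vals$cutoffs))
    vals$cutoffs <- lapply(vals$cutoffs, unlist)
  do.call(flib_config, vals)
}

#' @export
print.flib_config <- function(x, ...) {
  cat("<flib_config>\n")
  cat("  random draws/position:", x$n_random, "\n")
  cat("  lengths:", x$len_range[1], "-", x$len_range[2],
      " exhaustive top-k:", x$top_k, "\n")
  cat("  lib20:", x$lib20_size, " enrichment pool:", x$pool_size,
      paste0("(", x$enrich_pool, ")"), " RMSD <", x$enrich_rmsd, "A\n")
  cat("  threading cap:", x$threading_cap,
      " homolog prob >=", x$homolog_prob, "%\n")
  cat("  ranking:", if (x$per_residue) "per-residue scores" else "raw sums",
      " seed:", x$seed, "\n")
  invisible(x)
}
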