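#' Run the full fragment-library pipeline
#'
#' Orchestrates the whole generation routine for one target: random and
#' exhaustive extraction, merge (LIB3000), torsion ranking (LIB20),
#' enrichment, conversion and filtering of threading hits, and the final
#' merge; optionally evaluates the final library against the native
#' structure. Fully deterministic under the config seed: identical inputs,
#' config and seed give byte-identical library files.
#'
#' @param profile a `target_profile`.
#' @param db a `template_db`.
#' @param config a [flib_config()].
#' @param hits optional `threading_hits`.
#' @param native optional native [chain_structure]; when given, the final
#'   library is evaluated over `eval_grid`.
#' @param matrices environment substitution matrices.
#' @param eval_grid RMSD cutoff grid for the evaluation report.
#' @param keep_stages keep every intermediate library in the result.
#' @return a `flib_run`: list with `final` (the FINAL
#'   `fragment_library`), `eval` (a `flib_eval` or `NULL`), and the
#'   intermediate stages when requested.
#' @export
run_flib <- function(profile, db, config = flib_config(), hits = NULL,
                     native = NULL, matrices = default_env_matrices(),
                     eval_grid = seq(0.1, 2.0, by = 0.1),
                     keep_stages = FALSE) {
  stage <- "random_extract"
  res <- tryCatch({
    rand <- random_extract(profile, db, config, matrices)
    stage <- "exhaustive_extract"
    exh <- exhaustive_extract(profile, db, config, matrices)
    stage <- "merge_to_lib3000"
    lib3000 <- merge_to_lib3000(rand, exh)
    lib3000 <- add_torsion_scores(lib3000, profile, db, matrices)
    stage <- "rank_to_lib20"
    lib20 <- rank_to_lib20(lib3000, profile, db, config, matrices)
    stage <- "enrich"
    enriched <- enrich(lib3000, lib20, profile, db, config, matrices)
    stage <- "threading"
    th <- if (is.null(hits)) {
      new_fragment_library(frag_cols(), "THREADING",
                           nchar(profile$sequence))
    } else {
      homologs <- read_homolog_hits(hits, config$homolog_prob)
      raw <- hits_to_fragments(hits, db, homologs,
                               nchar(profile$sequence))
      cap_and_filter(raw, profile, config$threading_cap)
    }
    stage <- "merge_final"
    final <- merge_final(enriched, th)
    final$provenance <- list(config = config, seed = config$seed,
                             db_entries = length(db$entries),
                             homologs = profile$homolog_ids)
    stage <- "evaluate"
    ev <- if (!is.null(native))
      evaluate_curves(final, native, db, grid = eval_grid,
                      profile = profile)
    out <- list(final = final, eval = ev, config = config)
    if (keep_stages)
      out$stages <- list(random = rand, exhaustive = exh,
                         lib3000 = lib3000, lib20 = lib20,
                         enriched = enriched, threading = th)
    out
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  class(res) <- "flib_run"
  res
}

#' @export
print.flib_run <- function(x, ...) {
  cat("<flib_run>\n")
  print(x$final)
  if (!is.null(x$eval)) print(x$eval)
  invisible(x)
}
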