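# Fragment library container: a data.frame of fragments plus stage and
# provenance. One row per fragment: target position `pos` (1-based, window
# covers pos..pos+len-1), `len`, source `template` id and `tstart`
# (1-based), `origin` stage, window SS class and the three scores (raw
# sums; per-residue = score / len). `hit_score` is set for
# threading-derived fragments only.

frag_cols <- function() {
  data.frame(pos = integer(0), len = integer(0),
             template = character(0), tstart = integer(0),
             origin = character(0), ss_class = character(0),
             score_rama = numeric(0), score_ss = numeric(0),
             score_tors = numeric(0), hit_score = numeric(0),
             stringsAsFactors = FALSE)
}

new_fragment_library <- function(frags, stage, target_len,
                                 provenance = list(), coords = NULL) {
  base <- frag_cols()
  for (nm in names(base)) if (is.null(frags[[nm]]))
    frags[[nm]] <- rep(base[[nm]][NA][1], nrow(frags))
  frags <- frags[names(base)]
  rownames(frags) <- NULL
  structure(list(frags = frags, stage = stage, target_len = target_len,
                 provenance = provenance, coords = coords),
            class = "fragment_library")
}

frag_key <- function(frags) {
  paste(frags$pos, frags$template, frags$tstart, frags$len, sep = "|")
}

#' @export
print.fragment_library <- function(x, ...) {
  np <- length(unique(x$frags$pos))
  cat("<fragment_library> stage ", x$stage, ": ", nrow(x$frags),
      " fragments over ", np, " position(s) (target length ",
      x$target_len, ")\n", sep = "")
  if (nrow(x$frags)) {
    cat("  lengths ", min(x$frags$len), "-", max(x$frags$len),
        ", mean ", round(mean(x$frags$len), 1),
        "; mean/position ", round(nrow(x$frags) / max(np, 1), 1),
        "\n", sep = "")
    cat("  origins: ", paste(names(table(x$frags$origin)),
                             table(x$frags$origin),
                             sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.fragment_library <- function(object, ...) {
  f <- object$frags
  per_pos <- if (nrow(f)) table(factor(f$pos, levels = modelable_positions(
    object$target_len))) else integer(0)
  out <- list(stage = object$stage, n_fragments = nrow(f),
              target_len = object$target_len,
              mean_per_position = if (length(per_pos)) mean(per_pos) else 0,
              mean_length = if (nrow(f)) mean(f$len) else NA_real_,
              origins = if (nrow(f)) table(f$origin) else NULL)
  class(out) <- "summary.fragment_library"
  out
}

#' @export
print.summary.fragment_library <- function(x, ...) {
  cat("Fragment library, stage ", x$stage, "\n", sep = "")
  cat("  fragments:      ", x$n_fragments, "\n")
  cat("  mean/position:  ", round(x$mean_per_position, 2), "\n")
  cat("  mean length:    ", round(x$mean_length, 2), "\n")
  invisible(x)
}

# positions of the target that admit at least a minimum-length window
modelable_positions <- function(target_len, min_len = 6L) {
  if (target_len < min_len) return(integer(0))
  seq_len(target_len - min_len + 1L)
}

# Calpha coordinates of fragment i: from the attached coords list when
# present (libraries read from torsion-only formats), else from the
# template database.
frag_ca <- function(lib, i, db = NULL) {
  if (!is.null(lib$coords) && !is.null(lib$coords[[i]]))
    return(lib$coords[[i]])
  if (is.null(db)) stop("fragment coordinates require a template database")
  f <- lib$frags[i, ]
  e <- db$entries[[f$template]]
  if (is.null(e)) stop("template '", f$template, "' not in database")
  e$ca[f$tstart:(f$tstart + f$len - 1L), , drop = FALSE]
}

#' Write / read a fragment library as TSV
#'
#' One row per fragment: target position (1-based), length, template id,
#' template start (1-based), origin, SS class, the three scores and the
#' threading hit score. A `#` header records the stage and target length.
#'
#' @param lib a `fragment_library`.
#' @param path file path.
#' @export
write_library <- function(lib, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# fraglib library v1",
               paste("# stage", lib$stage),
               paste("# target_len", lib$target_len)), con)
  f <- lib$frags
  num <- function(x) ifelse(is.na(x), "NA",
                            formatC(x, digits = 10, format = "g"))
  writeLines(paste("pos", "len", "template", "tstart", "origin", "ss_class",
                   "score_rama", "score_ss", "score_tors", "hit_score",
                   sep = "\t"), con)
  if (nrow(f))
    writeLines(paste(f$pos, f$len, f$template, f$tstart, f$origin,
                     f$ss_class, num(f$score_rama), num(f$score_ss),
                     num(f$score_tors), num(f$hit_score), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "# fraglib library v1")
    stop("not a fraglib library file: ", path)
  stage <- sub("^# stage ", "", lines[2])
  target_len <- as.integer(sub("^# target_len ", "", lines[3]))
  df <- utils::read.table(text = lines[-(1:3)], header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  new_fragment_library(df, stage, target_len)
}
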