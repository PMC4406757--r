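# Threading hits: sequence-to-structure alignments of the target onto
# template entries, mined for nine-residue fragments. A hit carries a
# probability (percent), a score and one or more gapless aligned blocks
# (target start, template start, length), all 1-based.

new_threading_hits <- function(hits, blocks) {
  stopifnot(all(c("id", "prob", "score") %in% names(hits)),
            all(c("hit", "target_start", "template_start", "len") %in%
                  names(blocks)))
  structure(list(hits = hits, blocks = blocks), class = "threading_hits")
}

#' @export
print.threading_hits <- function(x, ...) {
  cat("<threading_hits> ", nrow(x$hits), " hit(s), ",
      nrow(x$blocks), " gapless block(s)\n", sep = "")
  invisible(x)
}

#' Read / write a threading hit list (simple TSV dialect)
#'
#' Columns: `id`, `prob` (percent), `score`, `blocks` — the latter a
#' comma-separated list of gapless aligned blocks
#' `target_start:template_start:len` (1-based).
#'
#' @param path TSV file.
#' @return a `threading_hits` object.
#' @export
read_threading_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric",
                                         "numeric", "character"))
  blocks <- list()
  for (i in seq_len(nrow(df))) {
    for (b in strsplit(df$blocks[i], ",")[[1]]) {
      v <- as.integer(strsplit(b, ":")[[1]])
      if (length(v) != 3L || anyNA(v))
        stop("malformed block '", b, "' in hit ", df$id[i])
      blocks[[length(blocks) + 1L]] <-
        data.frame(hit = i, target_start = v[1], template_start = v[2],
                   len = v[3])
    }
  }
  new_threading_hits(df[c("id", "prob", "score")],
                     if (length(blocks)) do.call(rbind, blocks) else
                       data.frame(hit = integer(0), target_start = integer(0),
                                  template_start = integer(0),
                                  len = integer(0)))
}

#' @rdname read_threading_tsv
#' @param hits a `threading_hits` object.
#' @export
write_threading_tsv <- function(hits, path) {
  rows <- vapply(seq_len(nrow(hits$hits)), function(i) {
    b <- hits$blocks[hits$blocks$hit == i, , drop = FALSE]
    paste(hits$hits$id[i], hits$hits$prob[i], hits$hits$score[i],
          paste(sprintf("%d:%d:%d", b$target_start, b$template_start,
                        b$len), collapse = ","),
          sep = "\t")
  }, character(1))
  writeLines(c("id\tprob\tscore\tblocks", rows), path)
  invisible(path)
}

#' Read an HHR-format threading hit file
#'
#' Parses the hit summary table (probability, score) and the pairwise
#' alignments of an HHsearch-style `.hhr` report; gapless aligned blocks
#' are derived by splitting the alignment at any gap in either sequence.
#'
#' @param path `.hhr` file.
#' @return a `threading_hits` object.
#' @export
read_hhr <- function(path) {
  lines <- readLines(path)
  alns <- grep("^No [0-9]+", lines)
  if (!length(alns)) stop("no alignments found in ", path)
  hits <- list(); blocks <- list()
  bounds <- c(alns, length(lines) + 1L)
  for (k in seq_along(alns)) {
    seg <- lines[alns[k]:(bounds[k + 1L] - 1L)]
    idline <- grep("^>", seg, value = TRUE)[1]
    id <- strsplit(sub("^>", "", idline), "\\s+")[[1]][1]
    stat <- grep("^Probab=", seg, value = TRUE)[1]
    prob <- as.numeric(sub(".*Probab=([0-9.]+).*", "\\1", stat))
    score <- as.numeric(sub(".*Score=([0-9.]+).*", "\\1", stat))
    qlines <- grep("^Q ", seg, value = TRUE)
    tlines <- grep("^T ", seg, value = TRUE)
    skip <- function(v) !grepl("^(Q|T)\\s+(Consensus|ss_pred|ss_dssp|ss_conf)",
                               v)
    qlines <- qlines[skip(qlines)]
    tlines <- tlines[skip(tlines)]
    if (!length(qlines) || length(qlines) != length(tlines))
      stop("malformed alignment block for hit ", id, " in ", path)
    qi <- ti <- NA_integer_; qseq <- tseq <- ""
    for (j in seq_along(qlines)) {
      qp <- strsplit(trimws(qlines[j]), "\\s+")[[1]]
      tp <- strsplit(trimws(tlines[j]), "\\s+")[[1]]
      if (j == 1L) { qi <- as.integer(qp[3]); ti <- as.integer(tp[3]) }
      qseq <- paste0(qseq, qp[4]); tseq <- paste0(tseq, tp[4])
    }
    qs <- strsplit(qseq, "")[[1]]; ts <- strsplit(tseq, "")[[1]]
    qpos <- qi - 1L; tpos <- ti - 1L
    bstart_q <- bstart_t <- blen <- 0L
    i <- length(hits) + 1L
    hits[[i]] <- data.frame(id = id, prob = prob, score = score,
                            stringsAsFactors = FALSE)
    flush <- function() {
      if (blen > 0L)
        blocks[[length(blocks) + 1L]] <<-
          data.frame(hit = i, target_start = bstart_q,
                     template_start = bstart_t, len = blen)
    }
    for (c_i in seq_along(qs)) {
      qg <- qs[c_i] == "-"; tg <- ts[c_i] == "-"
      if (!qg) qpos <- qpos + 1L
      if (!tg) tpos <- tpos + 1L
      if (!qg && !tg) {
        if (blen == 0L) { bstart_q <- qpos; bstart_t <- tpos }
        blen <- blen + 1L
      } else { flush(); blen <- 0L }
    }
    flush()
  }
  new_threading_hits(do.call(rbind, hits),
                     do.call(rbind, blocks))
}

#' Convert threading hits to nine-residue fragments
#'
#' Hits from homolog templates are dropped. Every gapless aligned block of
#' each surviving hit yields all of its length-9 windows, mapped to target
#' positions through the block alignment; each fragment carries the hit
#' score. Hits referencing templates absent from the database are skipped
#' with a warning. Fragments never span an alignment gap or a template
#' chain break.
#'
#' @param hits a `threading_hits` object.
#' @param db the `template_db`.
#' @param homolog_ids homolog template ids (see [read_homolog_hits()]).
#' @param target_len target sequence length.
#' @return a `fragment_library` at stage `THREADING`.
#' @export
hits_to_fragments <- function(hits, db, homolog_ids = character(0),
                              target_len) {
  frags <- list()
  for (i in seq_len(nrow(hits$hits))) {
    h <- hits$hits[i, ]
    if (h$id %in% homolog_ids) next
    e <- db$entries[[h$id]]
    if (is.null(e)) {
      warning("threading hit template '", h$id,
              "' not in database; skipped")
      next
    }
    b <- hits$blocks[hits$blocks$hit == i, , drop = FALSE]
    for (j in seq_len(nrow(b))) {
      if (b$len[j] < 9L) next
      for (off in 0:(b$len[j] - 9L)) {
        ts <- b$template_start[j] + off
        qs <- b$target_start[j] + off
        if (ts + 8L > length(e$aa) || qs + 8L > target_len) next
        if (e$segment[ts] != e$segment[ts + 8L]) next
        frags[[length(frags) + 1L]] <- data.frame(
          pos = qs, len = 9L, template = h$id, tstart = ts,
          origin = "THREADING", ss_class = NA_character_,
          score_rama = NA_real_, score_ss = NA_real_,
          score_tors = NA_real_, hit_score = h$score,
          stringsAsFactors = FALSE)
      }
    }
  }
  f <- if (length(frags)) do.call(rbind, frags) else frag_cols()
  f <- f[!duplicated(frag_key(f)), , drop = FALSE]
  new_fragment_library(f, "THREADING", target_len)
}

#' Cap and filter the threading library
#'
#' Per position, fragments are ranked by descending hit score (ties by
#' template id then start) and at most `cap` are kept; positions whose
#' nine-residue window is majority alpha-helical are emptied entirely
#' (threading fragments help beta, loop and mixed positions but degrade
#' helical ones).
#'
#' @param th_lib a `fragment_library` at stage `THREADING`.
#' @param profile the `target_profile` (for window SS classes).
#' @param cap maximum fragments per position.
#' @return the filtered `fragment_library`.
#' @export
cap_and_filter <- function(th_lib, profile, cap = 20L) {
  f <- th_lib$frags
  if (nrow(f)) {
    f$ss_class <- ss_class_vec(profile, f$pos, f$len)
    f <- f[f$ss_class != "alpha", , drop = FALSE]
    if (nrow(f)) {
      ord <- order(f$pos, -f$hit_score, f$template, f$tstart)
      f <- f[ord, , drop = FALSE]
      keep <- unlist(lapply(split(seq_len(nrow(f)), f$pos), function(ii)
        ii[seq_len(min(cap, length(ii)))]), use.names = FALSE)
      f <- f[sort(keep), , drop = FALSE]
    }
  }
  new_fragment_library(f, "THREADING", th_lib$target_len,
                       provenance = th_lib$provenance)
}

#' Merge the enriched and threading libraries into the final library
#'
#' Per-position union with duplicate removal; origin labels are preserved
#' (the first occurrence wins).
#'
#' @param enriched_lib,threading_lib fragment libraries for the same
#'   target.
#' @return a `fragment_library` at stage `FINAL`.
#' @export
merge_final <- function(enriched_lib, threading_lib) {
  stopifnot(enriched_lib$target_len == threading_lib$target_len)
  f <- rbind(enriched_lib$frags, threading_lib$frags)
  f <- f[!duplicated(frag_key(f)), , drop = FALSE]
  f <- f[order(f$pos, f$template, f$tstart, f$len), , drop = FALSE]
  new_fragment_library(f, "FINAL", enriched_lib$target_len,
                       provenance = enriched_lib$provenance)
}
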