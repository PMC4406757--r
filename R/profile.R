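#' Read a single-record FASTA sequence
#'
#' @param path FASTA file with exactly one record.
#' @return uppercased amino-acid string (standard 20 letters plus X).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  if (length(ss) > 1L)
    stop("expected a single FASTA record, found ", length(ss))
  seq <- toupper(as.character(ss[[1]]))
  bad <- setdiff(strsplit(seq, "")[[1]], c(strsplit(.aa_alphabet, "")[[1]], "X"))
  if (length(bad))
    stop("non-amino-acid letters in sequence: ", paste(bad, collapse = ""))
  seq
}

.aa_alphabet <- "ACDEFGHIKLMNPQRSTVWY"

#' Read a PSIPRED ss2-style secondary-structure prediction
#'
#' Tabular format: one row per residue with index, amino acid, predicted
#' 3-state letter and three state confidences (coil, helix, strand).
#'
#' @param path ss2-style file.
#' @return list with `ss3` (character vector in H/E/C), `aa` and a
#'   3-column `conf` matrix.
#' @export
read_psipred_ss2 <- function(path) {
  lines <- readLines(path)
  keep <- grepl("^\\s*\\d", lines)
  rows <- which(keep)
  if (!length(rows)) stop("no data rows in ", path)
  parts <- strsplit(trimws(lines[keep]), "\\s+")
  n <- length(parts)
  ss3 <- character(n); aa <- character(n)
  conf <- matrix(NA_real_, n, 3,
                 dimnames = list(NULL, c("C", "H", "E")))
  for (i in seq_len(n)) {
    p <- parts[[i]]
    if (length(p) < 6L)
      stop("malformed ss2 row at line ", rows[i], " of ", path)
    aa[i] <- p[2]; ss3[i] <- p[3]
    v <- suppressWarnings(as.numeric(p[4:6]))
    if (anyNA(v))
      stop("non-numeric confidence at line ", rows[i], " of ", path)
    conf[i, ] <- v
  }
  if (!all(ss3 %in% c("H", "E", "C")))
    stop("ss2 letters must be 3-state (H/E/C); found: ",
         paste(setdiff(ss3, c("H", "E", "C")), collapse = ","))
  if (any(abs(rowSums(conf) - 1) > 0.2))
    warning("ss2 confidences do not sum to ~1 for some rows")
  list(ss3 = ss3, aa = aa, conf = conf)
}

#' Read per-residue predicted torsion angles
#'
#' Tabular format (SPINE-X style): index, amino acid, predicted phi,
#' predicted psi. Angles are normalized to (-180, 180].
#'
#' @param path torsion-prediction file.
#' @return list with numeric vectors `phi`, `psi` and character `aa`.
#' @export
read_torsion_predictions <- function(path) {
  lines <- readLines(path)
  keep <- grepl("^\\s*\\d", lines)
  rows <- which(keep)
  if (!length(rows)) stop("no data rows in ", path)
  parts <- strsplit(trimws(lines[keep]), "\\s+")
  n <- length(parts)
  phi <- psi <- numeric(n); aa <- character(n)
  for (i in seq_len(n)) {
    p <- parts[[i]]
    if (length(p) < 4L)
      stop("missing column at line ", rows[i], " of ", path)
    aa[i] <- p[2]
    v <- suppressWarnings(as.numeric(p[3:4]))
    if (anyNA(v)) stop("non-numeric angle at line ", rows[i], " of ", path)
    phi[i] <- v[1]; psi[i] <- v[2]
  }
  list(phi = wrap_angle(phi), psi = wrap_angle(psi), aa = aa)
}

#' Identify homolog templates among threading hits
#'
#' A hit is flagged as a homolog when its probability is at or above the
#' threshold (default 99.5 percent). Fragments from homologs are excluded
#' everywhere downstream to emulate a true de novo prediction scenario.
#'
#' @param hits a `threading_hits` object or the data.frame inside one.
#' @param prob_threshold homolog probability threshold in percent.
#' @return character vector of homolog template ids.
#' @export
read_homolog_hits <- function(hits, prob_threshold = 99.5) {
  df <- if (inherits(hits, "threading_hits")) hits$hits else hits
  if (is.null(df) || nrow(df) == 0L) return(character(0))
  unique(df$id[df$prob >= prob_threshold])
}

#' Assemble a target profile
#'
#' Bundles everything known about the target before extraction: its
#' sequence, predicted 3-state secondary structure, predicted torsions and
#' the homolog id set derived from threading hits.
#'
#' @param sequence amino-acid string (or FASTA path via [read_fasta()]).
#' @param ss2 result of [read_psipred_ss2()] (or a plain H/E/C string).
#' @param torsions result of [read_torsion_predictions()] (or a list with
#'   `phi` and `psi`).
#' @param hits optional `threading_hits` used to flag homologs.
#' @param prob_threshold homolog probability threshold in percent.
#' @return a `target_profile`.
#' @export
target_profile <- function(sequence, ss2, torsions, hits = NULL,
                           prob_threshold = 99.5) {
  if (is.character(ss2) && length(ss2) == 1L)
    ss2 <- list(ss3 = strsplit(ss2, "")[[1]], conf = NULL)
  n <- nchar(sequence)
  if (length(ss2$ss3) != n)
    stop("predicted SS length (", length(ss2$ss3),
         ") does not match sequence length (", n, ")")
  if (length(torsions$phi) != n || length(torsions$psi) != n)
    stop("predicted torsion length does not match sequence length")
  structure(list(sequence = sequence,
                 aa = strsplit(sequence, "")[[1]],
                 pred_ss3 = ss2$ss3,
                 conf = ss2$conf,
                 pred_phi = wrap_angle(torsions$phi),
                 pred_psi = wrap_angle(torsions$psi),
                 homolog_ids = if (is.null(hits)) character(0) else
                   read_homolog_hits(hits, prob_threshold)),
            class = "target_profile")
}

#' @export
print.target_profile <- function(x, ...) {
  cat("<target_profile> ", nchar(x$sequence), " residues, ",
      length(x$homolog_ids), " homolog(s) flagged\n", sep = "")
  cat("  seq: ", abbrev_str(x$sequence), "\n", sep = "")
  cat("  ss:  ", abbrev_str(paste(x$pred_ss3, collapse = "")), "\n", sep = "")
  invisible(x)
}

.ss_classes <- c("alpha", "beta", "loop", "other")

#' Secondary-structure class of a fragment window
#'
#' A window is majority alpha-helical / beta-strand / loop when strictly
#' more than half of its predicted letters are H / E / C respectively;
#' windows with no strict majority are class "other". The class drives the
#' per-class acceptance cutoffs and the threading majority-alpha exclusion.
#'
#' @param profile a `target_profile`.
#' @param pos 1-based window start.
#' @param len window length; the window covers positions
#'   `pos..pos+len-1`.
#' @return one of `"alpha"`, `"beta"`, `"loop"`, `"other"`.
#' @export
ss_class_of_window <- function(profile, pos, len) {
  n <- length(profile$pred_ss3)
  if (pos < 1L || len < 1L || pos + len - 1L > n)
    stop("window [", pos, ", ", pos + len - 1L,
         "] out of range for target of length ", n)
  ss_class_of_letters(profile$pred_ss3[pos:(pos + len - 1L)])
}

ss_class_of_letters <- function(letters) {
  n <- length(letters)
  cnt <- c(H = sum(letters == "H"), E = sum(letters == "E"),
           C = sum(letters == "C"))
  top <- which.max(cnt)
  if (cnt[top] * 2L > n)
    c(H = "alpha", E = "beta", C = "loop")[[names(cnt)[top]]]
  else "other"
}
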