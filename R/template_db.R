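#' Pairwise sequence identity
#'
#' Global (Needleman-Wunsch) alignment with the BLOSUM62 scoring table and
#' gap open/extend penalties 11/1; identity is the number of identical
#' aligned positions divided by the alignment length (gaps included in the
#' denominator).
#'
#' @param seq_a,seq_b amino-acid strings.
#' @return identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global",
    substitutionMatrix = blosum62_matrix(),
    gapOpening = 11, gapExtension = 1)
  Biostrings::pid(aln, type = "PID1") / 100
}

.matrix_cache <- new.env(parent = emptyenv())

blosum62_matrix <- function() {
  if (is.null(.matrix_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .matrix_cache$blosum62 <- e$BLOSUM62
  }
  .matrix_cache$blosum62
}

# Make a chain usable as a template entry: torsions, Ramachandran regions
# and 3-state SS must all be present.
prepare_template <- function(chain, dssp_string = NULL,
                             regions = default_rama_regions()) {
  if (all(is.na(chain$phi)) && length(chain$aa) > 1L)
    chain <- compute_backbone_torsions(chain, regions)
  if (all(is.na(chain$ss3)))
    chain <- assign_ss3(chain, dssp_string)
  chain
}

#' Build a culled template database
#'
#' Entries with resolution worse than `resolution_cutoff` are removed;
#' then, processing chains best resolution first (ties broken by id),
#' any chain with more than `identity_cutoff` sequence identity to an
#' already-retained chain is removed (greedy culling, so the
#' better-resolution member of an over-identical pair survives). Chains
#' without a resolution (synthetic fixtures) count as resolution 0 and are
#' always retained by the resolution filter.
#'
#' @param chains list of [chain_structure]; torsions/SS are computed here
#'   if absent.
#' @param resolution_cutoff maximum resolution in Angstroms (default 5.0).
#' @param identity_cutoff maximum pairwise identity fraction (default 0.90).
#' @return a `template_db`: list of entries plus culling provenance.
#' @export
build_database <- function(chains, resolution_cutoff = 5.0,
                           identity_cutoff = 0.90) {
  if (length(chains) == 0L) {
    warning("no input chains: empty template database")
    return(new_template_db(list(), resolution_cutoff, identity_cutoff))
  }
  chains <- lapply(chains, prepare_template)
  res <- vapply(chains, function(ch)
    if (is.na(ch$resolution)) 0 else ch$resolution, numeric(1))
  ids <- vapply(chains, `[[`, character(1), "id")
  chains <- chains[res <= resolution_cutoff]
  ids <- ids[res <= resolution_cutoff]
  res <- res[res <= resolution_cutoff]
  ord <- order(res, ids)
  chains <- chains[ord]; ids <- ids[ord]
  kept <- list()
  for (i in seq_along(chains)) {
    dup <- FALSE
    for (k in kept) {
      if (pairwise_identity(chains[[i]]$sequence, k$sequence) >
          identity_cutoff) { dup <- TRUE; break }
    }
    if (!dup) kept[[length(kept) + 1L]] <- chains[[i]]
  }
  new_template_db(kept, resolution_cutoff, identity_cutoff)
}

new_template_db <- function(entries, resolution_cutoff, identity_cutoff) {
  names(entries) <- vapply(entries, `[[`, character(1), "id")
  structure(list(entries = entries,
                 provenance = list(resolution_cutoff = resolution_cutoff,
                                   identity_cutoff = identity_cutoff)),
            class = "template_db")
}

#' @export
print.template_db <- function(x, ...) {
  cat("<template_db> ", length(x$entries), " entries (culled at ",
      x$provenance$resolution_cutoff, " A resolution, ",
      round(100 * x$provenance$identity_cutoff), "% identity)\n", sep = "")
  for (e in utils::head(x$entries, 8))
    cat("  ", e$id, ": ", length(e$aa), " res\n", sep = "")
  if (length(x$entries) > 8) cat("  ...\n")
  invisible(x)
}

.db_format_version <- "fraglibdb 1"

#' Save / load a template database
#'
#' Single-file plain-text archive: a versioned header with the culling
#' provenance, then one record per entry carrying its sequence, 3-state SS
#' string, Ramachandran-region string, torsions and backbone coordinates.
#' The round-trip is lossless (coordinates and angles are stored with full
#' double precision).
#'
#' @param db a `template_db`.
#' @param path file path.
#' @return `save_database` returns `path` invisibly; `load_database`
#'   returns the `template_db`.
#' @export
save_database <- function(db, path) {
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) paste(ifelse(is.na(x), "NA", sprintf("%.17g", x)),
                           collapse = ",")
  writeLines(c(paste("#", .db_format_version),
               paste("#resolution_cutoff", db$provenance$resolution_cutoff),
               paste("#identity_cutoff", db$provenance$identity_cutoff),
               paste("#n_entries", length(db$entries))), con)
  for (e in db$entries) {
    writeLines(c(paste0(">", e$id, " ",
                        ifelse(is.na(e$resolution), "NA", e$resolution)),
                 e$sequence,
                 paste(ifelse(is.na(e$ss3), "C", e$ss3), collapse = ""),
                 rama_string(e$rama),
                 num(e$phi), num(e$psi),
                 num(as.vector(e$n)), num(as.vector(e$ca)),
                 num(as.vector(e$c)),
                 paste(e$segment, collapse = ","),
                 paste(e$resno, collapse = ",")), con)
  }
  invisible(path)
}

#' @rdname save_database
#' @export
load_database <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4L || lines[1] != paste("#", .db_format_version))
    stop("not a ", .db_format_version, " file: ", path)
  getnum <- function(i, key) {
    parts <- strsplit(lines[i], " ")[[1]]
    if (parts[1] != paste0("#", key)) stop("malformed header at line ", i)
    as.numeric(parts[2])
  }
  rc <- getnum(2, "resolution_cutoff")
  ic <- getnum(3, "identity_cutoff")
  nent <- getnum(4, "n_entries")
  entries <- vector("list", nent)
  i <- 5L
  parse_nums <- function(ln) {
    if (ln > length(lines))
      stop("truncated database file at line ", ln)
    tok <- trimws(strsplit(lines[ln], ",")[[1]])
    v <- suppressWarnings(as.numeric(tok))
    if (any(is.na(v) & tok != "NA"))
      stop("malformed numeric field at line ", ln)
    v
  }
  for (k in seq_len(nent)) {
    if (i > length(lines) || !startsWith(lines[i], ">"))
      stop("truncated database file at line ", i)
    hdr <- strsplit(sub("^>", "", lines[i]), " ")[[1]]
    id <- hdr[1]
    resolution <- suppressWarnings(as.numeric(hdr[2]))
    seq <- lines[i + 1L]
    ss3 <- strsplit(lines[i + 2L], "")[[1]]
    rama_ch <- strsplit(lines[i + 3L], "")[[1]]
    rama <- suppressWarnings(as.integer(rama_ch))
    phi <- parse_nums(i + 4L); psi <- parse_nums(i + 5L)
    nres <- nchar(seq)
    if (length(phi) != nres || length(rama) != nres)
      stop("malformed entry '", id, "' at line ", i)
    nmat <- matrix(parse_nums(i + 6L), nres, 3)
    camat <- matrix(parse_nums(i + 7L), nres, 3)
    cmat <- matrix(parse_nums(i + 8L), nres, 3)
    segment <- as.integer(strsplit(lines[i + 9L], ",")[[1]])
    resno <- as.integer(strsplit(lines[i + 10L], ",")[[1]])
    entries[[k]] <- new_chain_structure(
      id = id, aa = strsplit(seq, "")[[1]], n = nmat, ca = camat, c = cmat,
      resolution = resolution, segment = segment, resno = resno,
      phi = phi, psi = psi, ss3 = ss3, rama = rama)
    i <- i + 11L
  }
  new_template_db(entries, rc, ic)
}
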