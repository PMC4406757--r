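#' Environment-specific substitution matrices
#'
#' The sequence component of fragment scoring uses one 20x20 log-odds
#' substitution table per Ramachandran region ("environment"), so an
#' amino-acid pairing is scored in the context of the local backbone
#' conformation of the template residue. Tables are built BLOSUM-style from
#' environment-labelled alignment columns ([build_env_matrices()]); the
#' packaged default ([default_env_matrices()]) is seven copies of BLOSUM62
#' (half-bit units), a conformation-agnostic starting point users can
#' replace with matrices trained on their own alignments.
#'
#' @name env_matrices
NULL

new_env_matrices <- function(tables, labels, scale) {
  stopifnot(length(tables) == 7L)
  structure(list(tables = tables, labels = labels, scale = scale),
            class = "env_matrices")
}

#' @export
print.env_matrices <- function(x, ...) {
  cat("<env_matrices> 7 environment tables (20x20, scale ", x$scale,
      " per bit)\n", sep = "")
  for (i in 1:7)
    cat("  ", i, " ", x$labels[i], ": entries in [",
        min(x$tables[[i]]), ", ", max(x$tables[[i]]), "]\n", sep = "")
  invisible(x)
}

#' Default environment matrix set
#'
#' Seven copies of BLOSUM62 restricted to the 20 standard amino acids.
#'
#' @return an `env_matrices` object.
#' @export
default_env_matrices <- function() {
  if (is.null(.matrix_cache$default_env)) {
    aa <- strsplit(.aa_alphabet, "")[[1]]
    b62 <- blosum62_matrix()[aa, aa]
    .matrix_cache$default_env <- new_env_matrices(
      tables = rep(list(b62), 7L),
      labels = default_rama_regions()$label[match(1:7, default_rama_regions()$region)],
      scale = 2)
  }
  .matrix_cache$default_env
}

#' Build environment-specific substitution matrices from labelled columns
#'
#' BLOSUM-style construction: within every alignment column all unordered
#' residue pairs are counted toward the column's environment; per
#' environment, the score for pair (a, b) is
#' `round(scale * log2(P(a,b) / (p_a * p_b * (2 - delta_ab))))` where
#' `P(a,b)` are the observed pair frequencies and `p_a` the implied
#' single-residue frequencies. Pairs never observed in an environment get
#' `floor`. Environments with no columns at all get a neutral (all-zero)
#' table, with a warning.
#'
#' @param columns data.frame with columns `region` (1..7) and `residues`
#'   (a string of >= 2 amino acids per alignment column).
#' @param scale log-odds scale (2 = half-bit units, the default).
#' @param floor score assigned to unobserved pairs.
#' @return an `env_matrices` object.
#' @export
build_env_matrices <- function(columns, scale = 2, floor = -4) {
  if (is.null(columns) || nrow(columns) == 0L)
    stop("no labelled columns supplied")
  if (any(nchar(columns$residues) < 2L))
    stop("every column needs at least 2 residues")
  aa <- strsplit(.aa_alphabet, "")[[1]]
  tables <- vector("list", 7L)
  missing_env <- integer(0)
  for (e in 1:7) {
    cols <- columns$residues[columns$region == e]
    if (!length(cols)) { missing_env <- c(missing_env, e); next }
    f <- matrix(0, 20, 20, dimnames = list(aa, aa))
    for (s in cols) {
      r <- strsplit(s, "")[[1]]
      r <- r[r %in% aa]
      if (length(r) < 2L) next
      pr <- utils::combn(r, 2)
      for (k in seq_len(ncol(pr))) {
        a <- pr[1, k]; b <- pr[2, k]
        f[a, b] <- f[a, b] + 1
        if (a != b) f[b, a] <- f[b, a] + 1
      }
    }
    total <- (sum(f) + sum(diag(f))) / 2   # unordered pair count
    if (total == 0) { missing_env <- c(missing_env, e); next }
    # f is symmetric with c(a,b) stored at both [a,b] and [b,a]; the
    # diagonal holds c(a,a) once, so f/total is the unordered P(a,b)
    pab <- f / total
    p <- rowSums(f + diag(diag(f))) / (2 * total)
    expct <- outer(p, p) * (2 - diag(20))
    sc <- matrix(floor, 20, 20, dimnames = list(aa, aa))
    obs <- pab > 0 & expct > 0
    sc[obs] <- round(scale * log2(pab[obs] / expct[obs]))
    tables[[e]] <- sc
  }
  if (length(missing_env) == 7L) stop("no environment has any pair counts")
  if (length(missing_env)) {
    warning("environments with no columns set to neutral table: ",
            paste(missing_env, collapse = ","))
    neutral <- matrix(0L, 20, 20, dimnames = list(aa, aa))
    for (e in missing_env) tables[[e]] <- neutral
  }
  new_env_matrices(tables, labels = paste0("env", 1:7), scale = scale)
}

#' Write / read an environment matrix file
#'
#' Plain-text format, one block per environment: a header line
#' `ENV <index> <label> scale <scale>`, a column-header row of amino
#' acids, then 20 rows of integers. Round-trips exactly.
#'
#' @param mats an `env_matrices` object.
#' @param path file path.
#' @export
write_env_matrices <- function(mats, path) {
  con <- file(path, "w")
  on.exit(close(con))
  aa <- strsplit(.aa_alphabet, "")[[1]]
  writeLines("# fraglib environment substitution matrices v1", con)
  for (e in 1:7) {
    writeLines(sprintf("ENV %d %s scale %s", e, mats$labels[e],
                       format(mats$scale)), con)
    writeLines(paste(c(" ", aa), collapse = "\t"), con)
    tb <- mats$tables[[e]]
    for (a in aa)
      writeLines(paste(c(a, tb[a, aa]), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_env_matrices
#' @export
read_env_matrices <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "# fraglib environment substitution matrices"))
    stop("not an environment matrix file: ", path)
  aa <- strsplit(.aa_alphabet, "")[[1]]
  starts <- grep("^ENV ", lines)
  if (length(starts) != 7L) stop("expected 7 ENV blocks, found ",
                                 length(starts))
  tables <- vector("list", 7L)
  labels <- character(7)
  scale <- NA_real_
  for (s in starts) {
    hdr <- strsplit(lines[s], " ")[[1]]
    e <- as.integer(hdr[2]); labels[e] <- hdr[3]
    scale <- as.numeric(hdr[5])
    tb <- matrix(NA_real_, 20, 20, dimnames = list(aa, aa))
    for (r in 1:20) {
      row <- strsplit(lines[s + 1L + r], "\t")[[1]]
      tb[row[1], ] <- as.numeric(row[-1])
    }
    tables[[e]] <- tb
  }
  new_env_matrices(tables, labels, scale)
}

# 21 x 21 x 8 lookup array: dims = (target aa, fragment aa, region).
# Index 21 = 'X' (scores 0); region 8 = neutral environment for undefined
# torsions (scores 0).
env_matrix_array <- function(mats) {
  arr <- array(0, dim = c(21, 21, 8))
  for (e in 1:7) arr[1:20, 1:20, e] <- mats$tables[[e]]
  arr
}

# amino-acid letter -> index 1..21 (X and anything unknown -> 21)
aa_index <- function(letters) {
  i <- match(letters, strsplit(.aa_alphabet, "")[[1]])
  i[is.na(i)] <- 21L
  i
}
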