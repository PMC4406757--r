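#' RMSD of a fragment to the native window it represents
#'
#' Superposes the fragment's Calpha trace onto the native residues
#' `pos..pos+len-1` (matched through the native chain's residue numbers)
#' and returns the optimal-superposition RMSD. When any native residue of
#' the window is missing the fragment is unevaluable and `NA` is returned
#' — never a silent 0.
#'
#' @param ca fragment Calpha coordinates (L x 3 matrix).
#' @param pos 1-based target position of the fragment window.
#' @param native the native [chain_structure].
#' @return RMSD in Angstroms, or `NA` if unevaluable.
#' @export
fragment_rmsd_to_native <- function(ca, pos, native) {
  len <- nrow(ca)
  rows <- match(pos:(pos + len - 1L), native$resno)
  if (anyNA(rows)) return(NA_real_)
  superpose_rmsd(ca, native$ca[rows, , drop = FALSE])
}

#' Per-fragment RMSDs of a whole library
#'
#' @param lib a `fragment_library`.
#' @param native the native [chain_structure].
#' @param db template database supplying fragment coordinates (not needed
#'   for libraries that carry their own coordinates).
#' @return numeric vector, one RMSD per library row (`NA` = unevaluable).
#' @export
library_rmsds <- function(lib, native, db = NULL) {
  vapply(seq_len(nrow(lib$frags)), function(i)
    fragment_rmsd_to_native(frag_ca(lib, i, db), lib$frags$pos[i], native),
    numeric(1))
}

#' Library precision
#'
#' Fraction of evaluable fragments whose RMSD to the native window is
#' strictly below the cutoff. Unevaluable fragments (native gaps) are
#' excluded from numerator and denominator.
#'
#' @inheritParams library_rmsds
#' @param cutoff good-fragment RMSD cutoff in Angstroms.
#' @param rmsds optional precomputed result of [library_rmsds()].
#' @return fraction in `[0, 1]` (`NaN` for an empty library).
#' @export
precision <- function(lib, native, cutoff, db = NULL, rmsds = NULL) {
  if (is.null(rmsds)) rmsds <- library_rmsds(lib, native, db)
  r <- rmsds[!is.na(rmsds)]
  if (!length(r)) return(NaN)
  mean(r < cutoff)
}

#' Library coverage
#'
#' Fraction of target residues contained in the window of at least one
#' good (below-cutoff) fragment.
#'
#' @inheritParams precision
#' @return fraction in `[0, 1]`.
#' @export
coverage <- function(lib, native, cutoff, db = NULL, rmsds = NULL) {
  if (is.null(rmsds)) rmsds <- library_rmsds(lib, native, db)
  good <- which(!is.na(rmsds) & rmsds < cutoff)
  covered <- logical(lib$target_len)
  for (i in good) {
    f <- lib$frags[i, ]
    covered[f$pos:(f$pos + f$len - 1L)] <- TRUE
  }
  mean(covered)
}

#' Precision/coverage curves over an RMSD-cutoff grid
#'
#' Computes precision and coverage at every cutoff of the grid, overall
#' and stratified by the SS class of each fragment's window, along with
#' the best fragment RMSD per target position.
#'
#' @inheritParams library_rmsds
#' @param grid RMSD cutoffs in Angstroms (default 0.1 to 2.0 by 0.1).
#' @param profile optional `target_profile` used to (re)derive window SS
#'   classes; by default the classes stored in the library are used.
#' @return a `flib_eval` object: `overall` and `by_class` data.frames,
#'   `best_per_position`, fragment counts and the evaluated stage.
#' @export
evaluate_curves <- function(lib, native, db = NULL,
                            grid = seq(0.1, 2.0, by = 0.1),
                            profile = NULL) {
  rmsds <- library_rmsds(lib, native, db)
  f <- lib$frags
  cls <- if (!is.null(profile)) ss_class_vec(profile, f$pos, f$len)
  else f$ss_class
  overall <- data.frame(
    cutoff = grid,
    precision = vapply(grid, function(cc)
      precision(lib, native, cc, rmsds = rmsds), numeric(1)),
    coverage = vapply(grid, function(cc)
      coverage(lib, native, cc, rmsds = rmsds), numeric(1)))
  by_class <- do.call(rbind, lapply(.ss_classes, function(cl) {
    rows <- which(!is.na(cls) & cls == cl)
    sub <- lib
    sub$frags <- f[rows, , drop = FALSE]
    rc <- rmsds[rows]
    data.frame(class = cl, cutoff = grid,
               n = length(rows),
               precision = vapply(grid, function(cc)
                 precision(sub, native, cc, rmsds = rc), numeric(1)),
               coverage = vapply(grid, function(cc)
                 coverage(sub, native, cc, rmsds = rc), numeric(1)))
  }))
  pos_all <- modelable_positions(lib$target_len)
  best <- vapply(pos_all, function(p) {
    r <- rmsds[f$pos == p]
    r <- r[!is.na(r)]
    if (length(r)) min(r) else NA_real_
  }, numeric(1))
  structure(list(overall = overall, by_class = by_class,
                 best_per_position =
                   stats::setNames(best, pos_all),
                 rmsds = rmsds,
                 n_fragments = nrow(f),
                 n_unevaluable = sum(is.na(rmsds)),
                 mean_per_position = nrow(f) / max(length(pos_all), 1),
                 mean_length = if (nrow(f)) mean(f$len) else NA_real_,
                 stage = lib$stage),
            class = "flib_eval")
}

#' @export
print.flib_eval <- function(x, ...) {
  cat("<flib_eval> stage ", x$stage, ": ", x$n_fragments, " fragments (",
      x$n_unevaluable, " unevaluable)\n", sep = "")
  cat("  mean fragments/position ", round(x$mean_per_position, 1),
      ", mean length ", round(x$mean_length, 1), "\n", sep = "")
  show <- x$overall[x$overall$cutoff %in% c(0.5, 1.0, 1.5, 2.0), ]
  for (i in seq_len(nrow(show)))
    cat(sprintf("  cutoff %.1f A: precision %5.1f%%  coverage %5.1f%%\n",
                show$cutoff[i], 100 * show$precision[i],
                100 * show$coverage[i]))
  invisible(x)
}

#' @export
plot.flib_eval <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$overall$cutoff, 100 * x$overall$precision, type = "b",
                 pch = 16, xlab = "good-fragment RMSD cutoff (A)",
                 ylab = "precision (%)", ylim = c(0, 100),
                 main = paste("precision,", x$stage), ...)
  graphics::plot(x$overall$cutoff, 100 * x$overall$coverage, type = "b",
                 pch = 16, xlab = "good-fragment RMSD cutoff (A)",
                 ylab = "coverage (%)", ylim = c(0, 100),
                 main = paste("coverage,", x$stage), ...)
  invisible(x)
}

#' One-sided two-sample Kolmogorov-Smirnov test
#'
#' Tests whether the empirical CDF of `sample_a` lies above that of
#' `sample_b` (i.e. `sample_a` is stochastically smaller — here, lower
#' fragment RMSDs). The statistic is `sup_x (F_a(x) - F_b(x))` with its
#' asymptotic p-value.
#'
#' @param sample_a,sample_b numeric vectors (e.g. RMSD distributions).
#' @return list with `statistic` and `p_value`.
#' @export
ks_one_sided <- function(sample_a, sample_b) {
  k <- suppressWarnings(stats::ks.test(sample_a, sample_b,
                                       alternative = "greater"))
  list(statistic = unname(k$statistic), p_value = unname(k$p.value))
}

#' Read a Rosetta-style fragment file
#'
#' Parses the classic fragment-file dialect: `position: <n> neighbors:
#' <m>` headers, then per-residue rows `pdbid chain resno aa ss phi psi
#' omega ...` with blank lines separating fragments. Calpha coordinates
#' are reconstructed from the recorded torsions with the idealized-
#' geometry chain builder so RMSD evaluation is possible.
#'
#' @param path fragment file.
#' @param target_len target length (default: inferred from the largest
#'   position + fragment length).
#' @return a `fragment_library` (stage `EXTERNAL`) carrying its own
#'   coordinates.
#' @export
read_rosetta_fragments <- function(path, target_len = NULL) {
  lines <- readLines(path)
  frags <- list(); coords <- list()
  pos <- NA_integer_
  cur <- list()
  flush_frag <- function() {
    if (!length(cur)) return()
    df <- do.call(rbind, cur)
    ch <- build_chain_from_torsions(df$phi, df$psi,
                                    sequence = paste(df$aa, collapse = ""),
                                    omega = df$omega[-nrow(df)])
    i <- length(frags) + 1L
    frags[[i]] <<- data.frame(
      pos = pos, len = nrow(df),
      template = paste0(df$pdb[1], "_", df$chain[1]),
      tstart = df$resno[1], origin = "EXTERNAL",
      ss_class = NA_character_, score_rama = NA_real_,
      score_ss = NA_real_, score_tors = NA_real_, hit_score = NA_real_,
      stringsAsFactors = FALSE)
    coords[[i]] <<- ch$ca
    cur <<- list()
  }
  for (ln in seq_along(lines)) {
    l <- lines[ln]
    if (grepl("^\\s*position:", l)) {
      flush_frag()
      pos <- as.integer(sub(".*position:\\s*(\\d+).*", "\\1", l))
      next
    }
    if (!nzchar(trimws(l))) { flush_frag(); next }
    p <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(p) < 8L)
      stop("malformed fragment row at line ", ln, " of ", path)
    ang <- suppressWarnings(as.numeric(p[6:8]))
    if (anyNA(ang))
      stop("non-numeric torsion at line ", ln, " of ", path)
    cur[[length(cur) + 1L]] <- data.frame(
      pdb = p[1], chain = p[2], resno = as.integer(p[3]), aa = p[4],
      ss = p[5], phi = ang[1], psi = ang[2], omega = ang[3],
      stringsAsFactors = FALSE)
  }
  flush_frag()
  if (!length(frags)) stop("no fragments found in ", path)
  f <- do.call(rbind, frags)
  if (is.null(target_len)) target_len <- max(f$pos + f$len - 1L)
  new_fragment_library(f, "EXTERNAL", target_len, coords = coords)
}
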