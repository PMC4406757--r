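#' Ramachandran-specific sequence score
#'
#' Sum over window positions of the substitution score between the target
#' residue and the fragment residue, looked up in the environment table of
#' the fragment residue's Ramachandran region. Undefined regions (fragment
#' termini) use a neutral all-zero table. Higher is better.
#'
#' @param target_seq target window residues (string or character vector).
#' @param frag_seq fragment residues (same length).
#' @param frag_regions fragment Ramachandran region indices (1..7 or `NA`).
#' @param matrices an `env_matrices` set (default [default_env_matrices()]).
#' @return numeric score (sum over the window).
#' @export
rama_sequence_score <- function(target_seq, frag_seq, frag_regions,
                                matrices = default_env_matrices()) {
  t_aa <- if (length(target_seq) == 1L && nchar(target_seq[1]) > 1L)
    strsplit(target_seq, "")[[1]] else target_seq
  f_aa <- if (length(frag_seq) == 1L && nchar(frag_seq[1]) > 1L)
    strsplit(frag_seq, "")[[1]] else frag_seq
  if (length(t_aa) != length(f_aa) ||
      length(f_aa) != length(frag_regions))
    stop("window length mismatch")
  arr <- env_matrix_array(matrices)
  r <- ifelse(is.na(frag_regions), 8L, frag_regions)
  sum(arr[cbind(aa_index(t_aa), aa_index(f_aa), r)])
}

#' Secondary-structure match score
#'
#' Pairwise comparison of the target window's predicted 3-state secondary
#' structure against the fragment's known secondary structure:
#' match = +2, mismatch = -2, summed over the window.
#'
#' @param pred_ss target window predicted letters (string or vector, H/E/C).
#' @param frag_ss fragment letters (same length).
#' @return integer score in `[-2L, 2L]` per residue, summed.
#' @export
ss_score <- function(pred_ss, frag_ss) {
  a <- if (length(pred_ss) == 1L && nchar(pred_ss[1]) > 1L)
    strsplit(pred_ss, "")[[1]] else pred_ss
  b <- if (length(frag_ss) == 1L && nchar(frag_ss[1]) > 1L)
    strsplit(frag_ss, "")[[1]] else frag_ss
  if (length(a) != length(b)) stop("window length mismatch")
  if (!all(c(a, b) %in% c("H", "E", "C")))
    stop("secondary-structure letters must be H, E or C")
  sum(ifelse(a == b, 2L, -2L))
}

#' Predicted torsion-angle score
#'
#' Sum over the window of the circular absolute differences between the
#' target's predicted and the fragment's actual phi angles, plus the same
#' for psi. Lower is better (0 = perfect agreement). Undefined fragment
#' torsions (segment termini) contribute 0.
#'
#' @param pred_phi,pred_psi predicted angles for the target window
#'   (degrees).
#' @param frag_phi,frag_psi fragment angles (same length; `NA` allowed).
#' @return non-negative score in degrees.
#' @export
torsion_score <- function(pred_phi, pred_psi, frag_phi, frag_psi) {
  n <- length(pred_phi)
  if (length(pred_psi) != n || length(frag_phi) != n ||
      length(frag_psi) != n)
    stop("window length mismatch")
  dphi <- angle_diff(pred_phi, frag_phi)
  dpsi <- angle_diff(pred_psi, frag_psi)
  sum(dphi[!is.na(dphi)]) + sum(dpsi[!is.na(dpsi)])
}

# ---- vectorized scoring used by the extraction stages -------------------
#
# Candidates are described by parallel vectors (entry index, start, len,
# target pos). Scores are computed by expanding per-residue index vectors
# once and summing with rowsum(); this keeps random extraction at its
# default 5000 draws/position tractable in pure R.

# db_codes: precomputed per-entry integer views
db_codes <- function(db) {
  lapply(db$entries, function(e) list(
    aa = aa_index(e$aa),
    ss = match(e$ss3, c("H", "E", "C")),
    rama = ifelse(is.na(e$rama), 8L, e$rama),
    phi = e$phi, psi = e$psi))
}

# batch rama_seq + ss (+ optionally torsion) scores for candidate tuples
score_candidates <- function(cand, codes, profile, arr,
                             with_torsion = FALSE) {
  n <- nrow(cand)
  if (n == 0L)
    return(cbind(rama = numeric(0), ss = numeric(0),
                 tors = if (with_torsion) numeric(0)))
  lens <- cand$len
  tot <- sum(lens)
  cid <- rep.int(seq_len(n), lens)
  off <- sequence(lens) - 1L
  tpos <- rep.int(cand$pos, lens) + off
  fpos <- rep.int(cand$tstart, lens) + off
  ent <- rep.int(cand$entry, lens)
  t_aa <- aa_index(profile$aa)[tpos]
  t_ss <- match(profile$pred_ss3, c("H", "E", "C"))[tpos]
  # gather fragment-side codes entry by entry
  f_aa <- integer(tot); f_ss <- integer(tot); f_rama <- integer(tot)
  if (with_torsion) { f_phi <- numeric(tot); f_psi <- numeric(tot) }
  for (e in unique(ent)) {
    k <- which(ent == e)
    cd <- codes[[e]]
    f_aa[k] <- cd$aa[fpos[k]]
    f_ss[k] <- cd$ss[fpos[k]]
    f_rama[k] <- cd$rama[fpos[k]]
    if (with_torsion) {
      f_phi[k] <- cd$phi[fpos[k]]
      f_psi[k] <- cd$psi[fpos[k]]
    }
  }
  rama <- rowsum(arr[cbind(t_aa, f_aa, f_rama)], cid, reorder = TRUE)[, 1]
  ss <- rowsum(ifelse(t_ss == f_ss, 2, -2), cid, reorder = TRUE)[, 1]
  out <- cbind(rama = rama, ss = ss)
  if (with_torsion) {
    dphi <- angle_diff(profile$pred_phi[tpos], f_phi)
    dpsi <- angle_diff(profile$pred_psi[tpos], f_psi)
    d <- ifelse(is.na(dphi), 0, dphi) + ifelse(is.na(dpsi), 0, dpsi)
    out <- cbind(out, tors = rowsum(d, cid, reorder = TRUE)[, 1])
  }
  out
}
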