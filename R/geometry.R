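#' Circular absolute difference between two angles
#'
#' Difference on the circle, in degrees: `min(|a - b|, 360 - |a - b|)`.
#' A pair like (-179, +179) is 2 degrees apart, not 358. `NA` in either
#' argument yields `NA`.
#'
#' @param a,b angles in degrees (vectors recycle).
#' @return non-negative difference in degrees, in `[0, 180]`.
#' @export
angle_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# wrap angles into (-180, 180]
wrap_angle <- function(x) {
  w <- ((x + 180) %% 360) - 180
  ifelse(!is.na(w) & w == -180, 180, w)
}

#' Optimal-superposition RMSD over Calpha coordinates
#'
#' Minimum root-mean-square deviation between two equal-length point sets
#' over all rigid-body motions (proper rotations + translations), computed
#' by the closed-form Kabsch algorithm (SVD of the cross-covariance with a
#' determinant correction so reflections are never used).
#'
#' @param a,b numeric n x 3 matrices of coordinates in Angstroms.
#' @return RMSD in Angstroms.
#' @export
superpose_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != 3L || ncol(b) != 3L)
    stop("coordinate matrices must have 3 columns")
  n <- nrow(a)
  if (n != nrow(b)) stop("coordinate sets differ in length")
  if (n < 1L) stop("need at least one point")
  if (anyNA(a) || anyNA(b)) stop("coordinates contain NA")
  if (n == 1L) return(0)
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  h <- crossprod(ac, bc)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  # rotate a onto b with a proper rotation
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  ar <- ac %*% t(rot)
  sqrt(sum((ar - bc)^2) / n)
}

# Place atom D given positions of A, B, C, the bond length C-D, the bond
# angle B-C-D (degrees) and the dihedral A-B-C-D (degrees). Standard
# internal-to-Cartesian (NeRF-style) construction.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  tor <- dihedral * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) stop("colinear atoms: dihedral frame undefined")
  n <- n / nn
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + cbind(bc, m, n) %*% d2
}

# Canonical backbone geometry (Engh-Huber-like idealized values)
.bb_geom <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
  a_n_ca_c = 111.0, a_ca_c_n = 116.6, a_c_n_ca = 121.9
)

#' Build an idealized backbone from torsion angles
#'
#' Places N, Calpha and C atoms for each residue from the requested phi/psi
#' (and optionally omega) torsions using canonical bond lengths
#' (N-Ca 1.458, Ca-C 1.525, C-N 1.329 Angstroms) and bond angles, by the
#' standard internal-to-Cartesian chain construction. The first residue's
#' phi and the last residue's psi are ignored (they are undefined).
#'
#' @param phi,psi numeric vectors of torsions in degrees, one per residue.
#' @param sequence one-letter amino-acid string (defaults to poly-alanine).
#' @param omega peptide-bond torsions (length n-1 or scalar; default 180).
#' @param id chain identifier for the returned object.
#' @param resolution nominal resolution in Angstroms (`NA` = unknown).
#' @return a [chain_structure] with `n`, `ca`, `c` coordinates filled and
#'   torsions computed back from the coordinates.
#' @export
build_chain_from_torsions <- function(phi, psi, sequence = NULL,
                                      omega = 180, id = "synth_A",
                                      resolution = NA_real_) {
  nres <- length(phi)
  if (length(psi) != nres) stop("phi and psi lengths differ")
  if (nres < 1L) stop("empty chain")
  if (is.null(sequence)) sequence <- paste(rep("A", nres), collapse = "")
  aa <- strsplit(sequence, "")[[1]]
  if (length(aa) != nres) stop("sequence length does not match torsions")
  om <- rep_len(omega, max(nres - 1L, 1L))
  g <- .bb_geom
  n <- ca <- cc <- matrix(NA_real_, nres, 3)
  n[1, ] <- c(0, 0, 0)
  ca[1, ] <- c(g$b_n_ca, 0, 0)
  # first C: any position at the right bond angle; use a fixed frame
  a0 <- g$a_n_ca_c * pi / 180
  cc[1, ] <- ca[1, ] + g$b_ca_c * c(-cos(a0), sin(a0), 0)
  if (nres > 1L) {
    for (i in 2:nres) {
      n[i, ]  <- place_atom(n[i - 1, ], ca[i - 1, ], cc[i - 1, ],
                            g$b_c_n, g$a_ca_c_n, psi[i - 1])
      ca[i, ] <- place_atom(ca[i - 1, ], cc[i - 1, ], n[i, ],
                            g$b_n_ca, g$a_c_n_ca, om[i - 1])
      cc[i, ] <- place_atom(cc[i - 1, ], n[i, ], ca[i, ],
                            g$b_ca_c, g$a_n_ca_c, phi[i])
    }
  }
  ch <- new_chain_structure(id = id, aa = aa, n = n, ca = ca, c = cc,
                            resolution = resolution,
                            segment = rep(1L, nres),
                            resno = seq_len(nres))
  compute_backbone_torsions(ch)
}
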