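#' @importFrom bio3d read.pdb write.pdb torsion.xyz aa321 rmsd
NULL

# Internal constructor. `segment` marks contiguous runs of residues: a
# fragment window must never span two segments (chain breaks).
new_chain_structure <- function(id, aa, n, ca, c, resolution = NA_real_,
                                segment = rep(1L, length(aa)),
                                resno = seq_along(aa),
                                phi = rep(NA_real_, length(aa)),
                                psi = rep(NA_real_, length(aa)),
                                ss3 = rep(NA_character_, length(aa)),
                                rama = rep(NA_integer_, length(aa))) {
  nres <- length(aa)
  stopifnot(nrow(n) == nres, nrow(ca) == nres, nrow(c) == nres,
            length(segment) == nres, length(resno) == nres)
  structure(list(id = id, aa = aa,
                 sequence = paste(aa, collapse = ""),
                 n = n, ca = ca, c = c,
                 resolution = resolution, segment = segment, resno = resno,
                 phi = phi, psi = psi, ss3 = ss3, rama = rama),
            class = "chain_structure")
}

#' @export
print.chain_structure <- function(x, ...) {
  cat("<chain_structure> ", x$id, ": ", length(x$aa), " residues, ",
      length(unique(x$segment)), " segment(s)",
      if (!is.na(x$resolution)) sprintf(", %.2f A", x$resolution), "\n",
      sep = "")
  cat("  seq:  ", abbrev_str(x$sequence), "\n", sep = "")
  if (!all(is.na(x$ss3)))
    cat("  ss3:  ", abbrev_str(paste(x$ss3, collapse = "")), "\n", sep = "")
  if (!all(is.na(x$rama)))
    cat("  rama: ", abbrev_str(rama_string(x$rama)), "\n", sep = "")
  invisible(x)
}

abbrev_str <- function(s, width = 60) {
  if (nchar(s) > width) paste0(substr(s, 1, width - 3), "...") else s
}

#' @export
length.chain_structure <- function(x) length(x$aa)

#' Read one protein chain from a PDB file
#'
#' Reads ATOM records (first model; altloc blank or 'A') for the requested
#' chain and keeps only residues with complete N, Calpha and C backbone
#' atoms. Chain breaks — gaps in residue numbering or residues dropped for
#' missing atoms — split the chain into segments; no fragment window is
#' ever cut across a segment boundary. Non-standard residues are mapped to
#' 'X' (or dropped with `nonstandard = "skip"`, which also records a break).
#'
#' @param path PDB-format file.
#' @param chain_id one-character chain identifier.
#' @param nonstandard `"x"` (map to X, default) or `"skip"` (drop residue).
#' @return a [chain_structure].
#' @export
read_pdb_chain <- function(path, chain_id = "A", nonstandard = c("x", "skip")) {
  nonstandard <- match.arg(nonstandard)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!chain_id %in% unique(at$chain))
    stop("chain '", chain_id, "' not found in ", path)
  at <- at[at$chain == chain_id, , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  reskey <- paste(at$resno, at$insert)
  keys <- unique(reskey)
  res <- vector("list", length(keys))
  for (i in seq_along(keys)) {
    rows <- at[reskey == keys[i], , drop = FALSE]
    get1 <- function(el) {
      j <- which(rows$elety == el)[1]
      if (is.na(j)) NULL else c(rows$x[j], rows$y[j], rows$z[j])
    }
    aa1 <- bio3d::aa321(rows$resid[1])
    if (is.na(aa1) || !nzchar(aa1)) aa1 <- "X"
    res[[i]] <- list(resno = rows$resno[1], aa = aa1,
                     n = get1("N"), ca = get1("CA"), c = get1("C"))
  }
  complete <- vapply(res, function(r) {
    !is.null(r$n) && !is.null(r$ca) && !is.null(r$c)
  }, logical(1))
  if (nonstandard == "skip")
    complete <- complete & vapply(res, function(r) r$aa != "X", logical(1))
  dropped <- any(!complete)
  res <- res[complete]
  if (length(res) == 0L)
    stop("chain '", chain_id, "' in ", path,
         " has no residues with complete N/CA/C backbone")
  resno <- vapply(res, `[[`, numeric(1), "resno")
  ord <- order(resno)
  res <- res[ord]; resno <- resno[ord]
  segment <- cumsum(c(1L, as.integer(diff(resno) != 1)))
  resolution <- NA_real_
  if (!is.null(pdb$header) && !is.null(pdb$header$resolution)) {
    r <- suppressWarnings(as.numeric(pdb$header$resolution))
    if (length(r) && is.finite(r[1])) resolution <- r[1]
  }
  ch <- new_chain_structure(
    id = paste0(basename_noext(path), "_", chain_id),
    aa = vapply(res, `[[`, character(1), "aa"),
    n = do.call(rbind, lapply(res, `[[`, "n")),
    ca = do.call(rbind, lapply(res, `[[`, "ca")),
    c = do.call(rbind, lapply(res, `[[`, "c")),
    resolution = resolution, segment = segment, resno = as.integer(resno))
  if (dropped)
    attr(ch, "n_dropped") <- sum(!complete)
  ch
}

basename_noext <- function(path) sub("\\.[^.]*$", "", basename(path))

#' Compute backbone phi/psi torsions
#'
#' Standard dihedral definitions: phi(i) over C(i-1)-N(i)-Ca(i)-C(i),
#' psi(i) over N(i)-Ca(i)-C(i)-N(i+1). The first residue's phi and the last
#' residue's psi of every contiguous segment are undefined (`NA`); a
#' degenerate (colinear) atom arrangement also yields `NA` with a warning.
#' Angles are reported in degrees in (-180, 180]. Ramachandran regions are
#' filled in alongside.
#'
#' @param chain a [chain_structure] with backbone coordinates.
#' @param regions region map for [classify_rama_region()].
#' @return the chain with `phi`, `psi` and `rama` filled.
#' @export
compute_backbone_torsions <- function(chain, regions = default_rama_regions()) {
  nres <- length(chain$aa)
  phi <- psi <- rep(NA_real_, nres)
  for (seg in unique(chain$segment)) {
    idx <- which(chain$segment == seg)
    m <- length(idx)
    if (m < 2L) next
    xyz <- matrix(NA_real_, 3L * m, 3L)
    xyz[seq(1, 3 * m, by = 3), ] <- chain$n[idx, , drop = FALSE]
    xyz[seq(2, 3 * m, by = 3), ] <- chain$ca[idx, , drop = FALSE]
    xyz[seq(3, 3 * m, by = 3), ] <- chain$c[idx, , drop = FALSE]
    tors <- suppressWarnings(
      bio3d::torsion.xyz(as.vector(t(xyz)), atm.inc = 1))
    # atoms of residue j (within segment) are 3j-2 (N), 3j-1 (Ca), 3j (C);
    # tors[k] is the dihedral of atoms k-1..k+2, so phi(j) = tors[3j-2]
    # (atoms 3j-3..3j) and psi(j) = tors[3j-1] (atoms 3j-2..3j+1)
    for (j in seq_len(m)) {
      if (j > 1L) phi[idx[j]] <- tors[3L * j - 2L]
      if (j < m) psi[idx[j]] <- tors[3L * j - 1L]
    }
  }
  bad <- (!is.na(phi) & !is.finite(phi)) | (!is.na(psi) & !is.finite(psi))
  if (any(bad, na.rm = TRUE))
    warning("degenerate (colinear) backbone geometry at ",
            sum(bad, na.rm = TRUE), " residue(s); torsions set to NA")
  phi[!is.finite(phi)] <- NA_real_
  psi[!is.finite(psi)] <- NA_real_
  chain$phi <- wrap_angle(phi)
  chain$psi <- wrap_angle(psi)
  chain$rama <- classify_rama_region(chain$phi, chain$psi, regions)
  chain
}

#' Assign 3-state secondary structure
#'
#' With a DSSP 8-state string, applies the standard 8-to-3 reduction
#' (H, G, I to H; E, B to E; everything else, including space, to C). With
#' no DSSP string a torsion-based fallback is used (intended for idealized
#' synthetic chains): runs of at least 4 consecutive helical-region
#' residues (Ramachandran regions 1-2) become H, runs of at least 3
#' strand-region residues (regions 3-4) become E, all else C. Runs never
#' cross segment boundaries.
#'
#' @param chain a [chain_structure]; the fallback requires torsions
#'   (see [compute_backbone_torsions()]).
#' @param dssp_string optional 8-state string, same length as the chain.
#' @return the chain with `ss3` filled (letters in H/E/C).
#' @export
assign_ss3 <- function(chain, dssp_string = NULL) {
  nres <- length(chain$aa)
  if (!is.null(dssp_string)) {
    s <- strsplit(dssp_string, "")[[1]]
    if (length(s) != nres)
      stop("dssp_string length (", length(s),
           ") does not match chain length (", nres, ")")
    ss <- rep("C", nres)
    ss[s %in% c("H", "G", "I")] <- "H"
    ss[s %in% c("E", "B")] <- "E"
  } else {
    if (all(is.na(chain$rama)) && nres > 2L)
      chain <- compute_backbone_torsions(chain)
    helical <- !is.na(chain$rama) & chain$rama %in% c(1L, 2L)
    strand  <- !is.na(chain$rama) & chain$rama %in% c(3L, 4L)
    ss <- rep("C", nres)
    ss[run_at_least(helical, 4L, chain$segment)] <- "H"
    ss[run_at_least(strand, 3L, chain$segment)] <- "E"
  }
  chain$ss3 <- ss
  chain
}

# TRUE at positions belonging to a within-segment run of `flag` of length
# >= minlen
run_at_least <- function(flag, minlen, segment) {
  out <- logical(length(flag))
  r <- rle(paste0(as.integer(flag), "_", segment))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- startsWith(r$values, "1_") & r$lengths >= minlen
  for (k in which(keep)) out[starts[k]:ends[k]] <- TRUE
  out
}

# Valid fragment-window start positions of length L in a chain: window must
# lie in one segment and contain no 'X' residue.
valid_window_starts <- function(chain, len) {
  nres <- length(chain$aa)
  if (len > nres) return(integer(0))
  ok <- chain$aa != "X"
  starts <- seq_len(nres - len + 1L)
  keep <- vapply(starts, function(s) {
    i <- s:(s + len - 1L)
    all(ok[i]) && chain$segment[s] == chain$segment[s + len - 1L]
  }, logical(1))
  starts[keep]
}

#' Write a chain as a PDB file
#'
#' Writes the N/Ca/C backbone (ATOM records) so that [read_pdb_chain()]
#' round-trips the chain.
#'
#' @param chain a [chain_structure].
#' @param path output file.
#' @param chain_id chain identifier letter to stamp.
#' @return `path`, invisibly.
#' @export
write_chain_pdb <- function(chain, path, chain_id = "A") {
  nres <- length(chain$aa)
  xyz <- matrix(NA_real_, 3L * nres, 3L)
  xyz[seq(1, 3 * nres, by = 3), ] <- chain$n
  xyz[seq(2, 3 * nres, by = 3), ] <- chain$ca
  xyz[seq(3, 3 * nres, by = 3), ] <- chain$c
  aa3 <- vapply(chain$aa, function(a) {
    r <- bio3d::aa123(a)
    if (is.na(r)) "UNK" else r
  }, character(1))
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(xyz)),
                   resno = rep(chain$resno, each = 3L),
                   resid = rep(aa3, each = 3L),
                   elety = rep(c("N", "CA", "C"), nres),
                   chain = rep(chain_id, 3L * nres))
  invisible(path)
}
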