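# Shared fixtures and independent oracles.

# Brute-force rotation-grid RMSD oracle: align centroids, scan Euler
# angles on a coarse grid, then refine twice around the best rotation.
# Independent of the SVD-based implementation.
oracle_rmsd_grid <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  rotmat <- function(z1, y, z2) {
    cz1 <- cos(z1); sz1 <- sin(z1); cy <- cos(y); sy <- sin(y)
    cz2 <- cos(z2); sz2 <- sin(z2)
    rz1 <- matrix(c(cz1, -sz1, 0, sz1, cz1, 0, 0, 0, 1), 3, byrow = TRUE)
    ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    rz2 <- matrix(c(cz2, -sz2, 0, sz2, cz2, 0, 0, 0, 1), 3, byrow = TRUE)
    rz1 %*% ry %*% rz2
  }
  eval_rot <- function(z1, y, z2) {
    d <- ac %*% t(rotmat(z1, y, z2)) - bc
    sqrt(sum(d^2) / nrow(a))
  }
  best <- c(0, 0, 0); bestv <- eval_rot(0, 0, 0)
  step <- pi / 9   # 20 degrees
  centre <- c(pi, pi / 2, pi)
  span <- c(pi, pi / 2, pi)
  for (stage in 1:4) {
    g1 <- seq(centre[1] - span[1], centre[1] + span[1], by = step)
    g2 <- seq(centre[2] - span[2], centre[2] + span[2], by = step)
    g3 <- seq(centre[3] - span[3], centre[3] + span[3], by = step)
    for (z1 in g1) for (y in g2) for (z2 in g3) {
      v <- eval_rot(z1, y, z2)
      if (v < bestv) { bestv <- v; best <- c(z1, y, z2) }
    }
    centre <- best
    span <- rep(step * 1.5, 3)
    step <- step / 6
  }
  bestv
}

# Naive recount oracles for precision / coverage on a table of
# (pos, len, rmsd) rows.
naive_precision <- function(tab, cutoff) {
  r <- tab$rmsd[!is.na(tab$rmsd)]
  if (!length(r)) return(NaN)
  sum(r < cutoff) / length(r)
}

naive_coverage <- function(tab, cutoff, target_len) {
  covered <- rep(FALSE, target_len)
  for (i in seq_len(nrow(tab))) {
    if (!is.na(tab$rmsd[i]) && tab$rmsd[i] < cutoff)
      covered[tab$pos[i]:(tab$pos[i] + tab$len[i] - 1)] <- TRUE
  }
  sum(covered) / target_len
}

# One-sided two-sample KS statistic by direct ECDF sweep.
naive_ks_greater <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  max(vapply(xs, function(x) mean(a <= x) - mean(b <= x), numeric(1)))
}

# A tiny template database of idealized chains (native optionally
# included first).
tiny_db <- function(native = NULL, n_decoys = 2, len = 25, seed = 42) {
  chains <- make_decoy_set(n_decoys, len = len, seed = seed)
  if (!is.null(native)) chains <- c(list(native), chains)
  build_database(chains)
}

# A small zero-noise study case shared across extraction tests.
small_case <- function(seed = 1, n_decoys = 3) {
  ss <- paste0(strrep("H", 10), strrep("C", 4), strrep("E", 6),
               strrep("C", 4), strrep("H", 8))
  native <- make_ideal_chain(ss, seed = seed, id = "native_A")
  pred <- make_predictions(native, seed = seed + 1)
  profile <- target_profile(native$sequence,
                            list(ss3 = pred$ss3, conf = pred$conf),
                            list(phi = pred$phi, psi = pred$psi))
  chains <- c(list(native),
              make_decoy_set(n_decoys, len = nchar(ss), seed = seed + 2))
  list(native = native, profile = profile, db = build_database(chains))
}

# Write a PDB file holding two idealized chains A and B in one file.
write_two_chain_pdb <- function(path, len_a = 8, len_b = 6, seed = 3) {
  cha <- make_ideal_chain(strrep("H", len_a), seed = seed)
  chb <- make_ideal_chain(strrep("E", len_b), seed = seed + 1)
  xyz <- function(ch) {
    m <- matrix(NA_real_, 3 * length(ch$aa), 3)
    m[seq(1, nrow(m), 3), ] <- ch$n
    m[seq(2, nrow(m), 3), ] <- ch$ca
    m[seq(3, nrow(m), 3), ] <- ch$c
    m
  }
  coords <- rbind(xyz(cha), xyz(chb) + 50)
  na <- length(cha$aa); nb <- length(chb$aa)
  bio3d::write.pdb(
    file = path, xyz = as.vector(t(coords)),
    resno = c(rep(seq_len(na), each = 3), rep(seq_len(nb), each = 3)),
    resid = rep("ALA", 3 * (na + nb)),
    elety = rep(c("N", "CA", "C"), na + nb),
    chain = c(rep("A", 3 * na), rep("B", 3 * nb)))
  invisible(list(a = cha, b = chb))
}
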