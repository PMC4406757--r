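# Synthetic fixture generation: idealized chains built from canonical
# torsions, prediction files with configurable error models, decoy
# template sets and threading hit lists. Everything the pipeline consumes
# can be generated here, so the full pipeline runs without any external
# structure or prediction server.

.canonical_torsions <- list(H = c(phi = -57, psi = -47),
                            E = c(phi = -139, psi = 135))

# Permitted loop torsion set: conformations outside the helical (1-2) and
# strand (3-4) Ramachandran regions, so secondary-structure classes stay
# separable in fixtures (polyproline-II, left-handed helical, and two
# "other" conformations).
.loop_torsions <- matrix(c(-75, 150,
                           60, 45,
                           140, 160,
                           75, -150), ncol = 2, byrow = TRUE,
                         dimnames = list(NULL, c("phi", "psi")))

#' Build an idealized chain for a secondary-structure string
#'
#' Helical residues get canonical helix torsions (-57, -47), strand
#' residues canonical strand torsions (-139, 135), loop residues a
#' conformation sampled from a permitted set excluding the helical and
#' strand Ramachandran regions. Gaussian torsion noise of `noise_sd`
#' degrees is added on top. Deterministic under `seed`.
#'
#' @param ss_string string over H/E/C.
#' @param noise_sd torsion noise standard deviation in degrees.
#' @param seed integer seed.
#' @param id chain identifier.
#' @param sequence amino-acid string (default: random standard letters).
#' @param resolution resolution to stamp on the chain (default `NA`).
#' @return a [chain_structure] with torsions, regions and SS assigned.
#' @export
make_ideal_chain <- function(ss_string, noise_sd = 0, seed = 1,
                             id = "fixture_A", sequence = NULL,
                             resolution = NA_real_) {
  ss <- strsplit(ss_string, "")[[1]]
  if (!all(ss %in% c("H", "E", "C")))
    stop("ss_string must use letters H/E/C")
  n <- length(ss)
  set.seed(seed)
  if (is.null(sequence))
    sequence <- paste(sample(strsplit(.aa_alphabet, "")[[1]], n,
                             replace = TRUE), collapse = "")
  phi <- psi <- numeric(n)
  for (i in seq_len(n)) {
    if (ss[i] %in% names(.canonical_torsions)) {
      phi[i] <- .canonical_torsions[[ss[i]]]["phi"]
      psi[i] <- .canonical_torsions[[ss[i]]]["psi"]
    } else {
      k <- sample.int(nrow(.loop_torsions), 1L)
      phi[i] <- .loop_torsions[k, "phi"]
      psi[i] <- .loop_torsions[k, "psi"]
    }
  }
  if (noise_sd > 0) {
    phi <- wrap_angle(phi + stats::rnorm(n, 0, noise_sd))
    psi <- wrap_angle(psi + stats::rnorm(n, 0, noise_sd))
  }
  ch <- build_chain_from_torsions(phi, psi, sequence = sequence, id = id,
                                  resolution = resolution)
  assign_ss3(ch)
}

#' Generate prediction files for a chain
#'
#' With a zero error model the predicted secondary structure equals the
#' chain's assigned SS and the predicted torsions equal its true
#' torsions. With `flip_rate > 0` each SS letter is changed to a
#' different random letter with that probability; with `torsion_sd > 0`
#' wrapped Gaussian noise is added to the angles. Undefined terminal
#' torsions are emitted as the canonical value for the residue's SS
#' letter. Reproducible under `seed`.
#'
#' @param chain a [chain_structure] with `ss3` and torsions assigned.
#' @param flip_rate per-residue SS error probability.
#' @param torsion_sd torsion noise SD in degrees.
#' @param seed integer seed.
#' @param ss2_path,torsions_path optional output files (PSIPRED ss2 style
#'   and SPINE-X-style tabular).
#' @return list with `ss3`, `conf`, `phi`, `psi` (readable back through
#'   [read_psipred_ss2()] / [read_torsion_predictions()] when written).
#' @export
make_predictions <- function(chain, flip_rate = 0, torsion_sd = 0,
                             seed = 1, ss2_path = NULL,
                             torsions_path = NULL) {
  n <- length(chain$aa)
  if (all(is.na(chain$ss3))) stop("chain has no assigned SS")
  set.seed(seed)
  ss <- chain$ss3
  if (flip_rate > 0) {
    flip <- stats::runif(n) < flip_rate
    for (i in which(flip))
      ss[i] <- sample(setdiff(c("H", "E", "C"), ss[i]), 1L)
  }
  canon_for <- function(letter, comp) {
    if (letter %in% names(.canonical_torsions))
      .canonical_torsions[[letter]][comp]
    else .loop_torsions[1, comp]
  }
  phi <- chain$phi; psi <- chain$psi
  for (i in seq_len(n)) {
    if (is.na(phi[i])) phi[i] <- canon_for(chain$ss3[i], "phi")
    if (is.na(psi[i])) psi[i] <- canon_for(chain$ss3[i], "psi")
  }
  if (torsion_sd > 0) {
    phi <- wrap_angle(phi + stats::rnorm(n, 0, torsion_sd))
    psi <- wrap_angle(psi + stats::rnorm(n, 0, torsion_sd))
  }
  conf <- matrix(0.05, n, 3, dimnames = list(NULL, c("C", "H", "E")))
  conf[cbind(seq_len(n), match(ss, c("C", "H", "E")))] <- 0.9
  if (!is.null(ss2_path)) {
    con <- file(ss2_path, "w")
    writeLines(c("# PSF format remark line", ""), con)
    writeLines(sprintf("%4d %s %s  %6.3f %6.3f %6.3f",
                       seq_len(n), chain$aa, ss,
                       conf[, "C"], conf[, "H"], conf[, "E"]), con)
    close(con)
  }
  if (!is.null(torsions_path))
    writeLines(c("# idx aa phi psi",
                 sprintf("%4d %s %9.3f %9.3f", seq_len(n), chain$aa,
                         phi, psi)), torsions_path)
  list(ss3 = ss, conf = conf, phi = phi, psi = psi)
}

#' Generate a set of decoy template chains
#'
#' Random secondary-structure layouts (alternating runs of helix, strand
#' and loop with random lengths) realized as idealized chains; useful as
#' background templates in a synthetic database.
#'
#' @param n_decoys number of chains.
#' @param len residues per chain.
#' @param seed integer seed.
#' @param noise_sd torsion noise SD in degrees.
#' @return list of [chain_structure].
#' @export
make_decoy_set <- function(n_decoys, len = 60L, seed = 1, noise_sd = 0) {
  set.seed(seed)
  specs <- replicate(n_decoys, {
    ss <- character(0)
    while (length(ss) < len) {
      el <- sample(c("H", "E", "C"), 1L)
      run <- sample(switch(el, H = 5:10, E = 4:7, C = 3:6), 1L)
      ss <- c(ss, rep(el, run))
    }
    paste(ss[seq_len(len)], collapse = "")
  })
  seeds <- sample.int(1e6, n_decoys)
  lapply(seq_len(n_decoys), function(i)
    make_ideal_chain(specs[i], noise_sd = noise_sd, seed = seeds[i],
                     id = sprintf("decoy%02d_A", i)))
}

#' Generate a synthetic threading hit list
#'
#' One hit per requested probability: a window of the chosen template is
#' aligned gaplessly to a target window, producing a valid input for
#' [hits_to_fragments()]. Hit scores decrease with rank. Optionally
#' written as the TSV hit dialect.
#'
#' @param target_len target sequence length.
#' @param db `template_db` the hits refer into.
#' @param probabilities hit probabilities in percent, one hit each.
#' @param seed integer seed.
#' @param block_len aligned block length (default 20, capped to fit).
#' @param path optional TSV output file.
#' @return a `threading_hits` object.
#' @export
make_threading_hits <- function(target_len, db, probabilities, seed = 1,
                                block_len = 20L, path = NULL) {
  set.seed(seed)
  ids <- names(db$entries)
  hits <- list(); blocks <- list()
  for (k in seq_along(probabilities)) {
    id <- ids[1L + (k - 1L) %% length(ids)]
    e <- db$entries[[id]]
    bl <- min(block_len, length(e$aa), target_len)
    ts <- sample.int(length(e$aa) - bl + 1L, 1L)
    qs <- sample.int(target_len - bl + 1L, 1L)
    hits[[k]] <- data.frame(id = id, prob = probabilities[k],
                            score = 200 - 10 * (k - 1L),
                            stringsAsFactors = FALSE)
    blocks[[k]] <- data.frame(hit = k, target_start = qs,
                              template_start = ts, len = bl)
  }
  th <- new_threading_hits(do.call(rbind, hits), do.call(rbind, blocks))
  if (!is.null(path)) write_threading_tsv(th, path)
  th
}

#' Generate a complete synthetic study case
#'
#' A mixed-secondary-structure target with the stated number of decoy
#' templates, the native chain optionally planted in the database, and
#' prediction files under the given error model. This is the package's
#' standard test condition: a 60-residue target (helix - loop - strand -
#' loop - helix layout) with 10 decoys.
#'
#' @param target_ss target secondary-structure string.
#' @param n_decoys decoy templates in the database.
#' @param plant_native include the native chain among the templates.
#' @param flip_rate,torsion_sd prediction error model.
#' @param seed integer seed.
#' @return list with `native`, `profile`, `db` and `config`-ready pieces.
#' @export
make_fixture_case <- function(target_ss = paste0(
  strrep("H", 14), strrep("C", 5), strrep("E", 8), strrep("C", 5),
  strrep("E", 8), strrep("C", 5), strrep("H", 15)),
  n_decoys = 10L, plant_native = TRUE,
  flip_rate = 0, torsion_sd = 0, seed = 1) {
  native <- make_ideal_chain(target_ss, seed = seed,
                             id = "native_A")
  pred <- make_predictions(native, flip_rate = flip_rate,
                           torsion_sd = torsion_sd, seed = seed + 1L)
  profile <- target_profile(native$sequence,
                            list(ss3 = pred$ss3, conf = pred$conf),
                            list(phi = pred$phi, psi = pred$psi))
  chains <- make_decoy_set(n_decoys, len = nchar(target_ss),
                           seed = seed + 2L)
  if (plant_native) chains <- c(list(native), chains)
  db <- build_database(chains)
  list(native = native, profile = profile, db = db)
}
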