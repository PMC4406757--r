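#' Random fragment extraction
#'
#' For every modelable target position, `n_random` fragments are drawn
#' from the non-homolog template entries: a uniform template, a uniform
#' length within the configured range (truncated so the window fits the
#' target) and a uniform valid start (windows never span a chain break or
#' contain an 'X' residue). Each draw is scored with the
#' Ramachandran-sequence and SS scores and retained only if both
#' per-residue scores meet the acceptance cutoff of the window's SS class.
#' Deterministic under the config seed.
#'
#' @param profile a `target_profile`.
#' @param db a `template_db`.
#' @param config a [flib_config()].
#' @param matrices environment substitution matrices.
#' @return a `fragment_library` at stage `RANDOM`.
#' @export
random_extract <- function(profile, db, config = flib_config(),
                           matrices = default_env_matrices()) {
  entries <- non_homolog_entries(db, profile)
  tlen <- nchar(profile$sequence)
  positions <- modelable_positions(tlen, config$len_range[1])
  empty <- new_fragment_library(frag_cols(), "RANDOM", tlen,
                                provenance = list(config = config))
  if (length(entries) == 0L || length(positions) == 0L) {
    warning("no usable templates or positions: empty RANDOM library")
    return(empty)
  }
  set.seed(config$seed)
  lmin <- config$len_range[1]; lmax <- config$len_range[2]
  vs <- valid_starts_index(entries, lmin, lmax)
  # candidate draw table: one block of n_random rows per position
  n_per <- config$n_random
  cand <- data.frame(
    pos = rep(positions, each = n_per),
    len = NA_integer_, entry = NA_integer_, tstart = NA_integer_)
  maxlen <- pmin(lmax, tlen - cand$pos + 1L)
  todo <- seq_len(nrow(cand))
  for (iter in 1:100) {
    if (!length(todo)) break
    cand$len[todo] <- lmin + floor(stats::runif(length(todo)) *
                                     (maxlen[todo] - lmin + 1L))
    cand$entry[todo] <- sample.int(length(entries), length(todo),
                                   replace = TRUE)
    grp <- split(todo, list(e = cand$entry[todo], l = cand$len[todo]),
                 drop = TRUE)
    bad <- integer(0)
    for (g in grp) {
      e <- cand$entry[g[1]]; l <- cand$len[g[1]]
      starts <- vs[[e]][[l]]
      if (length(starts) == 0L) { bad <- c(bad, g); next }
      cand$tstart[g] <- starts[ceiling(stats::runif(length(g)) *
                                         length(starts))]
    }
    todo <- sort(bad)
  }
  if (length(todo)) {
    warning("no valid windows for some draws; ", length(todo),
            " draws dropped")
    cand <- cand[-todo, , drop = FALSE]
  }
  codes <- db_codes_for(entries)
  sc <- score_candidates(cand, codes, profile, env_matrix_array(matrices))
  cls <- ss_class_vec(profile, cand$pos, cand$len)
  cut_r <- vapply(config$cutoffs, `[[`, numeric(1), "rama")[cls]
  cut_s <- vapply(config$cutoffs, `[[`, numeric(1), "ss")[cls]
  keep <- sc[, "rama"] / cand$len >= cut_r & sc[, "ss"] / cand$len >= cut_s
  ids <- vapply(entries, `[[`, character(1), "id")
  frags <- data.frame(pos = cand$pos[keep], len = cand$len[keep],
                      template = ids[cand$entry[keep]],
                      tstart = cand$tstart[keep],
                      origin = "RANDOM", ss_class = cls[keep],
                      score_rama = sc[keep, "rama"],
                      score_ss = sc[keep, "ss"],
                      score_tors = NA_real_, hit_score = NA_real_,
                      stringsAsFactors = FALSE)
  new_fragment_library(frags, "RANDOM", tlen,
                       provenance = list(config = config,
                                         n_drawn = nrow(cand)))
}

non_homolog_entries <- function(db, profile) {
  db$entries[!names(db$entries) %in% profile$homolog_ids]
}

valid_starts_index <- function(entries, lmin, lmax) {
  lapply(entries, function(e) {
    out <- vector("list", lmax)
    for (l in lmin:lmax) out[[l]] <- valid_window_starts(e, l)
    out
  })
}

db_codes_for <- function(entries) {
  lapply(entries, function(e) list(
    aa = aa_index(e$aa),
    ss = match(e$ss3, c("H", "E", "C")),
    rama = ifelse(is.na(e$rama), 8L, e$rama),
    phi = e$phi, psi = e$psi))
}

# vectorized window SS class from prefix sums of predicted letters
ss_class_vec <- function(profile, pos, len) {
  cH <- cumsum(c(0L, profile$pred_ss3 == "H"))
  cE <- cumsum(c(0L, profile$pred_ss3 == "E"))
  cC <- cumsum(c(0L, profile$pred_ss3 == "C"))
  e <- pos + len
  h <- cH[e] - cH[pos]; s <- cE[e] - cE[pos]; l <- cC[e] - cC[pos]
  out <- rep("other", length(pos))
  out[2L * h > len] <- "alpha"
  out[2L * s > len] <- "beta"
  out[2L * l > len] <- "loop"
  out
}

#' Exhaustive fragment extraction
#'
#' Scores every valid window (all configured lengths) of every non-homolog
#' template against every compatible target position with the combined
#' per-residue Ramachandran-sequence + SS score, and keeps the `top_k`
#' best per position. Ties are broken deterministically by
#' (score, template id, template start, length).
#'
#' @inheritParams random_extract
#' @return a `fragment_library` at stage `EXHAUSTIVE`.
#' @export
exhaustive_extract <- function(profile, db, config = flib_config(),
                               matrices = default_env_matrices()) {
  entries <- non_homolog_entries(db, profile)
  tlen <- nchar(profile$sequence)
  lmin <- config$len_range[1]; lmax <- config$len_range[2]
  empty <- new_fragment_library(frag_cols(), "EXHAUSTIVE", tlen,
                                provenance = list(config = config))
  if (length(entries) == 0L || tlen < lmin) {
    warning("no usable templates or positions: empty EXHAUSTIVE library")
    return(empty)
  }
  arr <- env_matrix_array(matrices)
  ids <- vapply(entries, `[[`, character(1), "id")
  t_aa <- aa_index(profile$aa)
  t_ss <- match(profile$pred_ss3, c("H", "E", "C"))
  cds <- db_codes_for(entries)
  chunks <- list()
  for (l in lmin:min(lmax, tlen)) {
    # all valid windows of length l across entries
    went <- integer(0); wstart <- integer(0)
    for (e in seq_along(entries)) {
      st <- valid_window_starts(entries[[e]], l)
      went <- c(went, rep.int(e, length(st)))
      wstart <- c(wstart, st)
    }
    W <- length(wstart)
    if (W == 0L) next
    P <- tlen - l + 1L
    f_aa <- f_ss <- f_rama <- matrix(NA_integer_, W, l)
    for (e in unique(went)) {
      rows <- which(went == e)
      idx <- outer(wstart[rows], 0:(l - 1L), `+`)
      f_aa[rows, ] <- cds[[e]]$aa[idx]
      f_ss[rows, ] <- cds[[e]]$ss[idx]
      f_rama[rows, ] <- cds[[e]]$rama[idx]
    }
    S <- matrix(0, P, W)
    for (i in seq_len(l)) {
      flat <- 21L * (f_aa[, i] - 1L) + 441L * (f_rama[, i] - 1L)
      m21 <- matrix(arr[rep(1:21, W) + rep(flat, each = 21L)], 21L, W)
      ti <- t_aa[seq_len(P) + i - 1L]
      S <- S + m21[ti, , drop = FALSE]
      m3 <- matrix(-2, 3, W)
      m3[cbind(f_ss[, i], seq_len(W))] <- 2
      S <- S + m3[t_ss[seq_len(P) + i - 1L], , drop = FALSE]
    }
    # per position keep top_k of this length (global top_k applied later)
    k <- min(config$top_k, W)
    for (p in seq_len(P)) {
      ord <- order(-S[p, ], ids[went], wstart)[seq_len(k)]
      chunks[[length(chunks) + 1L]] <- data.frame(
        pos = p, len = l, entry = went[ord], tstart = wstart[ord],
        comb = S[p, ord] / l, stringsAsFactors = FALSE)
    }
  }
  if (!length(chunks)) {
    warning("no valid windows in any template: empty EXHAUSTIVE library")
    return(empty)
  }
  all <- do.call(rbind, chunks)
  all$template <- ids[all$entry]
  ord <- order(all$pos, -all$comb, all$template, all$tstart, all$len)
  all <- all[ord, , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(all)), all$pos), function(ii)
    ii[seq_len(min(config$top_k, length(ii)))]), use.names = FALSE)
  all <- all[sort(keep), , drop = FALSE]
  # recover the separate rama / ss components for the kept rows
  codes <- db_codes_for(entries)
  sc <- score_candidates(all[c("pos", "len", "entry", "tstart")],
                         codes, profile, arr)
  frags <- data.frame(pos = all$pos, len = all$len,
                      template = all$template, tstart = all$tstart,
                      origin = "EXHAUSTIVE",
                      ss_class = ss_class_vec(profile, all$pos, all$len),
                      score_rama = sc[, "rama"], score_ss = sc[, "ss"],
                      score_tors = NA_real_, hit_score = NA_real_,
                      stringsAsFactors = FALSE)
  new_fragment_library(frags, "EXHAUSTIVE", tlen,
                       provenance = list(config = config))
}

#' Merge random and exhaustive libraries (LIB3000)
#'
#' Per-position concatenation with duplicate removal (same position,
#' template, start and length); the first occurrence's origin label is
#' kept.
#'
#' @param random_lib,exhaustive_lib fragment libraries for the same target.
#' @return a `fragment_library` at stage `LIB3000`.
#' @export
merge_to_lib3000 <- function(random_lib, exhaustive_lib) {
  stopifnot(random_lib$target_len == exhaustive_lib$target_len)
  f <- rbind(random_lib$frags, exhaustive_lib$frags)
  f <- f[!duplicated(frag_key(f)), , drop = FALSE]
  f <- f[order(f$pos, f$template, f$tstart, f$len), , drop = FALSE]
  new_fragment_library(f, "LIB3000", random_lib$target_len,
                       provenance = c(random_lib$provenance["config"],
                                      list(merged = TRUE)))
}

# fill in torsion scores for rows that lack them
add_torsion_scores <- function(lib, profile, db,
                               matrices = default_env_matrices()) {
  need <- which(is.na(lib$frags$score_tors))
  if (!length(need)) return(lib)
  f <- lib$frags[need, , drop = FALSE]
  entry <- match(f$template, names(db$entries))
  if (anyNA(entry)) stop("library references templates missing from db")
  cand <- data.frame(pos = f$pos, len = f$len, entry = entry,
                     tstart = f$tstart)
  sc <- score_candidates(cand, db_codes(db), profile,
                         env_matrix_array(matrices), with_torsion = TRUE)
  lib$frags$score_tors[need] <- sc[, "tors"]
  lib
}

#' Rank by torsion score (LIB20)
#'
#' Per position, fragments are sorted by ascending torsion score (lower is
#' better; per-residue by default, raw sums with `per_residue = FALSE`)
#' and the best `lib20_size` are kept. Ties break by
#' (template id, start, length).
#'
#' @param lib3000 merged library; torsion scores are computed here if
#'   absent.
#' @param profile the `target_profile`.
#' @param db the `template_db` the fragments came from.
#' @param config a [flib_config()].
#' @param matrices environment substitution matrices.
#' @return a `fragment_library` at stage `LIB20`.
#' @export
rank_to_lib20 <- function(lib3000, profile, db, config = flib_config(),
                          matrices = default_env_matrices()) {
  lib <- add_torsion_scores(lib3000, profile, db, matrices)
  f <- lib$frags
  key <- if (config$per_residue) f$score_tors / f$len else f$score_tors
  ord <- order(f$pos, key, f$template, f$tstart, f$len)
  f <- f[ord, , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(f)), f$pos), function(ii)
    ii[seq_len(min(config$lib20_size, length(ii)))]), use.names = FALSE)
  new_fragment_library(f[sort(keep), , drop = FALSE], "LIB20",
                       lib$target_len, provenance = lib$provenance)
}

#' Enrichment by similarity to the top-ranked fragment
#'
#' Per position, every fragment of the torsion-ranked pool (the
#' `pool_size` best by torsion score, or all of LIB3000 with
#' `enrich_pool = "lib3000"`) whose Calpha RMSD to the position's
#' top-ranked fragment is strictly below `enrich_rmsd` is added to LIB20.
#' Fragments of different lengths are compared over their shared target
#' span (at least `min_overlap` residues). Duplicates are removed.
#'
#' @param lib3000 the merged library (the enrichment pool source).
#' @param lib20 the torsion-ranked library to enrich.
#' @inheritParams rank_to_lib20
#' @return a `fragment_library` at stage `ENRICHED`.
#' @export
enrich <- function(lib3000, lib20, profile, db, config = flib_config(),
                   matrices = default_env_matrices()) {
  lib <- add_torsion_scores(lib3000, profile, db, matrices)
  f <- lib$frags
  key <- if (config$per_residue) f$score_tors / f$len else f$score_tors
  ord <- order(f$pos, key, f$template, f$tstart, f$len)
  f <- f[ord, , drop = FALSE]
  added <- list()
  for (p in unique(lib20$frags$pos)) {
    top1 <- lib20$frags[lib20$frags$pos == p, , drop = FALSE][1, ]
    ca1 <- frag_ca(lib20, which(lib20$frags$pos == p)[1], db)
    rows <- which(f$pos == p)
    if (config$enrich_pool == "pool")
      rows <- rows[seq_len(min(config$pool_size, length(rows)))]
    for (r in rows) {
      m <- min(f$len[r], top1$len)
      if (m < config$min_overlap) next
      e <- db$entries[[f$template[r]]]
      ca2 <- e$ca[f$tstart[r]:(f$tstart[r] + m - 1L), , drop = FALSE]
      if (superpose_rmsd(ca2, ca1[seq_len(m), , drop = FALSE]) <
          config$enrich_rmsd)
        added[[length(added) + 1L]] <- f[r, , drop = FALSE]
    }
  }
  out <- rbind(lib20$frags,
               if (length(added)) do.call(rbind, added))
  dup <- duplicated(frag_key(out))
  out$origin[!dup & seq_len(nrow(out)) > nrow(lib20$frags)] <- "ENRICHMENT"
  out <- out[!dup, , drop = FALSE]
  out <- out[order(out$pos, out$template, out$tstart, out$len), ,
             drop = FALSE]
  new_fragment_library(out, "ENRICHED", lib20$target_len,
                       provenance = lib20$provenance)
}

#' Calibrate per-class acceptance cutoffs
#'
#' Runs cutoff-free random extraction on each training target, measures
#' fragment RMSD to the native structure, and for every SS class and every
#' candidate cutoff on the grid computes the precision (fraction of
#' retained fragments below `good_cutoff`) and coverage (fraction of the
#' class's positions still represented by a good fragment). The chosen
#' cutoff is the one maximizing precision subject to coverage of at least
#' `coverage_floor` times the best achievable coverage for that class.
#'
#' @param training list of cases, each a list with elements `profile`,
#'   `native` (a [chain_structure]) and `db`.
#' @param rama_grid,ss_grid candidate per-residue cutoffs to sweep.
#' @param good_cutoff RMSD defining a good fragment (Angstroms).
#' @param coverage_floor fraction of achievable coverage to retain.
#' @param config base configuration (its cutoffs are ignored here).
#' @param matrices environment substitution matrices.
#' @return list with `cutoffs` (usable as the `cutoffs` config field) and
#'   a `report` data.frame of the full sweep.
#' @export
calibrate_cutoffs <- function(training, rama_grid, ss_grid = rama_grid,
                              good_cutoff = 1.0, coverage_floor = 0.99,
                              config = flib_config(),
                              matrices = default_env_matrices()) {
  if (!length(rama_grid) || !length(ss_grid)) stop("empty cutoff grid")
  open_cut <- list(alpha = c(rama = -Inf, ss = -Inf),
                   beta = c(rama = -Inf, ss = -Inf),
                   loop = c(rama = -Inf, ss = -Inf),
                   other = c(rama = -Inf, ss = -Inf))
  cases <- lapply(training, function(tc) {
    cfg <- config; cfg$cutoffs <- open_cut
    lib <- random_extract(tc$profile, tc$db, cfg, matrices)
    rmsd <- library_rmsds(lib, tc$native, tc$db)
    data.frame(cls = lib$frags$ss_class, pos = lib$frags$pos,
               len = lib$frags$len,
               rama_pr = lib$frags$score_rama / lib$frags$len,
               ss_pr = lib$frags$score_ss / lib$frags$len,
               good = !is.na(rmsd) & rmsd < good_cutoff)
  })
  df <- do.call(rbind, cases)
  report <- list()
  cutoffs <- list()
  for (cl in .ss_classes) {
    sub <- df[df$cls == cl, , drop = FALSE]
    if (!nrow(sub)) {
      cutoffs[[cl]] <- c(rama = -Inf, ss = -Inf)
      next
    }
    npos <- length(unique(sub$pos))
    best_cov <- length(unique(sub$pos[sub$good])) / npos
    sweep <- expand.grid(rama = rama_grid, ss = ss_grid)
    sweep$precision <- NA_real_; sweep$coverage <- NA_real_
    for (k in seq_len(nrow(sweep))) {
      keep <- sub$rama_pr >= sweep$rama[k] & sub$ss_pr >= sweep$ss[k]
      if (!any(keep)) { sweep$precision[k] <- 0; sweep$coverage[k] <- 0
      } else {
        sweep$precision[k] <- mean(sub$good[keep])
        sweep$coverage[k] <-
          length(unique(sub$pos[keep & sub$good])) / npos
      }
    }
    ok <- sweep$coverage >= coverage_floor * best_cov
    pick <- if (any(ok)) which(ok)[which.max(sweep$precision[ok])]
    else which.max(sweep$coverage)
    cutoffs[[cl]] <- c(rama = sweep$rama[pick], ss = sweep$ss[pick])
    sweep$class <- cl
    report[[cl]] <- sweep
  }
  list(cutoffs = cutoffs, report = do.call(rbind, report))
}
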