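case <- small_case()

test_that("random extraction is deterministic and honors homolog exclusion", {
  cfg <- flib_config(n_random = 200, seed = 91)
  lib1 <- random_extract(case$profile, case$db, cfg)
  lib2 <- random_extract(case$profile, case$db, cfg)
  expect_identical(lib1$frags, lib2$frags)
  expect_gt(nrow(lib1$frags), 0)

  # flag every template as homolog: nothing can be sampled
  prof_h <- case$profile
  prof_h$homolog_ids <- names(case$db$entries)
  expect_warning(libh <- random_extract(prof_h, case$db, cfg), "empty")
  expect_equal(nrow(libh$frags), 0L)
})

test_that("with cutoffs at -Inf every draw is retained (5000 per position)", {
  # short target so the full default draw count stays cheap
  ss <- strrep("H", 12)
  native <- make_ideal_chain(ss, seed = 2, id = "t_A")
  pred <- make_predictions(native, seed = 3)
  prof <- target_profile(native$sequence, list(ss3 = pred$ss3),
                         list(phi = pred$phi, psi = pred$psi))
  db <- tiny_db(native, n_decoys = 2, len = 25)
  open_cut <- lapply(setNames(nm = c("alpha", "beta", "loop", "other")),
                     function(cl) c(rama = -Inf, ss = -Inf))
  cfg <- flib_config(cutoffs = open_cut, seed = 5)   # n_random = 5000
  lib <- random_extract(prof, db, cfg)
  counts <- table(lib$frags$pos)
  expect_equal(unname(counts), rep(5000L, 7), ignore_attr = TRUE)
  expect_true(all(lib$frags$len >= 6 & lib$frags$len <= 20))
})

test_that("acceptance cutoffs remove exactly the under-scoring draws", {
  open_cut <- lapply(setNames(nm = c("alpha", "beta", "loop", "other")),
                     function(cl) c(rama = -Inf, ss = -Inf))
  cfg_open <- flib_config(n_random = 300, cutoffs = open_cut, seed = 7)
  cfg_def <- flib_config(n_random = 300, seed = 7)
  all_lib <- random_extract(case$profile, case$db, cfg_open)
  kept_lib <- random_extract(case$profile, case$db, cfg_def)
  cut <- cfg_def$cutoffs
  f <- all_lib$frags
  manual <- f[f$score_rama / f$len >=
                vapply(cut, `[[`, numeric(1), "rama")[f$ss_class] &
              f$score_ss / f$len >=
                vapply(cut, `[[`, numeric(1), "ss")[f$ss_class], ]
  expect_equal(sort(fraglib:::frag_key(manual)),
               sort(fraglib:::frag_key(kept_lib$frags)))
})

test_that("exhaustive extraction equals brute-force enumeration on a tiny db", {
  ss <- paste0(strrep("H", 8), strrep("C", 4), strrep("E", 6))
  native <- make_ideal_chain(ss, seed = 21, id = "t_A")
  pred <- make_predictions(native, seed = 22)
  prof <- target_profile(native$sequence, list(ss3 = pred$ss3),
                         list(phi = pred$phi, psi = pred$psi))
  db <- tiny_db(n_decoys = 2, len = 28, seed = 23)
  cfg <- flib_config(top_k = 10000000L, len_range = c(6, 10), seed = 1)
  lib <- exhaustive_extract(prof, db, cfg)

  # independent brute force: every window x every compatible position,
  # scored with the scalar scoring functions
  m <- default_env_matrices()
  tlen <- nchar(prof$sequence)
  brute <- list()
  for (e in db$entries) for (l in 6:10) {
    for (s in fraglib:::valid_window_starts(e, l)) {
      for (p in seq_len(tlen - l + 1)) {
        idx <- s:(s + l - 1)
        r <- rama_sequence_score(prof$aa[p:(p + l - 1)], e$aa[idx],
                                 e$rama[idx], m)
        sc <- ss_score(prof$pred_ss3[p:(p + l - 1)], e$ss3[idx])
        brute[[length(brute) + 1]] <- data.frame(
          pos = p, len = l, template = e$id, tstart = s,
          score_rama = r, score_ss = sc)
      }
    }
  }
  brute <- do.call(rbind, brute)
  keyb <- paste(brute$pos, brute$template, brute$tstart, brute$len)
  keyl <- paste(lib$frags$pos, lib$frags$template, lib$frags$tstart,
                lib$frags$len)
  expect_setequal(keyl, keyb)
  ord <- match(keyb, keyl)
  expect_equal(lib$frags$score_rama[ord], brute$score_rama)
  expect_equal(lib$frags$score_ss[ord], brute$score_ss)
})

test_that("exhaustive top_k keeps exactly the best-scoring fragments", {
  cfg <- flib_config(top_k = 25L, len_range = c(6, 9), seed = 1)
  lib <- exhaustive_extract(case$profile, case$db, cfg)
  counts <- table(lib$frags$pos)
  expect_true(all(counts <= 25))
  # at interior positions plenty of windows exist, so the cap binds
  expect_true(any(counts == 25))

  cfg_all <- flib_config(top_k = 10000000L, len_range = c(6, 9), seed = 1)
  lib_all <- exhaustive_extract(case$profile, case$db, cfg_all)
  for (p in c(1, 5, 10)) {
    kept <- lib$frags[lib$frags$pos == p, ]
    all_p <- lib_all$frags[lib_all$frags$pos == p, ]
    min_kept <- min((kept$score_rama + kept$score_ss) / kept$len)
    drop_keys <- setdiff(fraglib:::frag_key(all_p),
                         fraglib:::frag_key(kept))
    dropped <- all_p[fraglib:::frag_key(all_p) %in% drop_keys, ]
    if (nrow(dropped))
      expect_lte(max((dropped$score_rama + dropped$score_ss) /
                       dropped$len), min_kept)
  }
})

test_that("with the native planted and perfect predictions the native window ranks first", {
  cfg <- flib_config(top_k = 50L, seed = 1)
  lib <- exhaustive_extract(case$profile, case$db, cfg)
  l3 <- fraglib:::add_torsion_scores(lib, case$profile, case$db)
  l20 <- rank_to_lib20(l3, case$profile, case$db, cfg)
  for (p in c(1, 8, 15)) {
    top <- l20$frags[l20$frags$pos == p, ][1, ]
    expect_equal(top$score_tors, 0)
    # torsion score 0 means the fragment matches the native conformation
    ca <- fraglib:::frag_ca(l20, which(l20$frags$pos == p)[1], case$db)
    expect_lt(fragment_rmsd_to_native(ca, p, case$native), 1e-3)
  }
})

test_that("merging to LIB3000 removes duplicates and preserves origins", {
  cfg <- flib_config(n_random = 100, top_k = 50, seed = 31)
  rand <- random_extract(case$profile, case$db, cfg)
  exh <- exhaustive_extract(case$profile, case$db, cfg)
  merged <- merge_to_lib3000(rand, exh)
  expect_false(any(duplicated(fraglib:::frag_key(merged$frags))))
  expect_setequal(unique(merged$frags$origin), c("RANDOM", "EXHAUSTIVE"))

  same <- merge_to_lib3000(rand, rand)
  expect_equal(sort(fraglib:::frag_key(same$frags)),
               sort(unique(fraglib:::frag_key(rand$frags))))

  empty <- new_fragment_library(fraglib:::frag_cols(), "EXHAUSTIVE",
                                rand$target_len)
  expect_equal(nrow(merge_to_lib3000(rand, empty)$frags),
               length(unique(fraglib:::frag_key(rand$frags))))
})

test_that("LIB20 keeps the 20 lowest torsion scores with deterministic ties", {
  cfg <- flib_config(n_random = 400, top_k = 200, seed = 41)
  rand <- random_extract(case$profile, case$db, cfg)
  exh <- exhaustive_extract(case$profile, case$db, cfg)
  l3 <- fraglib:::add_torsion_scores(merge_to_lib3000(rand, exh),
                                     case$profile, case$db)
  l20 <- rank_to_lib20(l3, case$profile, case$db, cfg)
  expect_true(all(table(l20$frags$pos) <= 20))
  for (p in c(3, 12)) {
    kept <- l20$frags[l20$frags$pos == p, ]
    pool <- l3$frags[l3$frags$pos == p, ]
    drop_keys <- setdiff(fraglib:::frag_key(pool), fraglib:::frag_key(kept))
    dropped <- pool[fraglib:::frag_key(pool) %in% drop_keys, ]
    if (nrow(dropped) && nrow(kept) == 20)
      expect_lte(max(kept$score_tors / kept$len),
                 min(dropped$score_tors / dropped$len))
  }
  # under-populated positions keep everything
  few <- l3
  few$frags <- few$frags[few$frags$pos == 1, ][1:3, ]
  l20few <- rank_to_lib20(few, case$profile, case$db, cfg)
  expect_equal(nrow(l20few$frags), 3L)
})

test_that("enrichment adds pool fragments strictly below the RMSD threshold", {
  cfg <- flib_config(n_random = 200, top_k = 100, seed = 51,
                     lib20_size = 5)
  rand <- random_extract(case$profile, case$db, cfg)
  exh <- exhaustive_extract(case$profile, case$db, cfg)
  l3 <- fraglib:::add_torsion_scores(merge_to_lib3000(rand, exh),
                                     case$profile, case$db)
  l20 <- rank_to_lib20(l3, case$profile, case$db, cfg)
  enr <- enrich(l3, l20, case$profile, case$db, cfg)
  expect_true(all(fraglib:::frag_key(l20$frags) %in%
                    fraglib:::frag_key(enr$frags)))
  # every added fragment really is < 0.5 A from its position's top-1
  added <- enr$frags[enr$frags$origin == "ENRICHMENT", ]
  for (i in utils::head(seq_len(nrow(added)), 20)) {
    p <- added$pos[i]
    t1row <- which(l20$frags$pos == p)[1]
    ca1 <- fraglib:::frag_ca(l20, t1row, case$db)
    e <- case$db$entries[[added$template[i]]]
    m <- min(added$len[i], l20$frags$len[t1row])
    ca2 <- e$ca[added$tstart[i]:(added$tstart[i] + m - 1), , drop = FALSE]
    expect_lt(superpose_rmsd(ca2, ca1[seq_len(m), , drop = FALSE]), 0.5)
  }
})

test_that("enrichment threshold is strict and respects the overlap floor", {
  # constructed case: position 1, top-1 fragment is the native window;
  # pool contains fragments at known RMSDs
  ss <- strrep("H", 30)
  native <- make_ideal_chain(ss, seed = 61, id = "nat_A")
  pred <- make_predictions(native, seed = 62)
  prof <- target_profile(native$sequence, list(ss3 = pred$ss3),
                         list(phi = pred$phi, psi = pred$psi))
  # helical decoy with one perturbed residue: nonzero RMSD to native
  bent <- make_ideal_chain(paste0(strrep("H", 15), "C", strrep("H", 14)),
                           seed = 63, id = "bent_A")
  db <- build_database(list(native, bent))
  cfg <- flib_config(n_random = 50, top_k = 50, seed = 64,
                     len_range = c(6, 9))
  exh <- exhaustive_extract(prof, db, cfg)
  l3 <- fraglib:::add_torsion_scores(exh, prof, db)
  l20 <- rank_to_lib20(l3, prof, db, cfg)
  enr <- enrich(l3, l20, prof, db, cfg)
  added <- enr$frags[enr$frags$origin == "ENRICHMENT", ]
  for (i in seq_len(nrow(added))) {
    p <- added$pos[i]
    ca1 <- fraglib:::frag_ca(l20, which(l20$frags$pos == p)[1], db)
    e <- db$entries[[added$template[i]]]
    m <- min(added$len[i], nrow(ca1))
    expect_gte(m, cfg$min_overlap)
    rm <- superpose_rmsd(
      e$ca[added$tstart[i]:(added$tstart[i] + m - 1), , drop = FALSE],
      ca1[seq_len(m), , drop = FALSE])
    expect_lt(rm, 0.5)   # strictly below, never equal
  }
})

test_that("cutoff calibration picks sensible cutoffs in constructed scenarios", {
  # a grid of one cutoff: that cutoff is chosen
  tr <- list(small_case(seed = 71))
  one <- calibrate_cutoffs(tr, rama_grid = -1, ss_grid = 0,
                           config = flib_config(n_random = 100, seed = 72))
  for (cl in c("alpha", "beta", "loop"))
    expect_equal(unname(one$cutoffs[[cl]]), c(-1, 0))
  expect_error(calibrate_cutoffs(tr, rama_grid = numeric(0)), "empty")

  # coverage floor 0: global precision argmax
  free <- calibrate_cutoffs(tr, rama_grid = c(-2, 2), ss_grid = c(-2, 2),
                            coverage_floor = 0,
                            config = flib_config(n_random = 100, seed = 72))
  rep_a <- free$report[free$report$class == "alpha", ]
  pick <- free$cutoffs$alpha
  expect_equal(max(rep_a$precision),
               rep_a$precision[rep_a$rama == pick["rama"] &
                                 rep_a$ss == pick["ss"]])
})
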