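ev_case <- small_case(seed = 17)

test_that("fragment RMSD to native is zero for native windows, rigid copies", {
  nat <- ev_case$native
  ca <- nat$ca[5:13, ]
  expect_equal(fragment_rmsd_to_native(ca, 5, nat), 0)
  th <- 1.1
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, byrow = TRUE)
  expect_lt(fragment_rmsd_to_native(ca %*% t(rot) + 7, 5, nat), 1e-9)
})

test_that("a displaced-atom fragment matches the rotation-grid oracle", {
  nat <- ev_case$native
  ca <- nat$ca[5:13, ]
  ca[4, ] <- ca[4, ] + c(0, 0, 3)
  want <- oracle_rmsd_grid(ca, nat$ca[5:13, ])
  expect_equal(fragment_rmsd_to_native(ca, 5, nat), want,
               tolerance = 5e-3)
})

test_that("fragments over missing native residues are unevaluable, not zero", {
  nat <- ev_case$native
  nat$resno <- nat$resno + ifelse(nat$resno > 10, 1L, 0L)  # residue 11 gone
  ca <- ev_case$native$ca[8:16, ]
  expect_true(is.na(fragment_rmsd_to_native(ca, 8, nat)))
  expect_equal(fragment_rmsd_to_native(ev_case$native$ca[1:6, ], 1, nat), 0)
})

test_that("precision and coverage match naive recounts on hand-built libraries", {
  tlen <- 12L
  frags <- data.frame(pos = c(1L, 3L, 5L, 7L), len = 6L,
                      template = "x_A", tstart = 1L, origin = "RANDOM",
                      ss_class = "alpha", score_rama = 0, score_ss = 0,
                      score_tors = 0, hit_score = NA_real_)
  lib <- new_fragment_library(frags, "FINAL", tlen)
  rmsds <- c(0.3, 0.7, 1.2, 1.9)
  tab <- data.frame(pos = frags$pos, len = frags$len, rmsd = rmsds)
  nat <- ev_case$native
  expect_equal(precision(lib, nat, 1.0, rmsds = rmsds), 0.5)
  expect_equal(precision(lib, nat, 0.5, rmsds = rmsds), 0.25)
  expect_equal(precision(lib, nat, 2.0, rmsds = rmsds), 1.0)
  for (cc in c(0.5, 1.0, 1.5, 2.0)) {
    expect_equal(precision(lib, nat, cc, rmsds = rmsds),
                 naive_precision(tab, cc))
    expect_equal(coverage(lib, nat, cc, rmsds = rmsds),
                 naive_coverage(tab, cc, tlen))
  }
  # one good length-6 fragment on a 12-residue target covers half
  expect_equal(coverage(lib, nat, 0.5, rmsds = rmsds), 0.5)
  empty <- new_fragment_library(fraglib:::frag_cols(), "FINAL", tlen)
  expect_equal(coverage(empty, nat, 1.0, rmsds = numeric(0)), 0)
  expect_true(is.nan(precision(empty, nat, 1.0, rmsds = numeric(0))))
})

test_that("good-fragment sets are nested and coverage is monotone in the cutoff", {
  cfg <- flib_config(n_random = 150, top_k = 80, seed = 93)
  run <- run_flib(ev_case$profile, ev_case$db, cfg, native = ev_case$native)
  ev <- run$eval
  expect_equal(nrow(ev$overall), 20L)
  expect_true(all(diff(ev$overall$coverage) >= 0))
  rmsds <- ev$rmsds
  good_small <- which(!is.na(rmsds) & rmsds < 0.5)
  good_big <- which(!is.na(rmsds) & rmsds < 1.5)
  expect_true(all(good_small %in% good_big))
})

test_that("per-class precisions recombine to the overall precision", {
  cfg <- flib_config(n_random = 150, top_k = 80, seed = 94)
  run <- run_flib(ev_case$profile, ev_case$db, cfg, native = ev_case$native)
  ev <- run$eval
  for (cc in c(0.5, 1.0)) {
    by <- ev$by_class[ev$by_class$cutoff == cc & ev$by_class$n > 0, ]
    weighted <- sum(by$precision * by$n) / sum(by$n)
    overall <- ev$overall$precision[ev$overall$cutoff == cc]
    expect_equal(weighted, overall, tolerance = 1e-9)
  }
})

test_that("one-sided KS matches a direct ECDF sweep", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  k <- ks_one_sided(a, b)
  expect_equal(k$statistic, naive_ks_greater(a, b))
  expect_equal(k$statistic, 1 / 3)
  expect_equal(ks_one_sided(a, a)$statistic, 0)
  expect_equal(ks_one_sided(c(1, 2), c(10, 11))$statistic, 1.0)
  set.seed(6)
  x <- rnorm(20); y <- rnorm(25, 1)
  expect_equal(ks_one_sided(x, y)$statistic, naive_ks_greater(x, y),
               tolerance = 1e-12)
})

test_that("rosetta fragment files parse and reconstruct coordinates", {
  tmp <- withr::local_tempfile(fileext = ".frag")
  helix <- function(resno0) sprintf(
    " 1abc A %5d %s H %8.3f %8.3f %8.3f", resno0 + 0:8,
    sample(c("A", "L", "K"), 9, TRUE), rep(-57, 9), rep(-47, 9),
    rep(180, 9))
  set.seed(10)
  lines <- c(" position:            1 neighbors:            3", "")
  for (k in 1:3) lines <- c(lines, helix(10 * k), "")
  lines <- c(lines, " position:            2 neighbors:            3", "")
  for (k in 1:3) lines <- c(lines, helix(10 * k + 1), "")
  writeLines(lines, tmp)
  lib <- read_rosetta_fragments(tmp)
  expect_equal(nrow(lib$frags), 6L)
  expect_equal(sort(unique(lib$frags$pos)), c(1L, 2L))
  expect_true(all(lib$frags$len == 9L))
  # reconstructed coordinates realize the recorded torsions
  ch <- compute_backbone_torsions(
    build_chain_from_torsions(rep(-57, 9), rep(-47, 9)))
  expect_lt(superpose_rmsd(lib$coords[[1]], ch$ca), 0.5)
  writeLines(c(" position: 1 neighbors: 1", "", " 1abc A 1 A H x y z"), tmp)
  expect_error(read_rosetta_fragments(tmp), "line")
})
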