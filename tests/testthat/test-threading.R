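th_case <- small_case(seed = 5)

test_that("aligned blocks yield every nine-residue window", {
  db <- th_case$db
  id <- names(db$entries)[2]
  hits <- fraglib:::new_threading_hits(
    data.frame(id = id, prob = 80, score = 100),
    data.frame(hit = 1L, target_start = 3L, template_start = 2L,
               len = 9L))
  lib <- hits_to_fragments(hits, db, character(0), target_len = 32)
  expect_equal(nrow(lib$frags), 1L)           # 9 - 9 + 1
  expect_equal(lib$frags$pos, 3L)
  expect_true(all(lib$frags$len == 9L))

  hits$blocks$len <- 12L
  lib12 <- hits_to_fragments(hits, db, character(0), target_len = 32)
  expect_equal(nrow(lib12$frags), 4L)         # 12 - 9 + 1
})

test_that("homolog hits and unresolvable templates produce no fragments", {
  db <- th_case$db
  id <- names(db$entries)[1]
  hits <- fraglib:::new_threading_hits(
    data.frame(id = c(id, "ghost_A"), prob = c(99.9, 50),
               score = c(250, 90)),
    data.frame(hit = c(1L, 2L), target_start = c(1L, 1L),
               template_start = c(1L, 1L), len = c(15L, 15L)))
  homologs <- read_homolog_hits(hits$hits)
  expect_equal(homologs, id)
  expect_warning(
    lib <- hits_to_fragments(hits, db, homologs, target_len = 32),
    "ghost_A")
  expect_equal(nrow(lib$frags), 0L)
})

test_that("capping keeps the top hit scores; alpha positions are emptied", {
  db <- th_case$db
  ids <- names(db$entries)[2:3]
  # 30 fragments at one position via three hits with many windows
  hits <- fraglib:::new_threading_hits(
    data.frame(id = rep(ids, c(2, 1)), prob = c(80, 70, 60),
               score = c(300, 200, 100)),
    data.frame(hit = 1:3, target_start = 16L,
               template_start = c(1L, 9L, 3L), len = 17L))
  lib <- hits_to_fragments(hits, db, character(0), target_len = 32)
  capped <- cap_and_filter(lib, th_case$profile, cap = 20L)
  counts <- table(capped$frags$pos)
  expect_true(all(counts <= 20))
  for (p in names(counts)) {
    kept <- capped$frags[capped$frags$pos == as.integer(p), ]
    pool <- lib$frags[lib$frags$pos == as.integer(p), ]
    if (nrow(pool) > nrow(kept))
      expect_gte(min(kept$hit_score),
                 max(pool$hit_score[!fraglib:::frag_key(pool) %in%
                                      fraglib:::frag_key(kept)]))
  }
  # the target starts with 10 predicted H: windows there are majority
  # alpha and must be emptied
  hits_a <- fraglib:::new_threading_hits(
    data.frame(id = ids[1], prob = 80, score = 100),
    data.frame(hit = 1L, target_start = 1L, template_start = 1L,
               len = 10L))
  lib_a <- hits_to_fragments(hits_a, db, character(0), target_len = 32)
  expect_gt(nrow(lib_a$frags), 0)
  capped_a <- cap_and_filter(lib_a, th_case$profile)
  expect_equal(nrow(capped_a$frags), 0L)
})

test_that("under-cap positions keep all their fragments", {
  db <- th_case$db
  hits <- fraglib:::new_threading_hits(
    data.frame(id = names(db$entries)[2], prob = 80, score = 100),
    data.frame(hit = 1L, target_start = 16L, template_start = 1L,
               len = 11L))
  lib <- hits_to_fragments(hits, db, character(0), target_len = 32)
  capped <- cap_and_filter(lib, th_case$profile, cap = 20L)
  expect_equal(nrow(capped$frags), nrow(lib$frags))   # 3 windows < cap
})

test_that("final merge is a per-position union without duplicates", {
  cfg <- flib_config(n_random = 100, top_k = 50, seed = 81)
  run <- run_flib(th_case$profile, th_case$db, cfg, keep_stages = TRUE)
  enr <- run$stages$enriched
  empty <- new_fragment_library(fraglib:::frag_cols(), "THREADING",
                                enr$target_len)
  expect_equal(merge_final(enr, empty)$frags, enr$frags)

  # full overlap: merging a library into itself changes nothing
  dup <- enr; dup$stage <- "THREADING"
  expect_equal(nrow(merge_final(enr, dup)$frags), nrow(enr$frags))

  hits <- make_threading_hits(enr$target_len, th_case$db,
                              probabilities = c(80, 60), seed = 82)
  th <- cap_and_filter(
    hits_to_fragments(hits, th_case$db, character(0), enr$target_len),
    th_case$profile)
  fin <- merge_final(enr, th)
  expect_false(any(duplicated(fraglib:::frag_key(fin$frags))))
  new_keys <- setdiff(fraglib:::frag_key(th$frags),
                      fraglib:::frag_key(enr$frags))
  expect_equal(nrow(fin$frags), nrow(enr$frags) + length(new_keys))
  expect_true(all(fin$frags$len[fin$frags$origin == "THREADING"] == 9L))
})

test_that("threading hit TSV round-trips", {
  hits <- make_threading_hits(30, th_case$db,
                              probabilities = c(99.9, 50), seed = 9)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_threading_tsv(hits, tmp)
  rt <- read_threading_tsv(tmp)
  expect_equal(rt$hits$id, hits$hits$id)
  expect_equal(rt$hits$prob, hits$hits$prob)
  expect_equal(rt$blocks, hits$blocks)
  expect_equal(length(read_homolog_hits(rt)), 1L)
})

test_that("hhr files parse into hits with gapless blocks", {
  tmp <- withr::local_tempfile(fileext = ".hhr")
  writeLines(c(
    "Query         target",
    "Match_columns 32",
    "",
    " No Hit        Prob E-value P-value Score SS Cols Query-HMM Template-HMM",
    "  1 tmpl_A      99.6 1e-30   1e-32   250.0 0.0 20   1-20     1-20 (60)",
    "  2 tmpl_B      45.0 1.0     0.1      80.0 0.0 18   3-20     5-22 (60)",
    "",
    "No 1",
    ">tmpl_A some description",
    "Probab=99.60  E-value=1e-30  Score=250.00  Aligned_cols=20",
    "",
    "Q target            1 MKVLAAGGDE 10 (32)",
    "Q Consensus         1 mkvlaaggde 10 (32)",
    "T tmpl_A            1 MKVLAAGGDE 10 (60)",
    "T Consensus         1 mkvlaaggde 10 (60)",
    "",
    "No 2",
    ">tmpl_B other",
    "Probab=45.00  E-value=1.0  Score=80.00  Aligned_cols=18",
    "",
    "Q target            3 VLAAG-GDEMKV 13 (32)",
    "T tmpl_B            5 VLAAGGGD-MKV 15 (60)",
    ""), tmp)
  hits <- read_hhr(tmp)
  expect_equal(nrow(hits$hits), 2L)
  expect_equal(hits$hits$prob, c(99.6, 45.0))
  expect_equal(hits$hits$score, c(250, 80))
  expect_equal(read_homolog_hits(hits), "tmpl_A")
  b1 <- hits$blocks[hits$blocks$hit == 1, ]
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$len, 10L)
  expect_equal(b1$target_start, 1L)
  # the gapped alignment splits into gapless blocks
  b2 <- hits$blocks[hits$blocks$hit == 2, ]
  expect_equal(nrow(b2), 3L)
  expect_equal(b2$len, c(5L, 2L, 3L))
  expect_equal(b2$target_start, c(3L, 8L, 11L))
  expect_equal(b2$template_start, c(5L, 11L, 13L))
})
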