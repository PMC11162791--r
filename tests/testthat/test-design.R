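pair <- synthetic_premir_pair("mir181")
params <- nn_params()

test_that("every candidate is the exact antisense of its window", {
  for (hp in list(pair$hairpin_a, pair$hairpin_b)) {
    cand <- enumerate_candidates(hp)
    expect_gt(nrow(cand), 0)
    for (i in seq_len(nrow(cand))) {
      win <- substr(hp$sequence, cand$window_start[i], cand$window_end[i])
      expect_identical(cand$target_site[i], win)
      expect_identical(rna_revcomp(cand$sequence[i]), win)
    }
  }
})

test_that("cleavage_overlap windows straddle the bond and touch the loop", {
  for (hp in list(pair$hairpin_a, pair$hairpin_b,
                  synthetic_premir_pair("mir16")$hairpin_a)) {
    cand <- enumerate_candidates(hp, classes = "cleavage_overlap",
                                 min_side = 2)
    s0 <- cand$window_start - 1L  # back to 0-based
    expect_true(all(hp$site5p - s0 >= 2))
    expect_true(all(cand$window_end - hp$site5p >= 2))
    expect_true(all(cand$window_end > hp$loop$start))  # loop overlap
    expect_true(all(cand$length == 13L))
  }
})

test_that("the loop_covering window applies the flank rule (11->13, 16->18)", {
  la <- enumerate_candidates(pair$hairpin_a, classes = "loop_covering")
  lb <- enumerate_candidates(pair$hairpin_b, classes = "loop_covering")
  expect_equal(nrow(la), 1L)
  expect_equal(la$length, 13L)
  expect_equal(lb$length, 18L)
  # flank = 2 widens symmetrically
  la2 <- enumerate_candidates(pair$hairpin_a, classes = "loop_covering",
                              loop_flank = 2)
  expect_equal(la2$length, 15L)
})

test_that("an out-of-bounds loop window is skipped with a warning", {
  hp <- parse_hairpin("GGGGAAAACCCC", interval(0, 4), interval(8, 12),
                      structure = "((((....))))")
  expect_warning(out <- enumerate_candidates(hp, k = 8,
                                             classes = "loop_covering",
                                             loop_flank = 6),
                 "exceeds")
  expect_equal(nrow(out), 0L)
})

test_that("the 3p cleavage bond can be targeted symmetrically", {
  cand <- enumerate_candidates(pair$hairpin_a, classes = "cleavage_overlap",
                               site = "3p")
  s0 <- cand$window_start - 1L
  expect_true(all(s0 < pair$hairpin_a$site3p))
  expect_true(all(cand$window_end - pair$hairpin_a$site3p >= 2))
})

test_that("scored fields equal independent stand-alone recomputation", {
  idx <- build_index(c(sib = pair$hairpin_b$sequence), k = 13)
  cand <- enumerate_candidates(pair$hairpin_a, classes = "cleavage_overlap")
  scored <- score_candidates(cand, params = params, index = idx,
                             paralogs = c(sib = pair$hairpin_b$sequence))
  for (i in seq_len(nrow(scored))) {
    expect_equal(scored$dg37[i],
                 duplex_energy(scored$sequence[i], scored$target_site[i],
                               params)$dg37)
    ss <- self_structure(scored$sequence[i], params)
    expect_equal(scored$hairpin_flag[i], ss$hairpin_flag)
    expect_equal(scored$homodimer_flag[i], ss$homodimer_flag)
    expect_equal(scored$hits_v1[i],
                 count_hits(rna_revcomp(scored$sequence[i]), idx, 1))
    expect_equal(scored$paralog_min_mm[i],
                 min_mismatch_to_paralog(scored$sequence[i],
                                         pair$hairpin_b$sequence))
  }
})

test_that("auto modification places LNA near the ends and the middle", {
  m13 <- apply_modification_pattern("ACGUACGUACGUA")
  expect_equal(m13$lna_positions[[1]], c(2L, 7L, 12L))
  m18 <- apply_modification_pattern(strrep("ACU", 6))
  expect_equal(m18$lna_positions[[1]], c(2L, 9L, 17L))
  expect_equal(m13$modified, "A+CGUAC+GUACG+UA")
  expect_equal(m13$backbone, "2OMe")
  expect_error(apply_modification_pattern("ACGUACGUACGUA", spec = 0L),
               "out of range")
  expect_error(apply_modification_pattern("ACGUACGUACGUA", spec = 14L),
               "out of range")
  m_expl <- apply_modification_pattern("ACGUACGUACGUA", spec = c(1L, 13L))
  expect_equal(m_expl$lna_positions[[1]], c(1L, 13L))
})

test_that("ranking follows the documented key and filters", {
  toy <- tibble::tibble(
    precursor = "p", class = "cleavage_overlap",
    sequence = c("CCC", "AAA", "BBB", "DDD", "EEE", "FFF"),
    dg37 = c(-20, -25, -25, -25, -18, -30),
    hits_v1 = c(0L, 2L, 0L, 0L, 0L, 0L),
    hits_v2 = c(0L, 0L, 5L, 1L, 0L, 0L),
    hairpin_flag = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    homodimer_flag = FALSE,
    selectivity_pass = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  r <- rank_candidates(toy)
  # FFF dropped (structured), EEE dropped (not selective); then dg, hits_v1,
  # hits_v2, sequence
  expect_equal(r$sequence, c("DDD", "BBB", "AAA", "CCC"))
  expect_equal(r$rank, 1:4)
  # independent oracle: order by the documented key on the surviving set
  surv <- toy[toy$selectivity_pass & !toy$hairpin_flag & !toy$homodimer_flag, ]
  surv <- surv[order(surv$dg37, surv$hits_v1, surv$hits_v2, surv$sequence), ]
  expect_equal(r$sequence, surv$sequence)
  # keep_structured retains the folded candidate
  r2 <- rank_candidates(toy, keep_structured = TRUE)
  expect_equal(r2$sequence[1], "FFF")
})

test_that("an empty post-filter set warns and returns an empty ranking", {
  toy <- tibble::tibble(precursor = "p", class = "cleavage_overlap",
                        sequence = "AAA", dg37 = -20, hits_v1 = 0L,
                        hits_v2 = 0L, hairpin_flag = FALSE,
                        homodimer_flag = FALSE, selectivity_pass = FALSE)
  expect_warning(r <- rank_candidates(toy), "no candidate")
  expect_equal(nrow(r), 0L)
  expect_equal(attr(r, "n_input"), 1L)
})

test_that("ranking is deterministic across repeated scoring runs", {
  idx <- build_index(c(sib = pair$hairpin_a$sequence), k = 13)
  run <- function() {
    design_asos(pair$hairpin_b, params = params, index = idx,
                paralogs = c(sib = pair$hairpin_a$sequence))
  }
  r1 <- run(); r2 <- run()
  expect_identical(tidy(r1), tidy(r2))
})

test_that("top-ranked candidates discriminate the sibling on fixture families", {
  for (seed in c(2, 17, 91)) {
    fx <- generate_paralog_hairpins(stem_identity_pct = 92, seed = seed)
    sib <- c(b = fx$hairpin_b$sequence)
    r <- design_asos(fx$hairpin_a, params = params, paralogs = sib)
    if (nrow(r) > 0) {
      expect_gte(r$paralog_min_mm[r$rank == 1], 2L)
      expect_true(all(r$selectivity_pass))
    }
  }
})

test_that("tidy and glance summarise a ranked design", {
  r <- design_asos(pair$hairpin_a, params = params,
                   paralogs = c(sib = pair$hairpin_b$sequence))
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$rank, seq_len(nrow(td)))
  g <- glance(r)
  expect_equal(g$n_ranked, nrow(td))
  expect_equal(g$best_dg37, min(td$dg37))
  expect_true(g$all_selective)
})

test_that("autoplot returns a ggplot for designs and control pools", {
  r <- design_asos(pair$hairpin_a, params = params,
                   paralogs = c(sib = pair$hairpin_b$sequence))
  expect_s3_class(autoplot(r), "ggplot")
})
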