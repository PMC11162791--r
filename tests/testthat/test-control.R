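test_that("the candidate space counts 4^k sites and guards its bounds", {
  expect_equal(enumerate_space(1)$total, 4)
  expect_equal(enumerate_space(3)$total, 64)
  expect_error(enumerate_space(0), "1..16")
  expect_error(enumerate_space(17), "1..16")
  # codes round-trip through the 2-bit packing in ascending order
  sites <- seloligo:::decode_kmers(0:63, 3)
  expect_equal(length(unique(sites)), 64L)
  expect_equal(seloligo:::encode_kmers(sites), as.numeric(0:63))
  expect_equal(sites[1], "AAA")
  expect_equal(sites[64], "UUU")
})

test_that("an empty reference leaves the whole space surviving every round", {
  idx <- build_index(character(0), k = 4)
  el <- eliminate_by_alignment(enumerate_space(4), idx)
  expect_equal(el$trace$survivor_count, rep(256, 3))
  expect_equal(el$trace$aligned_count, rep(0, 3))
  expect_equal(el$final_v, 2L)
  expect_equal(length(el$pool), 256L)
})

test_that("neighborhood-marking elimination equals per-candidate brute force", {
  set.seed(303)
  for (case in 1:100) {
    k <- sample(4:6, 1)
    n_tx <- sample(1:3, 1)
    seqs <- vapply(seq_len(n_tx),
                   function(i) rand_rna(sample((k + 2):25, 1)), character(1))
    names(seqs) <- paste0("t", seq_len(n_tx))
    idx <- suppressWarnings(build_index(seqs, k = k))
    el <- eliminate_by_alignment(enumerate_space(k), idx,
                                 v_schedule = c(0, 1, 2))
    for (row in seq_len(nrow(el$trace))) {
      v <- el$trace$v[row]
      expect_equal(el$trace$survivor_count[row],
                   length(oracle_survivors(k, seqs, v)),
                   info = sprintf("case %d k=%d v=%d", case, k, v))
    }
    if (!is.na(el$final_v)) {
      expect_setequal(el$pool, oracle_survivors(k, seqs, el$final_v))
    }
  }
})

test_that("elimination also honours forward-only references at k = 8", {
  set.seed(304)
  seqs <- c(t1 = rand_rna(60), t2 = rand_rna(40))
  idx <- build_index(seqs, k = 8, both_orientations = FALSE)
  el <- eliminate_by_alignment(enumerate_space(8), idx, v_schedule = c(0, 1),
                               max_pool = 70000)
  expect_equal(el$trace$survivor_count[1],
               length(oracle_survivors(8, seqs, 0, both = FALSE)))
  expect_equal(el$trace$survivor_count[2],
               length(oracle_survivors(8, seqs, 1, both = FALSE)))
})

test_that("survivor sets shrink monotonically and chain across rounds", {
  set.seed(305)
  for (i in 1:10) {
    seqs <- c(a = rand_rna(50), b = rand_rna(30))
    el <- eliminate_by_alignment(enumerate_space(5),
                                 build_index(seqs, k = 5))
    tr <- el$trace
    expect_true(all(diff(tr$survivor_count) <= 0))
    expect_equal(tr$input_count[-1], tr$survivor_count[-nrow(tr)])
    expect_equal(tr$input_count - tr$aligned_count, tr$survivor_count)
  }
})

test_that("characteristic filters reject runs, tandem repeats and homodimers", {
  f <- filter_characteristics(c("AAAUCGGUCAGCU",   # AAA run
                                "ACACACGGUCAUG",   # AC x3
                                "GCAUGAUGGCAUG",   # clean
                                "GCAUGAUACAUGC"),  # self-complementary run
                              params = nn_params())
  expect_equal(f$filtered, "GCAUGAUGGCAUG")
  rej <- stats::setNames(f$rejections$n_rejected, f$rejections$rule)
  expect_equal(rej[["mononucleotide_run"]], 1L)
  expect_equal(rej[["dinucleotide_repeat"]], 1L)
  expect_equal(rej[["homodimer"]], 1L)
  expect_error(filter_characteristics(character(0)), "empty")
  # thresholds are configurable
  f2 <- filter_characteristics("AAAUCGGUCAGCU", max_nt_run = 3,
                               params = nn_params())
  expect_equal(length(f2$filtered), 1L)
})

test_that("emitted controls are the antisense of chosen sites, reproducibly", {
  pool <- c("GCAUGAUGGCAUG", "AGCUGGAUCAGGC", "UUGACGGAUGCAU",
            "CAGGCAUUGACGG", "GAUCCGUAAGCAU", "ACGGAUUGCAGGC",
            "UGCAGGAUCGUAA", "CCGUAAGCAUGGA", "AUUGCAGGCGAUC",
            "GGAUCGUAACCGU")
  one <- emit_controls(pool[1], n = 1, seed = 5)
  expect_equal(one$sequence, rna_revcomp(pool[1]))
  a <- emit_controls(pool, n = 3, seed = 42)
  b <- emit_controls(pool, n = 3, seed = 42)
  expect_identical(a, b)
  # seeded-oracle replay of the uniform choice
  set.seed(42)
  expect_equal(a$target_site, pool[sample.int(10, 3)])
  expect_true(all(a$sequence == rna_revcomp(a$target_site)))
  expect_error(emit_controls(character(0), seed = 1), "empty")
  expect_error(emit_controls(pool, n = 1), "seed")
  expect_error(emit_controls(pool, n = 11, seed = 1), "n must be")
})

test_that("every emitted control is transcriptome-null beyond final_v", {
  set.seed(307)
  seqs <- c(t1 = rand_rna(80), t2 = rand_rna(60))
  idx <- build_index(seqs, k = 5)
  cp <- design_controls(idx, k = 5, v_schedule = c(0, 1), n = 3, seed = 9)
  expect_gte(cp$final_v, 0)
  for (ctrl in cp$controls$sequence) {
    site <- rna_revcomp(ctrl)
    d <- min(vapply(c(seqs, rna_revcomp(seqs)), function(s) {
      min_d <- Inf
      for (off in 0:(nchar(s) - 5)) {
        min_d <- min(min_d, oracle_hamming(site, substr(s, off + 1, off + 5)))
      }
      min_d
    }, numeric(1)))
    expect_gte(d, cp$final_v + 1)
  }
})

test_that("the control pipeline is byte-deterministic for a fixed seed", {
  set.seed(308)
  seqs <- c(t1 = rand_rna(70))
  idx <- build_index(seqs, k = 5)
  cp1 <- design_controls(idx, k = 5, v_schedule = c(0, 1), n = 2, seed = 4)
  cp2 <- design_controls(idx, k = 5, v_schedule = c(0, 1), n = 2, seed = 4)
  expect_identical(cp1$controls, cp2$controls)
  expect_identical(cp1$trace, cp2$trace)
  expect_identical(glance(cp1), glance(cp2))
  expect_identical(tidy(cp1), cp1$controls)
  expect_s3_class(autoplot(cp1), "ggplot")
})

test_that("the space/index k mismatch and schedule errors are caught", {
  idx <- build_index(c(a = strrep("ACGU", 10)), k = 6)
  expect_error(eliminate_by_alignment(enumerate_space(5), idx), "match")
  expect_error(eliminate_by_alignment(enumerate_space(6), idx,
                                      v_schedule = c(1, 0)),
               "increasing")
})
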