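test_that("parse_hairpin derives cleavage bonds from the arm annotations", {
  hp <- parse_hairpin("GGGGAAAACCCC", interval(0, 4), interval(8, 12),
                      name = "toy", structure = "((((....))))")
  expect_s3_class(hp, "premirna_hairpin")
  expect_equal(hp$site5p, 4L)
  expect_equal(hp$site3p, 8L)
  expect_equal(hp$loop$start, 4L)
  expect_equal(hp$loop$end, 8L)
})

test_that("parse_hairpin tolerates DNA-styled input and rejects bad records", {
  expect_warning(hp <- parse_hairpin("GGGGAAAATCCC", interval(0, 4),
                                     interval(8, 12)),
                 "converting to U")
  expect_equal(substr(hp$sequence, 9, 9), "U")
  expect_error(parse_hairpin("GGGGAAAAXCCC", interval(0, 4), interval(8, 12)),
               "non-ACGU")
  expect_error(parse_hairpin(strrep("A", 20), interval(0, 10), interval(5, 20)),
               "overlap")
  expect_error(parse_hairpin("GGGGAAAACCCC", interval(0, 4), interval(8, 12),
                             structure = "((((....)))"),
               "length")
  expect_error(parse_hairpin("GGGGAAAACCCC", interval(0, 4), interval(8, 12),
                             structure = "((((....))))))))....(((("),
               "length|bracket")
  expect_error(parse_hairpin("GGGGAAAACCCC", interval(0, 4), interval(8, 12),
                             structure = ")(((....))()"),
               "bracket")
})

test_that("intervals enforce their invariants and print 1-based", {
  expect_error(interval(-1, 3), "invalid interval")
  expect_error(interval(5, 5), "invalid interval")
  expect_equal(iv_length(interval(4, 8)), 4L)
  expect_equal(format(interval(4, 8)), "5-8")
})

test_that("infer_loop returns the terminal-loop run, excluding stem bulges", {
  # bulged stem: the 2-nt bulge after the first closing helix must not be
  # merged into the apical loop
  db <- "((((((....))..))))...."
  sq <- "GGCGGGAAAACCAACCGCAAAA"
  hp <- parse_hairpin(sq, interval(0, 5), interval(14, 22), structure = db)
  expect_equal(hp$loop$start, 6L)
  expect_equal(hp$loop$end, 10L)
})

test_that("infer_loop rejects multibranch structures by name", {
  err <- expect_error(
    parse_hairpin("GGGAAACCCGGGAAACCCAA", interval(0, 3), interval(15, 20),
                  name = "branchy",
                  structure = "(((...)))(((...))).."),
    "branchy")
  expect_match(conditionMessage(err), "not a single hairpin")
})

test_that("infer_loop falls back to folding when no structure is given", {
  hp <- parse_hairpin("GGGGAAAACCCC", interval(0, 4), interval(8, 12))
  expect_equal(hp$loop$start, 4L)
  expect_equal(hp$loop$end, 8L)
})

test_that("the synthetic paralog pairs reproduce the documented loop sizes", {
  pa <- synthetic_premir_pair("mir181")
  expect_equal(nchar(pa$hairpin_a$sequence), 62L)
  expect_equal(nchar(pa$hairpin_b$sequence), 67L)
  expect_equal(iv_length(pa$hairpin_a$loop), 11L)
  expect_equal(iv_length(pa$hairpin_b$loop), 16L)
  pb <- synthetic_premir_pair("mir16")
  expect_equal(nchar(pb$hairpin_a$sequence), 64L)
  expect_equal(nchar(pb$hairpin_b$sequence), 65L)
  expect_equal(iv_length(pb$hairpin_a$loop), 9L)
  expect_equal(iv_length(pb$hairpin_b$loop), 17L)
})

test_that("loop lies between the arms for generated and built-in hairpins", {
  hps <- c(synthetic_premir_pair("mir181")[c("hairpin_a", "hairpin_b")],
           synthetic_premir_pair("mir16")[c("hairpin_a", "hairpin_b")])
  set.seed(5)
  for (s in sample.int(1e6, 5)) {
    fx <- generate_paralog_hairpins(seed = s)
    hps <- c(hps, list(fx$hairpin_a, fx$hairpin_b))
  }
  for (hp in hps) {
    expect_gte(hp$loop$start, hp$site5p)
    expect_lte(hp$loop$end, hp$site3p)
    expect_false(seloligo:::iv_overlaps(hp$loop, hp$arm5p))
    expect_false(seloligo:::iv_overlaps(hp$loop, hp$arm3p))
  }
})

test_that("region_identity is symmetric, exact, and ungapped-only", {
  a <- "ACGUACGUAC"; b <- "ACGAACGUGC"
  ra <- region_identity(a, b); rb <- region_identity(b, a)
  expect_equal(ra$matches, 8L)
  expect_equal(ra$identity_pct, 80)
  expect_equal(ra, rb)
  expect_equal(region_identity(a, a)$identity_pct, 100)
  set.seed(9)
  for (i in 1:20) {
    x <- rand_rna(15); y <- rand_rna(15)
    expect_equal(region_identity(x, y)$identity_pct == 100, x == y)
  }
  expect_error(region_identity("ACGU", "ACG"), "equal length")
})

test_that("composition_stats partitions exactly into G/C and A/U", {
  expect_equal(composition_stats("GGGG")$gc_pct, 100)
  expect_equal(composition_stats("GGGG")$au_pct, 0)
  set.seed(3)
  for (i in 1:50) {
    st <- composition_stats(rand_rna(sample(1:40, 1), pgc = runif(1)))
    expect_identical(st$gc_pct + st$au_pct, 100)
  }
  expect_error(composition_stats("ACGU", interval(4, 8)), "bounds")
})

test_that("nussinov_fold handles trivial shapes", {
  expect_equal(nussinov_fold("GGGAAACCC"), "(((...)))")
  expect_equal(nussinov_fold("AAAAAA"), "......")
  expect_equal(nussinov_fold("ACG"), "...")
})

test_that("nussinov_fold is maximal and valid versus exhaustive enumeration", {
  set.seed(181)
  for (i in 1:200) {
    n <- sample(5:12, 1)
    s <- rand_rna(n, pgc = runif(1, 0.2, 0.8))
    db <- nussinov_fold(s)
    expect_true(oracle_valid_structure(s, db))
    expect_equal(sum(strsplit(db, "")[[1]] == "("), oracle_max_pairs(s),
                 info = s)
  }
})

test_that("nussinov_fold traceback is deterministic", {
  set.seed(7)
  for (i in 1:20) {
    s <- rand_rna(30)
    expect_identical(nussinov_fold(s), nussinov_fold(s))
  }
})
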