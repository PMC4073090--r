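test_that("recall probabilities match hand-counted fractions", {
  # 3 transcripts over a 4-item list
  tr <- rbind(
    mk_transcript(1, c(4, 2)),
    mk_transcript(2, c(4, 3, 1)),
    mk_transcript(3, c(2, NA, 2), classes = c("correct", "intrusion",
                                              "repetition"))
  )
  spc <- recall_probability(tr, 4)
  expect_equal(spc$p_recall, c(1 / 3, 2 / 3, 1 / 3, 2 / 3))
  expect_equal(spc$p_first, c(0, 1 / 3, 0, 2 / 3))
  # everyone recalls everything
  full <- rbind(mk_transcript(1, 1:4), mk_transcript(2, 1:4))
  expect_equal(recall_probability(full, 4)$p_recall, rep(1, 4))
  # a run with zero events counts in the denominator when n_runs is given
  spc5 <- recall_probability(tr, 4, n_runs = 6)
  expect_equal(spc5$p_recall, c(1 / 6, 2 / 6, 1 / 6, 2 / 6))
  expect_error(recall_probability(tr[0, ], 4), "empty")
})

test_that("clustering index equals observed minus permutation expectation", {
  cats <- c(`1` = "A", `2` = "A", `3` = "B", `4` = "B")
  expect_equal(clustering_index(mk_transcript(1, 1:4), cats), 1)   # A A B B
  expect_equal(clustering_index(mk_transcript(1, c(1, 3, 2, 4)), cats), -1)
  one_cat <- c(`1` = "A", `2` = "A", `3` = "A", `4` = "A")
  expect_equal(clustering_index(mk_transcript(1, 1:4), one_cat), 0)
  expect_error(clustering_index(mk_transcript(1, 1), cats),
               class = "can_undefined_metric")
})

test_that("the chance term equals exhaustive permutation enumeration", {
  compositions <- list(c("A", "A", "B", "B"),
                       c("A", "A", "A", "B", "B"),
                       c("A", "A", "B", "B", "C", "C"),
                       c("A", "A", "A", "A", "B", "C"))
  for (cats in compositions) {
    r_c <- table(cats)
    formula_expect <- sum(r_c * (r_c - 1)) / length(cats)
    expect_equal(formula_expect, mean_adjacency_enumerated(cats),
                 tolerance = 1e-12)
  }
})

test_that("clustering is invariant to relabeling and order reversal", {
  set.seed(8)
  for (i in 1:10) {
    cats <- sample(c("A", "B", "C"), 8, replace = TRUE)
    ids <- as.character(1:8)
    m1 <- stats::setNames(cats, ids)
    m2 <- stats::setNames(chartr("ABC", "XYZ", cats), ids)
    tr <- mk_transcript(1, 1:8)
    fwd <- clustering_index(tr, m1)
    expect_equal(clustering_index(tr, m2), fwd)
    rev_tr <- mk_transcript(1, 8:1,
                            items = 8:1)
    rev_map <- stats::setNames(cats, ids)
    expect_equal(clustering_index(rev_tr, rev_map), fwd)
  }
})

test_that("chance correction is unbiased over random permutations", {
  set.seed(123)
  cats <- c(rep("A", 4), rep("B", 3), rep("C", 3))
  idx <- replicate(10000, {
    ord <- sample(10)
    m <- stats::setNames(cats[ord], as.character(1:10))
    clustering_index(mk_transcript(1, 1:10), m)
  })
  se <- sd(idx) / sqrt(length(idx))
  expect_lt(abs(mean(idx)), 3 * se)
})

test_that("isolate-advantage measures match hand counts", {
  vr <- rbind(mk_transcript(1, c(7, 3)), mk_transcript(2, c(2, 5)),
              mk_transcript(3, c(7, 1)), mk_transcript(4, c(4, 7)))
  bl <- rbind(mk_transcript(1, c(7, 2)), mk_transcript(2, c(3, 1)),
              mk_transcript(3, c(5, 4)), mk_transcript(4, c(6, 2)))
  m <- vr_measures(vr, bl, isolate_position = 7)
  expect_equal(m$p_isolate, 3 / 4)
  expect_equal(m$p_baseline, 1 / 4)
  expect_equal(m$advantage, 0.5)
  expect_equal(m$isolate_proportion, 3 / 8)
  # identical transcript sets give zero advantage
  m0 <- vr_measures(vr, vr, 7)
  expect_equal(m0$advantage, 0)
})

test_that("lag-CRP matches a brute-force transition counter", {
  trs <- rbind(
    mk_transcript(1, c(3, 4, 5)),
    mk_transcript(2, c(1, 2, 4, 3)),
    mk_transcript(3, c(5, 1)),
    mk_transcript(4, c(2, NA, 3), classes = c("correct", "intrusion",
                                              "correct")),
    mk_transcript(5, c(4))
  )
  got <- lag_crp(trs, 5)
  want <- lag_crp_brute(trs, 5)
  expect_equal(got$crp, unname(want))
  # transcript recalling 3,4,5 alone: lag +1 is certain
  solo <- lag_crp(mk_transcript(1, c(3, 4, 5)), 5)
  expect_equal(solo$crp[solo$lag == 1], 1)
  expect_true(all(solo$crp[solo$lag %in% c(-1, -2, 2)] == 0, na.rm = TRUE))
  # single recalls leave every lag undefined
  empty <- lag_crp(mk_transcript(1, 2), 5)
  expect_true(all(is.na(empty$crp)))
})

test_that("transcripts round-trip through the CSV schema", {
  tr <- mk_transcript(1, c(3, NA, 2), classes = c("correct", "intrusion",
                                                  "correct"))
  f <- tempfile(fileext = ".csv")
  write_transcripts(tr, f, header_comment = "seed=1")
  back <- read_transcripts(f)
  expect_equal(back$serial_position, tr$serial_position)
  expect_equal(back$classification, tr$classification)
  unlink(f)
  writeLines("a,b\n1,2", f)
  expect_error(read_transcripts(f), "lacks columns")
  unlink(f)
})
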