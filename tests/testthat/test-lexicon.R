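test_that("unrelated connectivity respects the connection probability", {
  p0 <- can_params(p_conn = 0)
  expect_true(all(build_unrelated_lexicon(p0, seed = 1)$W_xy == 0))
  p1 <- can_params(p_conn = 1)
  expect_true(all(build_unrelated_lexicon(p1, seed = 1)$W_xy == 1))
  # binomial expectation: 45 features x 16% = 7.2 features per word
  p <- can_params()
  counts <- unlist(lapply(1:60, function(s)
    rowSums(build_unrelated_lexicon(p, seed = s)$W_xy)))
  expect_equal(mean(counts), p$n_sem * p$p_conn, tolerance = 0.05)
})

test_that("lexica and lists are reproducible under a seed", {
  p <- can_params()
  a <- build_unrelated_lexicon(p, seed = 99)
  b <- build_unrelated_lexicon(p, seed = 99)
  expect_identical(a, b)
  lex <- build_category_lexicon(c(a = 4, b = 4, c = 4, d = 4), p, seed = 7)
  l1 <- make_cvlt_list(lex, seed = 5)
  l2 <- make_cvlt_list(lex, seed = 5)
  expect_identical(l1, l2)
})

test_that("category members share exactly their band plus random features", {
  p <- can_params()
  lex <- build_category_lexicon(c(first = 5, second = 5), p, seed = 3)
  b1 <- lex$shared_features$first
  b2 <- lex$shared_features$second
  expect_length(intersect(b1, b2), 0)
  for (i in 1:5) {
    expect_true(all(lex$W_xy[i, b1] == 1))
    expect_true(all(lex$W_xy[i + 5, b2] == 1))
    # overlap between same-category members is at least the band
    expect_gte(sum(lex$W_xy[1, ] & lex$W_xy[i, ]), p$n_shared)
  }
  # cross-category overlap excludes both bands (random collisions only)
  for (i in 1:5) for (j in 6:10) {
    ov <- which(lex$W_xy[i, ] & lex$W_xy[j, ] == 1)
    expect_length(intersect(ov, c(b1, b2)), 0)
  }
  # non-item units carry no band features
  fillers <- setdiff(seq_len(p$n_lex), lex$items)
  expect_true(all(lex$W_xy[fillers, c(b1, b2)] == 0))
})

test_that("CVLT lexicon has four disjoint five-feature bands", {
  p <- can_params()
  lex <- build_category_lexicon(c(a = 4, b = 4, c = 4, d = 4), p, seed = 2)
  expect_length(lex$shared_features, 4)
  expect_true(all(lengths(lex$shared_features) == p$n_shared))
  expect_length(unique(unlist(lex$shared_features)), 20)
})

test_that("CVLT order is a no-adjacent-same-category permutation", {
  p <- can_params()
  lex <- build_category_lexicon(c(a = 4, b = 4, c = 4, d = 4), p, seed = 1)
  for (s in 1:20) {
    sl <- make_cvlt_list(lex, seed = s)
    expect_setequal(sl$items, lex$items)
    expect_false(any(sl$categories[-1] == sl$categories[-16]))
  }
})

test_that("constrained sampler's support matches brute force on a 2x2 design", {
  p <- can_params()
  lex <- build_category_lexicon(c(a = 2, b = 2), p, seed = 1)
  cats <- lex$category_of[lex$items]
  valid <- Filter(function(ix) {
    cc <- cats[ix]; !any(cc[-1] == cc[-4])
  }, perms(1:4))
  valid_keys <- sort(vapply(valid, paste, character(1), collapse = "-"))
  expect_length(valid_keys, 8)            # enumeration oracle
  seen <- unique(vapply(1:300, function(s) {
    sl <- make_cvlt_list(lex, seed = s)
    paste(match(sl$items, lex$items), collapse = "-")
  }, character(1)))
  expect_setequal(sort(seen), valid_keys)
})

test_that("isolate lists place one other-category item at the given position", {
  p <- can_params()
  lex <- build_category_lexicon(c(main = 11, isolate = 1), p, seed = 4)
  sl1 <- make_vr_list(lex, 1)
  expect_equal(sl1$categories[1], "isolate")
  expect_true(all(sl1$categories[-1] == "main"))
  sl7 <- make_vr_list(lex, 7)
  expect_equal(which(sl7$categories == "isolate"), 7L)
  expect_error(make_vr_list(lex, 13), "range")
  expect_false(anyDuplicated(sl7$items) > 0)
})

test_that("the same-category baseline differs from the isolate list in one item", {
  p <- can_params()
  set.seed(5)
  vr <- build_design("von_restorff", p, isolate_position = 7)
  bl <- build_design("same_category", p, isolate_position = 7)
  expect_equal(length(vr$study_list$items), length(bl$study_list$items))
  expect_equal(bl$study_list$critical_position, 7L)
  expect_length(unique(bl$study_list$categories), 1L)
  # isolate list: exactly one position is off-category
  expect_equal(sum(vr$study_list$categories != "main"), 1L)
})

test_that("lexicon export records the seed and features", {
  p <- can_params()
  lex <- build_unrelated_lexicon(p, seed = 31)
  f <- tempfile(fileext = ".csv")
  export_lexicon(lex, f)
  lines <- readLines(f, n = 1)
  expect_match(lines, "seed=31")
  df <- read.csv(f, comment.char = "#")
  expect_equal(nrow(df), p$n_lex)
  unlink(f)
})
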