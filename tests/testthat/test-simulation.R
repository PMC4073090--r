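test_that("encoding follows the prescribed per-step operation order", {
  calls <- character(0)
  rec <- function(name, fn) {
    force(name); force(fn)
    function(...) { calls <<- c(calls, name); fn(...) }
  }
  local_mocked_bindings(
    update_adaptation = rec("adapt", update_adaptation),
    detect_surprise = rec("surprise", detect_surprise),
    step_lexical = rec("lex", step_lexical),
    step_semantic = rec("sem", step_semantic),
    step_categorization = rec("cat", step_categorization),
    update_context = rec("context", update_context),
    hebbian_update_category = rec("hebb", hebbian_update_category),
    .package = "canrecall"
  )
  p <- can_params(T_enc = 2L, theta_surprise = 1e9)
  set.seed(1)
  d <- build_design("unrelated", p)
  sl <- d$study_list
  sl$items <- sl$items[1]; sl$categories <- sl$categories[1]
  calls <- character(0)
  encode_list(d$lexicon, sl, p, seed = 1)
  per_step <- c("adapt", "surprise", "lex", "sem", "cat", "context", "hebb")
  expect_equal(calls, rep(per_step, 2))
  # lesioned: no surprise check, no Hebbian learning
  p_off <- can_params(T_enc = 2L, frontal_enabled = FALSE)
  calls <- character(0)
  encode_list(d$lexicon, sl, p_off, seed = 1)
  expect_equal(calls, rep(c("adapt", "lex", "sem", "cat", "context"), 2))
})

test_that("retrieval follows the prescribed per-step operation order", {
  calls <- character(0)
  rec <- function(name, fn) {
    force(name); force(fn)
    function(...) { calls <<- c(calls, name); fn(...) }
  }
  local_mocked_bindings(
    update_adaptation = rec("adapt", update_adaptation),
    step_lexical = rec("lex", step_lexical),
    step_semantic = rec("sem", step_semantic),
    step_categorization = rec("cat", step_categorization),
    .package = "canrecall"
  )
  p <- can_params(T_enc = 2L, T_ret = 3L)
  set.seed(1)
  d <- build_design("unrelated", p)
  enc <- encode_list(d$lexicon, d$study_list, p, seed = 1)
  calls <- character(0)
  retrieve(enc, p, seed = 2)
  expect_equal(calls, rep(c("adapt", "lex", "sem", "cat"), 3))
})

test_that("an unreachable retrieval threshold yields an empty recall", {
  p <- can_params(theta_retrieve = 1e6, T_ret = 120L)
  set.seed(2)
  tr <- run_trial("unrelated", p, seed = 2)
  expect_equal(nrow(tr$recall$events), 0L)
})

test_that("noise-free runs are bit-identical under a fixed seed", {
  p <- can_params(noise_sd = 0, T_ret = 200L)
  set.seed(5)
  d <- build_design("cvlt", p)
  e1 <- encode_list(d$lexicon, d$study_list, p, seed = 42)
  e2 <- encode_list(d$lexicon, d$study_list, p, seed = 42)
  expect_identical(e1$state, e2$state)
  expect_identical(e1$weights, e2$weights)
  r1 <- retrieve(e1, p, seed = 43)
  r2 <- retrieve(e2, p, seed = 43)
  expect_identical(r1$events, r2$events)
})

test_that("context weights equal the step-summed F of the logged trajectory", {
  p <- can_params(noise_sd = 0)
  set.seed(3)
  d <- build_design("unrelated", p)
  sl <- d$study_list
  sl$items <- sl$items[1:2]; sl$categories <- sl$categories[1:2]
  enc <- encode_list(d$lexicon, sl, p, seed = 7, log_trajectories = TRUE)
  # independent accumulation from the trajectory log
  expect_equal(enc$weights$Cx, colSums(activation_fn(enc$trajectory$x)),
               tolerance = 1e-10)
  expect_equal(enc$weights$Cy, colSums(activation_fn(enc$trajectory$y)),
               tolerance = 1e-10)
  expect_equal(enc$weights$Cz, colSums(activation_fn(enc$trajectory$z)),
               tolerance = 1e-10)
})

test_that("the retrieval monitor resets after the third unsuccessful attempt", {
  # rebuild the reset count from the event stream with an independent fold
  p <- can_params()
  for (s in c(4, 9)) {
    tr <- run_trial("cvlt", p, seed = s)
    ev <- tr$recall$events
    expect_gte(nrow(ev), 5)   # defaults always produce events
    expect_equal(tr$recall$n_resets,
                 resets_from_events(ev, p$max_unsuccessful))
    expect_gte(sum(ev$classification != "correct"), 3)
  }
})

test_that("recall events are classified correct / repetition / intrusion", {
  p <- can_params()
  tr <- run_trial("cvlt", p, seed = 6)
  ev <- tr$recall$events
  # first occurrence of each list item is correct, later ones repetitions
  for (u in unique(ev$item_id)) {
    sub <- ev$classification[ev$item_id == u]
    if (u %in% tr$study_list$items) {
      expect_equal(sub[1], "correct")
    } else {
      expect_equal(sub[1], "intrusion")
      expect_true(is.na(ev$serial_position[ev$item_id == u][1]))
    }
    if (length(sub) > 1) expect_true(all(sub[-1] == "repetition"))
  }
  expect_equal(ev$output_position, seq_len(nrow(ev)))
})

test_that("condition runs aggregate per-run measures and curves", {
  p <- can_params(T_ret = 250L)
  cond <- run_condition("cvlt", p, frontal = FALSE, n_runs = 4, seed = 2)
  expect_equal(nrow(cond$per_run), 4)
  expect_equal(cond$list_length, 16L)
  expect_true(all(cond$curve$p_recall >= 0 & cond$curve$p_recall <= 1))
  expect_lte(sum(cond$curve$p_first), 1 + 1e-12)
  expect_equal(sort(unique(cond$transcripts$run_id)),
               seq_len(4)[seq_len(4) %in% cond$transcripts$run_id])
  # n_runs = 1 reduces to a single trial's metrics
  c1 <- run_condition("unrelated", p, frontal = TRUE, n_runs = 1, seed = 3)
  expect_equal(c1$n_runs, 1L)
})

test_that("invalid design / position combinations are rejected", {
  p <- can_params()
  expect_error(run_condition("von_restorff", p, n_runs = 1, seed = 1),
               "isolate_position")
  expect_error(build_design("same_category", p), "isolate_position")
})
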