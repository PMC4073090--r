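# Shared helpers: reduced-size parameter sets and independent oracles used
# across the unit tests.  Oracles are deliberately written as plain loops /
# closed forms, independent of the package's update functions.

# a minimal one-unit-per-layer parameter set for scalar-dynamics tests
scalar_params <- function(...) {
  can_params(n_lex = 1L, n_sem = 1L, n_cat = 1L, n_list = 1L,
             n_shared = 1L, noise_sd = 0, ...)
}

# weights with all couplings zeroed, for isolating single terms
zero_weights <- function(params) {
  w <- can_weights(matrix(0L, params$n_lex, params$n_sem), params, seed = 1)
  w$W_yz[] <- 0
  w
}

# invert F: the y-activation whose rate equals f
inv_F <- function(f) f / (1 - f)

# closed-form adaptation: a_t = la^t a0 + sum_k (1-la) la^k F(y_{t-1-k})
adaptation_closed_form <- function(Fy_seq, lambda_a, a0 = 0) {
  t <- length(Fy_seq)
  lambda_a^t * a0 +
    sum((1 - lambda_a) * lambda_a^(0:(t - 1)) * rev(Fy_seq))
}

# mean number of adjacent same-category pairs over all permutations,
# by exhaustive enumeration (feasible for R <= 7)
perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}
mean_adjacency_enumerated <- function(cats) {
  ps <- perms(seq_along(cats))
  mean(vapply(ps, function(ix) {
    cc <- cats[ix]
    sum(cc[-1] == cc[-length(cc)])
  }, numeric(1)))
}

# independent lag-CRP counter (plain double loop)
lag_crp_brute <- function(transcripts, list_length) {
  lags <- setdiff(seq(-(list_length - 1L), list_length - 1L), 0L)
  obs <- avail <- stats::setNames(numeric(length(lags)), lags)
  for (rid in unique(transcripts$run_id)) {
    tr <- transcripts[transcripts$run_id == rid &
                        transcripts$classification == "correct", ]
    sp <- tr$serial_position[order(tr$output_position)]
    if (length(sp) < 2L) next
    for (i in 1:(length(sp) - 1L)) {
      pool <- setdiff(seq_len(list_length), sp[1:i])
      for (s in pool) avail[as.character(s - sp[i])] <-
          avail[as.character(s - sp[i])] + 1
      obs[as.character(sp[i + 1L] - sp[i])] <-
        obs[as.character(sp[i + 1L] - sp[i])] + 1
    }
  }
  ifelse(avail > 0, obs / avail, NA_real_)
}

# rebuild the retrieval monitor's reset count from an event sequence
# (events within one time step are batched; at most one reset per step)
resets_from_events <- function(events, max_unsuccessful = 2L) {
  unsucc <- 0L; resets <- 0L
  for (s in unique(events$step)) {
    batch <- events[events$step == s, ]
    unsucc <- unsucc + sum(batch$classification != "correct")
    if (unsucc > max_unsuccessful) {
      resets <- resets + 1L
      unsucc <- 0L
    }
  }
  resets
}

# a tiny hand-written transcript builder
mk_transcript <- function(run_id, positions, classes = NULL, items = NULL) {
  n <- length(positions)
  if (is.null(classes)) classes <- rep("correct", n)
  if (is.null(items)) items <- ifelse(is.na(positions), 900 + seq_len(n),
                                      positions)
  data.frame(run_id = run_id, output_position = seq_len(n), step = seq_len(n),
             item_id = items, serial_position = positions,
             classification = classes, stringsAsFactors = FALSE)
}
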