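#' Encode a study list
#'
#' Runs the encoding phase: each list item's lexical unit is clamped with
#' sensory input for `T_enc` time steps, and at every step the model
#' applies, in order: (1) the adaptation update, (2) the novelty check
#' (which may latch a surprise boost for the remainder of the current
#' item), (3) the lexical update, (4) the semantic update, (5) the
#' categorization update, (6) context learning, and (7) fast Hebbian
#' category learning for units above the learning threshold.  Steps (2)
#' and (7) are skipped entirely when `frontal_enabled` is `FALSE`
#' (frontal-lesion mode), so the lesioned model leaves `W_yz` untouched.
#'
#' A latched surprise raises the sensory input to `input_surprise` and the
#' learning rate to `delta_surprise` until the current item's offset; the
#' boost never carries into the next item.
#'
#' @param lexicon A `can_lexicon`.
#' @param study_list A `can_study_list` whose items exist in the lexicon.
#' @param params A [can_params].
#' @param seed Optional integer seed (governs the random initial `W_yz`
#'   and the lexical noise); if `NULL`, the current RNG stream is used.
#' @param weights Optional pre-built [can_weights] (otherwise initialized
#'   from the lexicon).
#' @param log_trajectories If `TRUE`, keeps the full per-step activation
#'   matrices of all three layers.
#' @return An object of class `can_encoding`: list with `state`,
#'   `weights`, `W_yz_init`, per-step `buffer_count` (number of lexical
#'   units whose `F`-activation exceeds `theta_buffer`), per-unit
#'   `peak_F` and `peak_x` (maximum lexical activation reached, in `F`
#'   units and in raw units), `surprise`
#'   (per-position data frame of surprise decisions), the inputs, and
#'   optional `trajectory`.
#' @export
encode_list <- function(lexicon, study_list, params, seed = NULL,
                        weights = NULL, log_trajectories = FALSE) {
  if (!all(study_list$items %in% seq_len(nrow(lexicon$W_xy))))
    stop("study list refers to items outside the lexicon", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(weights)) weights <- can_weights(lexicon$W_xy, params)
  W_yz_init <- weights$W_yz
  st <- can_state(params)
  n_items <- length(study_list$items)
  total_steps <- n_items * params$T_enc
  Fy_hist <- matrix(0, total_steps, params$n_sem)
  buffer_count <- integer(total_steps)
  peak_F <- peak_x <- numeric(params$n_lex)
  surprise_log <- data.frame(position = seq_len(n_items),
                             item_id = study_list$items,
                             surprised = FALSE,
                             step = NA_integer_,
                             magnitude = NA_real_)
  traj <- if (log_trajectories) {
    list(x = matrix(0, total_steps, params$n_lex),
         y = matrix(0, total_steps, params$n_sem),
         z = matrix(0, total_steps, params$n_cat),
         a = matrix(0, total_steps, params$n_sem))
  }
  t <- 0L
  for (p in seq_len(n_items)) {
    item <- study_list$items[p]
    latched <- FALSE
    for (s in seq_len(params$T_enc)) {
      t <- t + 1L
      st$a <- update_adaptation(st$a, st$y, params)
      if (params$frontal_enabled && !latched &&
          !(params$suppress_first_surprise && p == 1L)) {
        hw <- if (params$surprise_variant == "variance_normalized") {
          if (t > 1L) Fy_hist[max(1L, t - params$surprise_window):(t - 1L), ,
                              drop = FALSE]
          else matrix(0, 1L, params$n_sem)  # pre-list activity is zero
        }
        sp <- detect_surprise(st$y, st$a, params, history_window = hw)
        if (sp$active) {
          latched <- TRUE
          surprise_log$surprised[p] <- TRUE
          surprise_log$step[p] <- t
          surprise_log$magnitude[p] <- sp$magnitude
        }
      }
      eff <- apply_surprise(params,
                            list(active = latched && params$frontal_enabled))
      input_vec <- numeric(params$n_lex)
      input_vec[item] <- eff$input
      x_new <- step_lexical(st, weights, input_vec, params)
      y_new <- step_semantic(st, weights, params)
      z_new <- step_categorization(st, weights, params)
      st$x <- x_new; st$y <- y_new; st$z <- z_new
      weights <- update_context(weights, st)
      if (params$frontal_enabled) {
        weights$W_yz <- hebbian_update_category(weights$W_yz, st$z, st$y,
                                                eff$rate, params$theta_learn,
                                                params$norm_mode)
      }
      Fx <- activation_fn(st$x)
      Fy_hist[t, ] <- activation_fn(st$y)
      buffer_count[t] <- sum(Fx > params$theta_buffer)
      peak_F <- pmax(peak_F, Fx)
      peak_x <- pmax(peak_x, st$x)
      if (log_trajectories) {
        traj$x[t, ] <- st$x; traj$y[t, ] <- st$y
        traj$z[t, ] <- st$z; traj$a[t, ] <- st$a
      }
    }
  }
  structure(list(state = st, weights = weights, W_yz_init = W_yz_init,
                 buffer_count = buffer_count, peak_F = peak_F,
                 peak_x = peak_x,
                 surprise = surprise_log, lexicon = lexicon,
                 study_list = study_list, params = params,
                 trajectory = traj),
            class = "can_encoding")
}

#' Retrieve from an encoded network
#'
#' Runs `T_ret` retrieval steps.  Relative to encoding, the context drives
#' every layer (`mu_x Cx`, `mu_y Cy`, `mu_z Cz`), the categorization layer
#' feeds the semantic layer (`varpi W_yz F(z)`), the semantic-to-
#' categorization gain is reduced to `phi_ret`, and there is no sensory
#' input.  A lexical unit whose activation crosses `theta_retrieve` is
#' recalled and its activation reset to zero (it may later re-cross and be
#' logged as a repetition).  A recall is *correct* if a list item is
#' recalled for the first time; re-retrievals are *repetitions* and
#' first-time non-list items are *intrusions*, both counted as
#' unsuccessful.  When the number of unsuccessful retrievals since the
#' last reset exceeds `max_unsuccessful`, the retrieval monitor resets the
#' categorization layer, permanently inhibits the categorization units
#' that were active (above `theta_learn`) since the last reset, and
#' restarts its counter; a different unit can then win through the context
#' drive, which typically moves recall on to a new category.
#'
#' @param encoding A `can_encoding` from [encode_list()], or equivalently
#'   the `state`/`weights` pair plus list information via the `...`
#'   arguments below.
#' @param params A [can_params] (defaults to the one used at encoding).
#' @param seed Optional integer seed for the retrieval noise.
#' @param log_trajectories If `TRUE`, logs per-step activations.
#' @return An object of class `can_recall`: list with `events` (data frame
#'   with columns `output_position`, `step`, `item_id`, `serial_position`
#'   — `NA` for intrusions — and `classification` in
#'   `c("correct", "repetition", "intrusion")`), `n_resets`, `inhibited`
#'   (final inhibition mask) and optional `trajectory`.
#' @export
retrieve <- function(encoding, params = encoding$params, seed = NULL,
                     log_trajectories = FALSE) {
  if (!inherits(encoding, "can_encoding"))
    stop("retrieve() expects the result of encode_list()", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  st <- encoding$state
  weights <- encoding$weights
  study_list <- encoding$study_list
  list_items <- study_list$items
  recalled <- integer(0)     # list items recalled correctly
  seen <- integer(0)         # anything retrieved at least once
  inhibited <- rep(FALSE, params$n_cat)
  active_since_reset <- rep(FALSE, params$n_cat)
  unsucc <- 0L
  n_resets <- 0L
  zero_input <- numeric(params$n_lex)
  ev_step <- integer(0); ev_item <- integer(0); ev_class <- character(0)
  traj <- if (log_trajectories) {
    list(x = matrix(0, params$T_ret, params$n_lex),
         y = matrix(0, params$T_ret, params$n_sem),
         z = matrix(0, params$T_ret, params$n_cat))
  }
  for (t in seq_len(params$T_ret)) {
    st$a <- update_adaptation(st$a, st$y, params)
    x_new <- step_lexical(st, weights, zero_input, params,
                          retrieval_mode = TRUE)
    y_new <- step_semantic(st, weights, params, retrieval_mode = TRUE)
    z_new <- step_categorization(st, weights, params, retrieval_mode = TRUE,
                                 inhibited = inhibited)
    st$x <- x_new; st$y <- y_new; st$z <- z_new
    active_since_reset <- active_since_reset | (st$z > params$theta_learn)
    crossers <- which(st$x > params$theta_retrieve)
    if (length(crossers) > 0L) {
      crossers <- crossers[order(st$x[crossers], decreasing = TRUE)]
      for (u in crossers) {
        cls <- if (u %in% seen) "repetition"
               else if (u %in% list_items) "correct"
               else "intrusion"
        if (cls == "correct") recalled <- c(recalled, u)
        else unsucc <- unsucc + 1L
        seen <- union(seen, u)
        ev_step <- c(ev_step, t); ev_item <- c(ev_item, u)
        ev_class <- c(ev_class, cls)
        st$x[u] <- 0
      }
      if (unsucc > params$max_unsuccessful) {
        inhibited <- inhibited | active_since_reset
        st$z[] <- 0
        active_since_reset[] <- FALSE
        unsucc <- 0L
        n_resets <- n_resets + 1L
      }
    }
    if (log_trajectories) {
      traj$x[t, ] <- st$x; traj$y[t, ] <- st$y; traj$z[t, ] <- st$z
    }
  }
  events <- data.frame(
    output_position = seq_along(ev_step),
    step = ev_step,
    item_id = ev_item,
    serial_position = match(ev_item, list_items),
    classification = ev_class,
    stringsAsFactors = FALSE
  )
  structure(list(events = events, n_resets = n_resets, inhibited = inhibited,
                 study_list = study_list, params = params, trajectory = traj),
            class = "can_recall")
}

#' @export
print.can_recall <- function(x, ...) {
  cat("<can_recall>", sum(x$events$classification == "correct"),
      "correct,", sum(x$events$classification == "repetition"),
      "repetitions,", sum(x$events$classification == "intrusion"),
      "intrusions;", x$n_resets, "categorization resets\n")
  invisible(x)
}

#' Build the lexicon and study list for a named design
#'
#' @param design One of `"cvlt"` (16 items, 4 categories of 4, no two
#'   adjacent same-category), `"von_restorff"` (11 main-category items
#'   plus one isolate), `"same_category"` (all `n_list` items one
#'   category; the Von Restorff baseline) or `"unrelated"`.
#' @param params A [can_params].
#' @param isolate_position Serial position of the isolate
#'   (`"von_restorff"`) or of the matched critical item
#'   (`"same_category"`).
#' @param seed Optional integer seed.
#' @return List with elements `lexicon` and `study_list`.
#' @export
build_design <- function(design = c("cvlt", "von_restorff", "same_category",
                                    "unrelated"),
                         params, isolate_position = NULL, seed = NULL) {
  design <- match.arg(design)
  if (!is.null(seed)) set.seed(seed)
  if (design %in% c("von_restorff", "same_category") &&
      is.null(isolate_position))
    stop("isolate_position is required for the ", design, " design",
         call. = FALSE)
  if (design == "cvlt") {
    lex <- build_category_lexicon(c(a = 4L, b = 4L, c = 4L, d = 4L), params)
    sl <- make_cvlt_list(lex)
  } else if (design == "von_restorff") {
    lex <- build_category_lexicon(c(main = params$n_list - 1L, isolate = 1L),
                                  params)
    sl <- make_vr_list(lex, isolate_position)
  } else if (design == "same_category") {
    lex <- build_category_lexicon(stats::setNames(params$n_list, "main"),
                                  params)
    sl <- make_same_category_list(lex, isolate_position)
  } else {
    lex <- build_unrelated_lexicon(params)
    sl <- make_unrelated_list(lex)
  }
  list(lexicon = lex, study_list = sl)
}

#' Simulate one encode-retrieve trial of a named design
#'
#' @inheritParams build_design
#' @param seed Optional integer seed governing the lexicon, list order,
#'   weight initialization and noise of this trial.
#' @param log_trajectories Passed to [encode_list()] and [retrieve()].
#' @return List with `lexicon`, `study_list`, `encoding` and `recall`.
#' @export
run_trial <- function(design, params = can_params(), isolate_position = NULL,
                      seed = NULL, log_trajectories = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  d <- build_design(design, params, isolate_position)
  enc <- encode_list(d$lexicon, d$study_list, params,
                     log_trajectories = log_trajectories)
  rec <- retrieve(enc, params, log_trajectories = log_trajectories)
  list(lexicon = d$lexicon, study_list = d$study_list,
       encoding = enc, recall = rec)
}

#' Simulate many runs of a condition and aggregate its measures
#'
#' Builds a fresh lexicon and presentation order for every run (the CVLT
#' order is resampled each time), encodes and retrieves, and aggregates
#' serial-position recall probability, first-recall probability, the
#' chance-corrected clustering index (categorized designs), buffer
#' occupancy, and per-run recall counts.
#'
#' @inheritParams build_design
#' @param frontal If `FALSE`, runs the frontal-lesion model (overrides
#'   `params$frontal_enabled`).
#' @param n_runs Number of independent simulated trials.
#' @param seed Integer master seed; per-run seeds are derived from it.
#' @param clustering_scope Which recalls enter the clustering index:
#'   `"correct"` (default) or `"with_repetitions"`.
#' @return An object of class `can_condition`: list with the pooled
#'   `transcripts` data frame (`run_id` + recall events), `per_run`
#'   summaries (correct count, clustering index, late-window buffer
#'   occupancy, surprise count), the serial-position `curve` (see
#'   [recall_probability()]), `list_length`, and identifying metadata
#'   (`design`, `frontal`, `n_runs`, `seed`, `params`, `params_digest`).
#' @examples
#' \donttest{
#' cond <- run_condition("cvlt", frontal = FALSE, n_runs = 5, seed = 1)
#' mean(cond$per_run$clustering, na.rm = TRUE)
#' }
#' @export
run_condition <- function(design = c("cvlt", "von_restorff", "same_category",
                                     "unrelated"),
                          params = can_params(), isolate_position = NULL,
                          frontal = params$frontal_enabled,
                          n_runs = 100L, seed = 1L,
                          clustering_scope = c("correct", "with_repetitions")) {
  design <- match.arg(design)
  clustering_scope <- match.arg(clustering_scope)
  if (n_runs < 1L) stop("n_runs must be >= 1", call. = FALSE)
  params$frontal_enabled <- isTRUE(frontal)
  validate_params(params)
  set.seed(seed)
  run_seeds <- sample.int(2147483646L, n_runs)
  transcripts <- vector("list", n_runs)
  per_run <- data.frame(run_id = seq_len(n_runs), n_correct = 0L,
                        clustering = NA_real_, buffer_late = NA_real_,
                        n_surprise = 0L)
  list_length <- NA_integer_
  for (i in seq_len(n_runs)) {
    tr <- run_trial(design, params, isolate_position, seed = run_seeds[i])
    list_length <- length(tr$study_list$items)
    ev <- tr$recall$events
    ev$run_id <- rep.int(i, nrow(ev))
    transcripts[[i]] <- ev
    per_run$n_correct[i] <- sum(ev$classification == "correct")
    if (design %in% c("cvlt", "von_restorff"))
      per_run$clustering[i] <-
        tryCatch(clustering_index(ev, tr$study_list,
                                  scope = clustering_scope),
                 error = function(e) NA_real_)
    late <- tr$encoding$buffer_count
    late <- late[(length(late) - params$T_enc + 1L):length(late)]
    per_run$buffer_late[i] <- mean(late)
    per_run$n_surprise[i] <- sum(tr$encoding$surprise$surprised)
  }
  transcripts <- do.call(rbind, transcripts)
  curve <- if (nrow(transcripts) > 0L) {
    recall_probability(transcripts, list_length, n_runs = n_runs)
  } else {
    structure(data.frame(position = seq_len(list_length), p_recall = 0,
                         p_first = 0),
              n_runs = n_runs, class = c("can_spc", "data.frame"))
  }
  structure(list(design = design, frontal = params$frontal_enabled,
                 isolate_position = isolate_position, n_runs = n_runs,
                 seed = seed, params = params,
                 params_digest = params_digest(params),
                 list_length = list_length,
                 transcripts = transcripts, per_run = per_run,
                 curve = curve),
            class = "can_condition")
}

#' @export
print.can_condition <- function(x, ...) {
  cat("<can_condition> design =", x$design,
      if (!is.null(x$isolate_position) && !is.na(x$isolate_position[1]))
        paste0("(critical position ", x$isolate_position, ")") else "",
      "| frontal =", x$frontal, "| runs =", x$n_runs, "\n")
  cat("  mean correct recalls:", round(mean(x$per_run$n_correct), 2), "\n")
  if (any(!is.na(x$per_run$clustering)))
    cat("  mean clustering index:",
        round(mean(x$per_run$clustering, na.rm = TRUE), 2), "\n")
  invisible(x)
}
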