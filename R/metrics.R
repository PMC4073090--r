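#' Serial-position recall and first-recall probabilities
#'
#' For every serial position, the probability of recall is the fraction of
#' runs (or participants) in which the item presented there was correctly
#' recalled at least once; the probability of first recall (PFR) is the
#' fraction of runs whose very first retrieval event is that position's
#' correct recall.  PFR sums to at most 1 across positions (a run whose
#' first event is an intrusion, or that recalls nothing, contributes to no
#' position).
#'
#' @param transcripts A transcript data frame with columns `run_id`,
#'   `output_position`, `serial_position` and `classification` (the schema
#'   written by [run_condition()] / [write_transcripts()]).
#' @param list_length Number of serial positions.
#' @param n_runs Number of runs the transcripts come from; defaults to the
#'   number of distinct `run_id`s, but should be given explicitly when
#'   some runs recalled nothing (they leave no rows).
#' @return An object of class `can_spc`: data frame with columns
#'   `position`, `p_recall`, `p_first`, plus attribute `n_runs`.
#' @export
recall_probability <- function(transcripts, list_length,
                               n_runs = length(unique(transcripts$run_id))) {
  if (is.null(transcripts) || nrow(transcripts) == 0L)
    stop("empty transcript set", call. = FALSE)
  p_recall <- p_first <- numeric(list_length)
  correct <- transcripts[transcripts$classification == "correct", ]
  for (pos in seq_len(list_length)) {
    p_recall[pos] <- length(unique(correct$run_id[
      correct$serial_position == pos])) / n_runs
  }
  firsts <- transcripts[transcripts$output_position == 1L &
                          transcripts$classification == "correct", ]
  for (pos in seq_len(list_length)) {
    p_first[pos] <- sum(firsts$serial_position == pos, na.rm = TRUE) / n_runs
  }
  structure(data.frame(position = seq_len(list_length),
                       p_recall = p_recall, p_first = p_first),
            n_runs = n_runs, class = c("can_spc", "data.frame"))
}

resolve_categories <- function(transcript, category_of) {
  sp <- transcript$serial_position
  if (inherits(category_of, "can_study_list")) {
    ids <- category_of$items
    cats <- category_of$categories
    return(cats[match(transcript$item_id, ids)])
  }
  if (!is.null(names(category_of))) {
    return(unname(category_of[as.character(transcript$item_id)]))
  }
  stop("category_of must be a can_study_list or a named item -> category map",
       call. = FALSE)
}

#' Chance-corrected semantic clustering index
#'
#' The CVLT-style clustering score of a single recall transcript:
#' the observed number of adjacent same-category pairs in the scored
#' recall order, minus the number expected if the same recalls were
#' emitted in uniformly random order.  With `r_c` scored recalls from
#' category `c` and `R` scored recalls in total, the chance expectation
#' of adjacent same-category pairs is `sum_c r_c (r_c - 1) / R` (the mean
#' over all permutations).  Positive values indicate recall organized by
#' category beyond chance.
#'
#' By default only correct recalls are scored; repetitions and intrusions
#' are dropped before pair counting (`scope = "with_repetitions"` keeps
#' repeated correct list items in the sequence).
#'
#' @param transcript Recall events of a single run (data frame with
#'   `item_id`, `output_position`, `classification`).
#' @param category_of A `can_study_list`, or a named character vector
#'   mapping item id to category label.
#' @param scope `"correct"` or `"with_repetitions"`.
#' @return The clustering index (a single number).  Fewer than two scored
#'   recalls leave the index undefined: an error of class
#'   `can_undefined_metric` is signalled.
#' @examples
#' tr <- data.frame(item_id = 1:4, output_position = 1:4,
#'                  classification = "correct")
#' cats <- c(`1` = "A", `2` = "A", `3` = "B", `4` = "B")
#' clustering_index(tr, cats)  # observed 2, chance 1 -> 1
#' @export
clustering_index <- function(transcript, category_of,
                             scope = c("correct", "with_repetitions")) {
  scope <- match.arg(scope)
  keep <- if (scope == "correct") transcript$classification == "correct"
          else transcript$classification %in% c("correct", "repetition")
  tr <- transcript[keep, , drop = FALSE]
  if (scope == "with_repetitions") {
    # repetitions of intrusions carry no category; drop unmatched items
    cats_all <- resolve_categories(tr, category_of)
    tr <- tr[!is.na(cats_all), , drop = FALSE]
  }
  tr <- tr[order(tr$output_position), , drop = FALSE]
  cats <- resolve_categories(tr, category_of)
  R <- length(cats)
  if (R < 2L) {
    cnd <- simpleError("clustering index undefined for fewer than 2 scored recalls")
    class(cnd) <- c("can_undefined_metric", class(cnd))
    stop(cnd)
  }
  observed <- sum(cats[-1] == cats[-R])
  r_c <- table(cats)
  expected <- sum(r_c * (r_c - 1)) / R
  observed - expected
}

#' Isolate-advantage (Von Restorff) measures
#'
#' Compares recall of the critical item between a Von Restorff condition
#' (the critical item is a category isolate) and its same-category
#' baseline (the same serial position holds an item of the list's own
#' category).
#'
#' @param transcripts_vr,transcripts_baseline Pooled transcript data
#'   frames (or [run_condition()] results) for the isolate and baseline
#'   conditions.
#' @param isolate_position Serial position of the critical item, shared by
#'   both conditions.
#' @return List with `p_isolate` (probability of recalling the critical
#'   item in the isolate condition), `p_baseline` (same position, baseline
#'   condition), `advantage` (their difference), `se_advantage` (binomial
#'   standard error of the difference), `isolate_proportion` (isolates
#'   recalled over total correct recalls in the isolate condition) and the
#'   run counts.
#' @export
vr_measures <- function(transcripts_vr, transcripts_baseline,
                        isolate_position) {
  get_tr <- function(x) if (inherits(x, "can_condition")) x$transcripts else x
  check_pos <- function(x) {
    if (inherits(x, "can_condition") &&
        !is.null(x$isolate_position) && !is.na(x$isolate_position[1]) &&
        x$isolate_position != isolate_position)
      stop("condition critical position does not match isolate_position",
           call. = FALSE)
  }
  check_pos(transcripts_vr); check_pos(transcripts_baseline)
  tv <- get_tr(transcripts_vr); tb <- get_tr(transcripts_baseline)
  p_at <- function(tr, pos) {
    runs <- unique(tr$run_id)
    hit <- tr$classification == "correct" & tr$serial_position == pos
    c(p = length(unique(tr$run_id[hit])) / length(runs), n = length(runs))
  }
  pv <- p_at(tv, isolate_position)
  pb <- p_at(tb, isolate_position)
  n_correct <- sum(tv$classification == "correct")
  n_isolate <- sum(tv$classification == "correct" &
                     tv$serial_position == isolate_position)
  se <- sqrt(pv["p"] * (1 - pv["p"]) / pv["n"] +
               pb["p"] * (1 - pb["p"]) / pb["n"])
  list(p_isolate = unname(pv["p"]),
       p_baseline = unname(pb["p"]),
       advantage = unname(pv["p"] - pb["p"]),
       se_advantage = unname(se),
       isolate_proportion = if (n_correct > 0) n_isolate / n_correct
                            else NA_real_,
       n_runs_vr = unname(pv["n"]), n_runs_baseline = unname(pb["n"]),
       isolate_position = isolate_position)
}

#' Lag conditional response probability (lag-CRP)
#'
#' The standard temporal-order measure of free recall: for every signed
#' lag, the number of observed transitions between successively recalled
#' serial positions at that lag, divided by the number of times that lag
#' was available.  Repetitions and intrusions are excluded from both the
#' transition and the availability sets (transitions are taken between
#' successive *correct* recalls after pruning).
#'
#' @inheritParams recall_probability
#' @return Data frame with columns `lag` (`-(L-1) .. L-1`, excluding 0),
#'   `crp` (`NA` where the lag was never available), `n_obs`, `n_avail`.
#' @export
lag_crp <- function(transcripts, list_length) {
  lags <- setdiff(seq(-(list_length - 1L), list_length - 1L), 0L)
  n_obs <- n_avail <- stats::setNames(numeric(length(lags)), lags)
  for (rid in unique(transcripts$run_id)) {
    tr <- transcripts[transcripts$run_id == rid &
                        transcripts$classification == "correct", ]
    tr <- tr[order(tr$output_position), ]
    sp <- tr$serial_position
    if (length(sp) < 2L) next
    remaining <- setdiff(seq_len(list_length), sp[1])
    for (i in seq_len(length(sp) - 1L)) {
      avail <- as.character(remaining - sp[i])
      n_avail[avail] <- n_avail[avail] + 1
      n_obs[as.character(sp[i + 1L] - sp[i])] <-
        n_obs[as.character(sp[i + 1L] - sp[i])] + 1
      remaining <- setdiff(remaining, sp[i + 1L])
    }
  }
  data.frame(lag = as.integer(names(n_obs)),
             crp = ifelse(n_avail > 0, n_obs / n_avail, NA_real_),
             n_obs = as.numeric(n_obs), n_avail = as.numeric(n_avail),
             row.names = NULL)
}

#' Read and write recall transcripts
#'
#' Transcripts use one CSV schema for simulated and empirical data:
#' columns `run_id`, `output_position`, `step` (optional for empirical
#' data), `item_id`, `serial_position` (`NA` for intrusions) and
#' `classification`.
#'
#' @param transcripts Transcript data frame.
#' @param path CSV file path.
#' @param header_comment Optional `#` header line content (e.g. seed and
#'   parameter digest).
#' @return `read_transcripts()` returns the transcript data frame;
#'   `write_transcripts()` returns `path` invisibly.
#' @export
write_transcripts <- function(transcripts, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.csv(transcripts, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transcripts
#' @export
read_transcripts <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("run_id", "output_position", "item_id", "serial_position",
            "classification")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop("transcript file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df
}
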