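#' Detect novelty ("surprise") from the semantic prediction mismatch
#'
#' The novelty mechanism compares the current semantic activation with the
#' adaptation vector — a leaky integral of its history that acts as the
#' network's prediction — and scores the mismatch as
#' `sum_i |F(y_i) - a_i|`.  A surprise is signalled when the score crosses
#' `theta_surprise`.  The `"variance_normalized"` variant divides the score
#' by `var(F(B)) + 1`, where `F(B)` is the semantic activation over a
#' recent time window: in an unrelated list the window variance is large
#' and damps spurious surprises, while in a categorized list it is small
#' and leaves a genuine isolate's mismatch nearly untouched.
#'
#' A lesioned model (`frontal_enabled = FALSE`) never detects novelty: the
#' result is always inactive with the magnitude still reported.
#'
#' @param y Semantic activation vector (raw; `F` is applied internally).
#' @param a Adaptation vector (already in `F`-units).
#' @param params A [can_params]; uses `theta_surprise`, `surprise_variant`
#'   and `frontal_enabled`.
#' @param history_window For the variance-normalized variant, a numeric
#'   matrix (steps x features) or vector of recent `F(y)` values; required
#'   for that variant, ignored by the raw variant.
#' @param variant Overrides `params$surprise_variant` when given.
#' @return An object of class `can_surprise`: list with `active` (flag),
#'   `magnitude` (the thresholded score, `>= 0`) and `variant`.
#' @examples
#' p <- can_params()
#' y <- rep(1, p$n_sem)              # F(y) = 0.5 everywhere
#' detect_surprise(y, activation_fn(y), p)$active   # perfect prediction
#' @export
detect_surprise <- function(y, a, params, history_window = NULL,
                            variant = NULL) {
  if (length(y) != length(a))
    stop("y and a must have equal length", call. = FALSE)
  variant <- if (is.null(variant)) params$surprise_variant
             else match.arg(variant, c("raw", "variance_normalized"))
  magnitude <- sum(abs(activation_fn(y) - a))
  if (variant == "variance_normalized") {
    if (is.null(history_window) || length(history_window) == 0L)
      stop("variance_normalized surprise requires a non-empty history_window",
           call. = FALSE)
    magnitude <- magnitude / (stats::var(as.vector(history_window)) + 1)
  }
  structure(list(
    active = params$frontal_enabled && magnitude > params$theta_surprise,
    magnitude = magnitude,
    variant = variant
  ), class = "can_surprise")
}

#' Effective input and learning rate under a surprise
#'
#' Maps a surprise decision to the effective (sensory input, Hebbian
#' learning rate) pair used for the current item: the boosted
#' `(input_surprise, delta_surprise)` while a surprise is latched, the
#' baseline `(input_base, delta)` otherwise.  The boost is scoped to the
#' current item only — it is withdrawn at item offset, never carried into
#' the next item.
#'
#' @param params A [can_params].
#' @param surprise A `can_surprise` (or any list with an `active` flag).
#' @return Named list with elements `input` and `rate`.
#' @export
apply_surprise <- function(params, surprise) {
  if (isTRUE(surprise$active)) {
    list(input = params$input_surprise, rate = params$delta_surprise)
  } else {
    list(input = params$input_base, rate = params$delta)
  }
}
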