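#' Saturating activation function
#'
#' The rate function used by every layer of the network:
#' `F(v) = v / (1 + v)` for `v > 0` and `0` otherwise.  It maps activations
#' into `[0, 1)` and is monotone non-decreasing.
#'
#' @param v Numeric vector of activations.
#' @return Numeric vector of the same length, in `[0, 1)`.
#' @examples
#' activation_fn(c(-2, 0, 1, 9))  # 0, 0, 0.5, 0.9
#' @export
activation_fn <- function(v) {
  out <- v / (1 + v)
  out[v <= 0] <- 0
  out
}

#' Network state of the CAN model
#'
#' Bundles the activation vectors of the three layers and the semantic
#' adaptation vector.  All activations start at zero.
#'
#' @param params A [can_params] object (layer sizes are taken from it).
#' @return An object of class `can_state` with fields `x` (lexical,
#'   `n_lex`), `y` (semantic, `n_sem`), `z` (categorization, `n_cat`) and
#'   `a` (semantic adaptation, `n_sem`).
#' @export
can_state <- function(params) {
  structure(list(x = numeric(params$n_lex),
                 y = numeric(params$n_sem),
                 z = numeric(params$n_cat),
                 a = numeric(params$n_sem)),
            class = "can_state")
}

#' Connection weights of the CAN model
#'
#' @param W_xy Binary lexical-semantic connectivity matrix
#'   (`n_lex x n_sem`); the same matrix serves both directions (the
#'   coupling is symmetric).
#' @param params A [can_params] object.
#' @param seed Optional integer seed for the random initial
#'   semantic-categorization weights.
#' @return An object of class `can_weights` with fields `W_xy`, `W_yz`
#'   (`n_sem x n_cat`, initialized `U(0, 1)` and rescaled so every
#'   categorization unit starts with the same incoming norm — the weight
#'   budget the normalization rule conserves thereafter), and the context
#'   weight vectors `Cx`, `Cy`, `Cz` (all zero-initialized).
#' @export
can_weights <- function(W_xy, params, seed = NULL) {
  stopifnot(is.matrix(W_xy),
            nrow(W_xy) == params$n_lex, ncol(W_xy) == params$n_sem)
  if (!is.null(seed)) set.seed(seed)
  W_yz <- matrix(stats::runif(params$n_sem * params$n_cat),
                 params$n_sem, params$n_cat)
  # equalize the synaptic budget: competition is then directional, not a
  # matter of which unit drew globally larger weights
  target <- sqrt(params$n_sem / 3)   # E[norm] of a U(0,1) column
  W_yz <- sweep(W_yz, 2, target / sqrt(colSums(W_yz^2)), "*")
  structure(list(
    W_xy = W_xy,
    W_yz = W_yz,
    Cx = numeric(params$n_lex),
    Cy = numeric(params$n_sem),
    Cz = numeric(params$n_cat)
  ), class = "can_weights")
}

check_dims <- function(state, weights, params) {
  if (length(state$x) != params$n_lex || length(state$y) != params$n_sem ||
      length(state$z) != params$n_cat || length(state$a) != params$n_sem ||
      nrow(weights$W_xy) != params$n_lex || ncol(weights$W_xy) != params$n_sem ||
      nrow(weights$W_yz) != params$n_sem || ncol(weights$W_yz) != params$n_cat) {
    stop("state/weights dimensions do not match the parameter set",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' One time step of the lexical layer (activation buffer)
#'
#' Applies the buffer update
#' `x(t) = lambda * x(t-1) + (1 - lambda) * [alpha F(x) - beta_x sum F(x_j)
#'  + I + xi W_xy F(y) + mu_x Cx (retrieval only) + N(0, noise_sd)]`,
#' where all right-hand activations are the previous step's, then floors
#' the result at zero.  Self-excitation against global inhibition makes the
#' layer a limited-capacity buffer: 3-4 units stay co-active during list
#' presentation.  Gaussian noise is resampled per unit per step; with
#' `noise_sd = 0` the map is deterministic.
#'
#' @param state A [can_state] (previous step).
#' @param weights A [can_weights].
#' @param input_vec Non-negative sensory input, length `n_lex` (the clamped
#'   input on the current item's unit, zero elsewhere; empty at retrieval).
#' @param params A [can_params].
#' @param retrieval_mode If `TRUE`, adds the context drive `mu_x * Cx`.
#' @return New lexical activation vector, element-wise `>= 0`.
#' @export
step_lexical <- function(state, weights, input_vec, params,
                         retrieval_mode = FALSE) {
  check_dims(state, weights, params)
  if (length(input_vec) != params$n_lex)
    stop("input_vec must have length n_lex", call. = FALSE)
  Fx <- activation_fn(state$x)
  Fy <- activation_fn(state$y)
  current <- params$alpha * Fx - params$beta_x * sum(Fx) + input_vec +
    params$xi * drop(weights$W_xy %*% Fy)
  if (retrieval_mode) current <- current + params$mu_x * weights$Cx
  if (params$noise_sd > 0)
    current <- current + stats::rnorm(params$n_lex, 0, params$noise_sd)
  pmax(params$lambda_ * state$x + (1 - params$lambda_) * current, 0)
}

#' One time step of the semantic-features layer
#'
#' Applies
#' `y(t) = lambda * y(t-1) + (1 - lambda) * [-beta_y sum F(y_j)
#'  + chi W_yx F(x) - kappa a(t)]`, floored at zero.  `state$a` must
#' already hold the current step's adaptation (it is updated first in the
#' per-step order).  In retrieval mode two further drives are added inside
#' the bracket: the context term `mu_y * Cy` and the categorization
#' feedback `varpi * W_yz F(z)`.
#'
#' @inheritParams step_lexical
#' @param retrieval_mode If `TRUE`, adds the context and categorization
#'   drives.
#' @return New semantic activation vector, element-wise `>= 0`.
#' @export
step_semantic <- function(state, weights, params, retrieval_mode = FALSE) {
  check_dims(state, weights, params)
  Fx <- activation_fn(state$x)
  Fy <- activation_fn(state$y)
  current <- -params$beta_y * sum(Fy) +
    params$chi * drop(crossprod(weights$W_xy, Fx)) -
    params$kappa * state$a
  if (retrieval_mode) {
    Fz <- activation_fn(state$z)
    current <- current + params$mu_y * weights$Cy +
      params$varpi * drop(weights$W_yz %*% Fz)
  }
  pmax(params$lambda_ * state$y + (1 - params$lambda_) * current, 0)
}

#' Update the semantic adaptation (leaky activation history)
#'
#' `a(t) = lambda_a * a(t-1) + (1 - lambda_a) * F(y(t-1))`.  The adaptation
#' vector is the network's prediction of the semantic activation; the
#' novelty mechanism compares it with the actual activation.
#'
#' @param a_prev Adaptation vector at the previous step (length `n_sem`).
#' @param y_prev Semantic activation at the previous step (length `n_sem`).
#' @param params A [can_params].
#' @return Updated adaptation vector, element-wise in `[0, 1)`.
#' @export
update_adaptation <- function(a_prev, y_prev, params) {
  if (length(a_prev) != length(y_prev))
    stop("a_prev and y_prev must have equal length", call. = FALSE)
  params$lambda_a * a_prev + (1 - params$lambda_a) * activation_fn(y_prev)
}

#' One time step of the categorization layer
#'
#' Applies
#' `z(t) = lambda * z(t-1) + (1 - lambda) * [-beta_z sum F(z_j)
#'  + phi W_zy F(y)]`, floored at zero, with `phi = phi_enc` during
#' encoding and the reduced `phi_ret` during retrieval, when the context
#' drive `mu_z * Cz` is also added.  Strong competition (`beta_z`) makes a
#' single unit (occasionally a few) win for each presented category.
#'
#' @inheritParams step_lexical
#' @param retrieval_mode If `TRUE`, uses `phi_ret` and adds `mu_z * Cz`.
#' @param inhibited Optional logical vector (length `n_cat`) of units
#'   permanently inhibited by the retrieval monitor; their activation is
#'   clamped to zero.
#' @return New categorization activation vector, element-wise `>= 0`.
#' @export
step_categorization <- function(state, weights, params,
                                retrieval_mode = FALSE, inhibited = NULL) {
  check_dims(state, weights, params)
  Fy <- activation_fn(state$y)
  Fz <- activation_fn(state$z)
  phi <- if (retrieval_mode) params$phi_ret else params$phi_enc
  current <- -params$beta_z * sum(Fz) + phi * drop(crossprod(weights$W_yz, Fy))
  if (retrieval_mode) current <- current + params$mu_z * weights$Cz
  z_new <- pmax(params$lambda_ * state$z + (1 - params$lambda_) * current, 0)
  if (!is.null(inhibited)) z_new[inhibited] <- 0
  z_new
}
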