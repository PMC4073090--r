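#' Fast Hebbian category learning with weight normalization
#'
#' Strengthens the connections between every categorization unit whose
#' activation crosses the learning threshold and the currently active
#' semantic features: column `k` of `W_yz` gains
#' `rate * F(z_k) * F(y)`, after which that unit's incoming weight vector
#' is renormalized.  Units below threshold keep their column untouched.
#' Normalization implements competition for synaptic resources: repeated
#' pairing with a category concentrates the unit's fixed weight budget on
#' the category's shared features.
#'
#' @param W_yz Semantic-categorization weight matrix (`n_sem x n_cat`),
#'   non-negative.
#' @param z Categorization activation vector (raw, not `F`-transformed).
#' @param y Semantic activation vector (raw).
#' @param rate Learning rate `delta` (or its surprise-boosted value);
#'   must be non-negative.
#' @param theta_learn Learning threshold on `z`.
#' @param norm_mode `"preserve"` rescales an updated column to its
#'   pre-update Euclidean norm (default; total synaptic strength per unit
#'   is invariant), `"unit"` rescales to unit norm, `"none"` skips
#'   normalization (raw Hebbian increment, mainly for inspection).
#' @return The updated weight matrix.
#' @export
hebbian_update_category <- function(W_yz, z, y, rate, theta_learn,
                                    norm_mode = c("preserve", "unit", "none")) {
  norm_mode <- match.arg(norm_mode)
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0)
    stop("rate must be a single non-negative number", call. = FALSE)
  if (nrow(W_yz) != length(y) || ncol(W_yz) != length(z))
    stop("W_yz dimensions do not match z/y", call. = FALSE)
  winners <- which(z > theta_learn)
  if (length(winners) == 0L || rate == 0) return(W_yz)
  Fy <- activation_fn(y)
  Fz <- activation_fn(z)
  for (k in winners) {
    old_norm <- sqrt(sum(W_yz[, k]^2))
    col <- W_yz[, k] + rate * Fz[k] * Fy
    if (norm_mode == "preserve") {
      new_norm <- sqrt(sum(col^2))
      if (new_norm > 0) col <- col * (old_norm / new_norm)
    } else if (norm_mode == "unit") {
      new_norm <- sqrt(sum(col^2))
      if (new_norm > 0) col <- col / new_norm
    }
    W_yz[, k] <- col
  }
  W_yz
}

#' Episodic context learning
#'
#' One encoding step of Hebbian learning between the single list-context
#' unit and the three layers: each context weight vector grows by the
#' current `F`-activation of its layer (`Cx_i += F(x_i)`, and likewise for
#' `Cy`, `Cz`).  Context weights never decrease, so after encoding they
#' integrate how long and how strongly each unit was active — the episodic
#' trace that cues retrieval.  Context learning is applied only during
#' encoding; at retrieval the weights are frozen.
#'
#' @param weights A [can_weights].
#' @param state A [can_state] holding the current (post-update) activations.
#' @return The updated [can_weights].
#' @export
update_context <- function(weights, state) {
  weights$Cx <- weights$Cx + activation_fn(state$x)
  weights$Cy <- weights$Cy + activation_fn(state$y)
  weights$Cz <- weights$Cz + activation_fn(state$z)
  weights
}
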