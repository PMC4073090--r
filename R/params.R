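#' Model parameters for the CAN free-recall network
#'
#' Constructs the full parameter set of the categorization-activation-novelty
#' (CAN) network.  The defaults are the package's calibrated profile: they
#' were selected by grid search so that the intact model shows a 3-4 item
#' activation buffer, primacy and recency, strong semantic clustering of
#' CVLT-like lists, and a serial-position-dependent isolation (Von Restorff)
#' advantage, while the frontal-lesion mode shows weaker clustering and no
#' isolation advantage.  See the package vignette for the calibration ranges
#' and the role of each parameter.
#'
#' @param lambda_ Time constant of the layer dynamics, in `[0, 1]`; the
#'   fraction of the previous activation carried into the next step.
#' @param lambda_a Time constant of the semantic adaptation integrator, in
#'   `[0, 1]`.  Larger values integrate activation history over a longer
#'   window.
#' @param alpha Lexical self-excitation gain (net of any self-inhibition;
#'   the global-inhibition sum below includes the unit's own term).
#' @param beta_x,beta_y,beta_z Global lateral inhibition gains of the
#'   lexical, semantic and categorization layers.
#' @param xi Gain of the semantic-to-lexical feedback.
#' @param chi Gain of the lexical-to-semantic drive.
#' @param kappa Gain of the adaptation term subtracted from the semantic
#'   input current.
#' @param phi_enc,phi_ret Gain of the semantic-to-categorization drive at
#'   encoding and its reduced value at retrieval (`phi_ret <= phi_enc`).
#' @param varpi Gain of the categorization-to-semantic drive at retrieval.
#' @param input_base,input_surprise Sensory input clamped on the current
#'   item's lexical unit, and its boosted value while a surprise is latched
#'   (`input_surprise >= input_base`).
#' @param delta,delta_surprise Fast Hebbian learning rate between the
#'   semantic and categorization layers, and its boosted value under
#'   surprise (`delta_surprise >= delta`).
#' @param mu_x,mu_y,mu_z Context-to-layer gains applied at retrieval.
#' @param noise_sd Standard deviation of the Gaussian noise added to the
#'   lexical input current each step (0.2 in the reference simulations).
#' @param theta_learn Categorization activation threshold above which fast
#'   Hebbian learning is triggered (also used to decide which units were
#'   "active" when the retrieval monitor inhibits them).
#' @param theta_retrieve Lexical activation threshold at which an item
#'   counts as recalled.
#' @param theta_surprise Threshold on the semantic prediction-mismatch score
#'   above which a surprise is latched.
#' @param theta_buffer Diagnostic threshold (in `F`-activation units) used
#'   only to report how many lexical units are "in the buffer"; it plays no
#'   role in the dynamics.
#' @param T_enc Number of time steps each list item is clamped for.
#' @param T_ret Total number of retrieval time steps.
#' @param max_unsuccessful Number of tolerated unsuccessful retrievals
#'   (repetitions plus intrusions) before the categorization layer is reset;
#'   the reset fires on the `max_unsuccessful + 1`-th event.
#' @param n_lex,n_sem,n_cat Layer sizes (lexical, semantic, categorization).
#' @param n_list Default list length for 12-item designs (CVLT lists use 16).
#' @param p_conn Probability that a lexical-semantic connection exists
#'   (random features).
#' @param n_shared Number of semantic features shared by all members of a
#'   category.
#' @param surprise_variant `"raw"` uses the summed absolute prediction
#'   mismatch; `"variance_normalized"` divides it by one plus the variance
#'   of recent semantic activation before thresholding.
#' @param surprise_window Length (in steps) of the activation-history window
#'   used by the variance-normalized surprise variant; defaults to one item
#'   presentation (`T_enc`).
#' @param suppress_first_surprise If `TRUE`, the first presented item never
#'   latches a surprise (with zero adaptation the very first item always has
#'   a large mismatch); the default `FALSE` lets the threshold decide, which
#'   affects all list types equally.
#' @param norm_mode How the incoming weight vector of a categorization unit
#'   is renormalized after a Hebbian update: `"preserve"` rescales it to the
#'   norm it had before the update (default), `"unit"` to unit norm.
#' @param frontal_enabled If `FALSE`, the frontal mechanisms are lesioned:
#'   no fast Hebbian category learning and no novelty detection.
#'
#' @return An object of class `can_params`: a validated named list.
#' @examples
#' p <- can_params()
#' p$alpha
#' p_lesion <- can_params(frontal_enabled = FALSE)
#' @seealso [load_config()], [write_config()]
#' @export
can_params <- function(lambda_ = 0.8,
                       lambda_a = 0.95,
                       alpha = 2.0,
                       beta_x = 0.25,
                       beta_y = 0.05,
                       beta_z = 2.1,
                       xi = 0.16,
                       chi = 1.5,
                       kappa = 0.6,
                       phi_enc = 1.2,
                       phi_ret = 0.45,
                       varpi = 2.1,
                       input_base = 1.2,
                       input_surprise = 1.7,
                       delta = 0.005,
                       delta_surprise = 0.1,
                       mu_x = 0.006,
                       mu_y = 0.0023,
                       mu_z = 0.018,
                       noise_sd = 0.2,
                       theta_learn = 1.2,
                       theta_retrieve = 1.3,
                       theta_surprise = 1.9,
                       theta_buffer = 0.45,
                       T_enc = 25L,
                       T_ret = 700L,
                       max_unsuccessful = 2L,
                       n_lex = 50L,
                       n_sem = 45L,
                       n_cat = 10L,
                       n_list = 12L,
                       p_conn = 0.16,
                       n_shared = 5L,
                       surprise_variant = c("raw", "variance_normalized"),
                       surprise_window = NULL,
                       suppress_first_surprise = FALSE,
                       norm_mode = c("preserve", "unit"),
                       frontal_enabled = TRUE) {
  surprise_variant <- match.arg(surprise_variant)
  norm_mode <- match.arg(norm_mode)
  if (is.null(surprise_window)) surprise_window <- as.integer(T_enc)
  p <- list(
    lambda_ = lambda_, lambda_a = lambda_a, alpha = alpha,
    beta_x = beta_x, beta_y = beta_y, beta_z = beta_z,
    xi = xi, chi = chi, kappa = kappa,
    phi_enc = phi_enc, phi_ret = phi_ret, varpi = varpi,
    input_base = input_base, input_surprise = input_surprise,
    delta = delta, delta_surprise = delta_surprise,
    mu_x = mu_x, mu_y = mu_y, mu_z = mu_z,
    noise_sd = noise_sd,
    theta_learn = theta_learn, theta_retrieve = theta_retrieve,
    theta_surprise = theta_surprise, theta_buffer = theta_buffer,
    T_enc = as.integer(T_enc), T_ret = as.integer(T_ret),
    max_unsuccessful = as.integer(max_unsuccessful),
    n_lex = as.integer(n_lex), n_sem = as.integer(n_sem),
    n_cat = as.integer(n_cat), n_list = as.integer(n_list),
    p_conn = p_conn, n_shared = as.integer(n_shared),
    surprise_variant = surprise_variant,
    surprise_window = as.integer(surprise_window),
    suppress_first_surprise = isTRUE(suppress_first_surprise),
    norm_mode = norm_mode,
    frontal_enabled = isTRUE(frontal_enabled)
  )
  class(p) <- "can_params"
  validate_params(p)
}

#' Validate a `can_params` object
#'
#' Checks every invariant of the parameter set (ranges, orderings between
#' baseline and boosted values, positive sizes) and fails with the name of
#' the offending field.
#'
#' @param p A `can_params` object (or a plain named list with the same
#'   fields).
#' @return `p`, invisibly classed as `can_params`, if valid.
#' @export
validate_params <- function(p) {
  chk <- function(cond, field, msg) {
    if (!isTRUE(cond)) stop("invalid parameter `", field, "`: ", msg, call. = FALSE)
  }
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  for (f in c("lambda_", "lambda_a", "alpha", "beta_x", "beta_y", "beta_z",
              "xi", "chi", "kappa", "phi_enc", "phi_ret", "varpi",
              "input_base", "input_surprise", "delta", "delta_surprise",
              "mu_x", "mu_y", "mu_z", "noise_sd",
              "theta_learn", "theta_retrieve", "theta_surprise",
              "theta_buffer", "p_conn")) {
    chk(num1(p[[f]]), f, "must be a single finite number")
  }
  chk(p$lambda_ >= 0 && p$lambda_ <= 1, "lambda_", "must lie in [0, 1]")
  chk(p$lambda_a >= 0 && p$lambda_a <= 1, "lambda_a", "must lie in [0, 1]")
  for (f in c("alpha", "beta_x", "beta_y", "beta_z", "xi", "chi", "kappa",
              "phi_enc", "phi_ret", "varpi", "input_base", "input_surprise",
              "delta", "delta_surprise", "mu_x", "mu_y", "mu_z", "noise_sd",
              "theta_learn", "theta_retrieve", "theta_surprise",
              "theta_buffer")) {
    chk(p[[f]] >= 0, f, "must be non-negative")
  }
  chk(p$phi_ret <= p$phi_enc, "phi_ret", "must not exceed phi_enc")
  chk(p$input_surprise >= p$input_base, "input_surprise",
      "must be at least input_base")
  chk(p$delta_surprise >= p$delta, "delta_surprise", "must be at least delta")
  chk(p$p_conn >= 0 && p$p_conn <= 1, "p_conn", "must lie in [0, 1]")
  for (f in c("T_enc", "T_ret", "n_lex", "n_sem", "n_cat", "n_list",
              "n_shared", "surprise_window")) {
    chk(is.numeric(p[[f]]) && length(p[[f]]) == 1L && p[[f]] >= 1 &&
          p[[f]] == as.integer(p[[f]]), f, "must be a positive integer")
  }
  chk(is.numeric(p$max_unsuccessful) && p$max_unsuccessful >= 0,
      "max_unsuccessful", "must be a non-negative integer")
  chk(p$n_list <= p$n_lex, "n_list", "cannot exceed n_lex")
  chk(p$surprise_variant %in% c("raw", "variance_normalized"),
      "surprise_variant", "must be 'raw' or 'variance_normalized'")
  chk(p$norm_mode %in% c("preserve", "unit"), "norm_mode",
      "must be 'preserve' or 'unit'")
  chk(is.logical(p$frontal_enabled) && length(p$frontal_enabled) == 1L,
      "frontal_enabled", "must be TRUE or FALSE")
  class(p) <- "can_params"
  invisible(p)
}

#' @export
print.can_params <- function(x, ...) {
  cat("<can_params>  (", if (x$frontal_enabled) "intact" else "frontal-lesioned",
      " model)\n", sep = "")
  nm <- setdiff(names(x), c("surprise_variant", "norm_mode", "frontal_enabled",
                            "suppress_first_surprise"))
  vals <- vapply(x[nm], function(v) format(v, digits = 4), character(1))
  cat(paste0("  ", format(nm), " = ", vals), sep = "\n")
  cat("  surprise_variant = ", x$surprise_variant,
      ", norm_mode = ", x$norm_mode,
      ", suppress_first_surprise = ", x$suppress_first_surprise, "\n", sep = "")
  invisible(x)
}

# fields whose config-file representation is not numeric
.char_fields <- c("surprise_variant", "norm_mode")
.flag_fields <- c("suppress_first_surprise", "frontal_enabled")

#' Load model parameters from a flat key/value configuration file
#'
#' Reads a plain-text configuration with one `key = value` (or `key: value`)
#' pair per line; `#` starts a comment.  Keys must be `can_params` field
#' names; unknown keys are rejected.  Missing keys take the calibrated
#' default.  An empty file therefore yields `can_params()`.
#'
#' @param path Path to the configuration file.
#' @return A validated [can_params] object.
#' @examples
#' tmp <- tempfile(fileext = ".cfg")
#' writeLines(c("alpha = 2.0", "frontal_enabled = FALSE"), tmp)
#' load_config(tmp)$frontal_enabled
#' @seealso [write_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  overrides <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[=:]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("cannot parse config line: '", ln, "'", call. = FALSE)
    key <- m[2]; val <- trimws(m[3])
    if (!key %in% names(formals(can_params))) {
      stop("unknown configuration key: '", key, "'", call. = FALSE)
    }
    overrides[[key]] <-
      if (key %in% .char_fields) val
      else if (key %in% .flag_fields) toupper(val) %in% c("TRUE", "T", "YES", "1")
      else {
        v <- suppressWarnings(as.numeric(val))
        if (is.na(v)) stop("non-numeric value for key '", key, "': ", val,
                           call. = FALSE)
        v
      }
  }
  do.call(can_params, overrides)
}

#' Write a resolved parameter set to a flat key/value file
#'
#' The written file round-trips through [load_config()] to an identical
#' parameter set.
#'
#' @param params A [can_params] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  params <- validate_params(params)
  fmt <- function(f) {
    v <- params[[f]]
    if (is.character(v)) v else if (is.logical(v)) as.character(v)
    else format(v, digits = 17)
  }
  nm <- names(unclass(params))
  writeLines(paste0(nm, " = ", vapply(nm, fmt, character(1))), path)
  invisible(path)
}

#' Short digest identifying a parameter set
#'
#' A compact checksum of the resolved parameter values, embedded in run
#' artifacts so that any result can be traced to the exact configuration
#' that produced it.
#'
#' @param params A [can_params] object.
#' @return A character scalar.
#' @export
params_digest <- function(params) {
  params <- validate_params(params)
  s <- paste(names(unclass(params)),
             vapply(unclass(params), function(v) paste(format(v, digits = 17),
                                                       collapse = ","),
                    character(1)),
             sep = "=", collapse = ";")
  # small rolling checksum; avoids a cryptographic dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("p%08x", h)
}
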