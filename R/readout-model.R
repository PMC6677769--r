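#' Construct a cortical readout linking model
#'
#' A probit linking model for two-alternative forced-choice decisions: the
#' responses of visual areas to the two dot patches are linearly weighted
#' into a scalar per patch, the difference (plus a side bias) is passed
#' through a cumulative normal with unit noise, and a lapse rate mixes in
#' stimulus-independent guessing.
#'
#' A *fixed* readout shares one weight per area across the contrast and
#' coherence tasks; a *flexible* readout fits one weight per area per task.
#'
#' @param areas Character vector of area labels.
#' @param weights Readout weights. For `readout_mode = "fixed"` a named
#'   numeric vector over `areas`; for `"flexible"` a list with elements
#'   `contrast` and `coherence`, each a named numeric vector.
#' @param beta_bias Side bias added to the decision variable.
#' @param lapse Lapse probability \eqn{\lambda \in [0, 1]}.
#' @param readout_mode `"fixed"` or `"flexible"`.
#' @param noise_mode `"additive"` (unit Gaussian noise) or `"poisson"`
#'   (noise variance set to the mean unweighted population response of the
#'   two patches).
#' @param selection_rho Optional efficient-selection exponent \eqn{\rho \ge 1}:
#'   area responses are raised to \eqn{\rho} (sign-preserving) before
#'   weighting and the \eqn{\rho}-th root of the aggregate is taken.
#' @param history Optional named numeric vector of stay/switch coefficients
#'   `c(beta_left_correct, beta_right_correct, beta_left_incorrect,
#'   beta_right_incorrect)`.
#' @param memory_cost Working-memory cost factor applied on post-cued catch
#'   trials: the decision variable is divided by this factor (equivalently,
#'   the noise standard deviation is scaled up). Default 1 (no cost).
#' @return An object of class `readout_model`.
#' @export
readout_model <- function(areas, weights, beta_bias = 0, lapse = 0,
                          readout_mode = c("flexible", "fixed"),
                          noise_mode = c("additive", "poisson"),
                          selection_rho = NULL, history = NULL,
                          memory_cost = 1) {
  readout_mode <- match.arg(readout_mode)
  noise_mode <- match.arg(noise_mode)
  check_prob(lapse, "lapse")
  if (!is.null(selection_rho)) stopifnot(selection_rho >= 1)
  if (!is.null(history)) {
    needed <- c("beta_left_correct", "beta_right_correct",
                "beta_left_incorrect", "beta_right_incorrect")
    stopifnot(all(needed %in% names(history)))
    history <- history[needed]
  }
  if (readout_mode == "fixed") {
    stopifnot(is.numeric(weights), all(areas %in% names(weights)))
    w <- list(contrast = weights[areas], coherence = weights[areas])
  } else {
    stopifnot(is.list(weights), all(c("contrast", "coherence") %in% names(weights)))
    stopifnot(all(areas %in% names(weights$contrast)),
              all(areas %in% names(weights$coherence)))
    w <- list(contrast = weights$contrast[areas],
              coherence = weights$coherence[areas])
  }
  stopifnot(memory_cost > 0)
  structure(
    list(areas = areas, weights = w, beta_bias = beta_bias, lapse = lapse,
         readout_mode = readout_mode, noise_mode = noise_mode,
         selection_rho = selection_rho, history = history,
         memory_cost = memory_cost),
    class = "readout_model"
  )
}

#' @export
print.readout_model <- function(x, ...) {
  cat(sprintf("<readout_model: %s readout, %s noise, %d areas>\n",
              x$readout_mode, x$noise_mode, length(x$areas)))
  cat("  contrast task weights: ",
      paste(sprintf("%s=%.3g", x$areas, x$weights$contrast), collapse = " "), "\n")
  if (x$readout_mode == "flexible") {
    cat("  coherence task weights:",
        paste(sprintf("%s=%.3g", x$areas, x$weights$coherence), collapse = " "), "\n")
  }
  cat(sprintf("  bias=%.3g lapse=%.3g\n", x$beta_bias, x$lapse))
  invisible(x)
}

#' Number of free parameters of a readout model specification
#'
#' Fixed readout: one weight per area plus one bias. Flexible readout: one
#' weight per area per task plus one bias. Optional history terms add four
#' parameters and the selection exponent adds one.
#'
#' @param model A [readout_model()] or a model specification list with
#'   elements `areas`, `readout_mode`, and optionally `history`,
#'   `selection_rho`.
#' @return Integer parameter count.
#' @export
n_free_params <- function(model) {
  a <- length(model$areas)
  n <- if (identical(model$readout_mode, "fixed")) a + 1L else 2L * a + 1L
  if (!is.null(model$history) && !isFALSE(model$history)) n <- n + 4L
  if (!is.null(model$selection_rho) && !isFALSE(model$selection_rho)) n <- n + 1L
  as.integer(n)
}

#' Implied sensory noise from fitted readout weights
#'
#' With unit noise in the probit link, a unit difference in weighted
#' response yields threshold (d' = 1) performance, so each weight scales the
#' raw BOLD response into threshold units: the implied per-area noise
#' standard deviation is the reciprocal of the weight magnitude (in percent
#' signal change), with the weight's sign reported separately.
#'
#' @param model A [readout_model()] or a `readout_fit`.
#' @return A tibble with columns `task`, `area`, `beta`, `sigma_implied`,
#'   `sign`. Zero weights yield infinite implied noise.
#' @export
implied_noise <- function(model) {
  if (inherits(model, "readout_fit")) model <- model$model
  stopifnot(inherits(model, "readout_model"))
  tasks <- if (model$readout_mode == "fixed") "both" else c("contrast", "coherence")
  purrr::map_dfr(tasks, function(tk) {
    w <- model$weights[[if (tk == "both") "contrast" else tk]]
    tibble(task = tk, area = model$areas, beta = unname(w[model$areas]),
           sigma_implied = unname(ifelse(w[model$areas] == 0, Inf,
                                         1 / abs(w[model$areas]))),
           sign = sign(unname(w[model$areas])))
  })
}

#' Serialize / deserialize a readout model
#'
#' @param model A [readout_model()].
#' @param path File path (JSON). Round-trips losslessly.
#' @export
write_readout_model <- function(model, path) {
  stopifnot(inherits(model, "readout_model"))
  payload <- unclass(model)
  payload$weights <- lapply(payload$weights, as.list)
  if (!is.null(payload$history)) payload$history <- as.list(payload$history)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_readout_model
#' @export
read_readout_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- if (p$readout_mode == "fixed") {
    unlist(p$weights$contrast)
  } else {
    list(contrast = unlist(p$weights$contrast),
         coherence = unlist(p$weights$coherence))
  }
  readout_model(
    areas = p$areas, weights = weights, beta_bias = p$beta_bias,
    lapse = p$lapse, readout_mode = p$readout_mode, noise_mode = p$noise_mode,
    selection_rho = p$selection_rho, history = if (!is.null(p$history)) unlist(p$history),
    memory_cost = p$memory_cost %||% 1
  )
}
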