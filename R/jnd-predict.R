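#' Analytic just-noticeable difference predicted by a readout model
#'
#' With unit Gaussian noise in the probit link, threshold performance
#' (d' = 1) is reached when the increment raises the weighted readout
#' response by exactly one. The JND at a base stimulus is therefore the
#' root of
#' \deqn{R(base + \Delta) - R(base) = 1}
#' in the cued feature, found by bisection. Under Poisson noise the
#' required difference is instead one noise standard deviation, where the
#' variance is the mean unweighted population response of the two patches.
#'
#' @param model A [readout_model()].
#' @param prfs A [prf_set()] or per-task list.
#' @param task `"contrast"` or `"coherence"`: which feature is incremented
#'   and which task's weights are used.
#' @param base Named list or vector with elements `contrast` and
#'   `coherence`: the base stimulus of both patches.
#' @param target Required readout difference in noise-SD units. The
#'   default 1 follows the unit-difference convention (d' = 1 on the
#'   decision variable, 84\% choice accuracy under the probit link). Pass
#'   `1 / sqrt(2)` for the alternative per-patch-noise convention under
#'   which accuracy at base + JND is \eqn{\Phi(1/\sqrt 2) \approx 76\%},
#'   the criterion used for the descriptive Weibull thresholds.
#' @param tol Bisection tolerance in stimulus units.
#' @return The JND in stimulus proportion units, with attribute
#'   `measurable`. If no increment within the displayable range `(0,
#'   1 - base]` reaches the target, returns `NA` with `measurable = FALSE`.
#' @export
predict_jnd <- function(model, prfs, task = c("contrast", "coherence"),
                        base, target = 1, tol = 1e-7) {
  task <- match.arg(task)
  stopifnot(inherits(model, "readout_model"), target > 0)
  prfs_by_task <- normalize_prfs(prfs, model$areas)
  ps <- prfs_by_task[[task]]
  w <- model$weights[[task]][model$areas]
  base_con <- base[["contrast"]]; base_coh <- base[["coherence"]]

  stim <- function(delta) {
    if (task == "contrast") list(con = base_con + delta, coh = base_coh)
    else list(con = base_con, coh = base_coh + delta)
  }
  W <- function(delta) {
    s <- stim(delta)
    readout_response(ps, w, s$con, s$coh)
  }
  noise_sd <- function(delta) {
    if (model$noise_mode != "poisson") return(1)
    s <- stim(delta)
    r_inc <- mean(area_response_matrix(ps, s$con, s$coh))
    r_base <- mean(area_response_matrix(ps, base_con, base_coh))
    sqrt(pmax((r_inc + r_base) / 2, 1e-8))
  }

  base_level <- if (task == "contrast") base_con else base_coh
  upper <- 1 - base_level
  if (upper <= 0) {
    return(structure(NA_real_, measurable = FALSE))
  }

  f <- function(delta) (W(delta) - W(0)) / noise_sd(delta) - target

  # require the readout not to decrease in the cued feature at the base
  eps <- min(1e-4, upper / 10)
  if (W(eps) < W(0) - 1e-12) {
    abort(sprintf(
      "readout is not increasing in %s at the base stimulus; JND undefined", task))
  }
  if (f(upper) < 0) {
    return(structure(NA_real_, measurable = FALSE))
  }

  lo <- 0; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  structure((lo + hi) / 2, measurable = TRUE)
}

#' Predicted JND on post-cued catch trials
#'
#' Two accounts of catch-trial behavior: the *wrong-readout* prediction
#' evaluates the JND for the probed feature using the weights of the run's
#' main task (the readout the observer would be stuck with if it could not
#' switch); the *memory-cost* prediction uses the correct (flexible)
#' readout but inflates the required response difference by a
#' working-memory cost factor, equivalent to scaling the noise SD.
#'
#' @inheritParams predict_jnd
#' @param task The feature probed on the catch trial (the run's un-cued
#'   feature).
#' @param mode `"wrong_readout"` or `"memory_cost"`.
#' @param memory_cost Cost factor (required d' in readout units) for
#'   `mode = "memory_cost"`.
#' @return JND in stimulus units with attribute `measurable`; `NA` when the
#'   readout in force is insensitive to the probed feature within the
#'   displayable range.
#' @export
predict_catch_jnd <- function(model, prfs, task = c("contrast", "coherence"),
                              base, mode = c("wrong_readout", "memory_cost"),
                              memory_cost = 1, tol = 1e-7) {
  task <- match.arg(task)
  mode <- match.arg(mode)
  if (mode == "wrong_readout") {
    other <- if (task == "contrast") "coherence" else "contrast"
    # probe `task`, but with the weights (and response functions) of the
    # other task's readout
    swapped <- model
    swapped$weights[[task]] <- model$weights[[other]]
    prfs_by_task <- normalize_prfs(prfs, model$areas)
    swapped_prfs <- prfs_by_task
    swapped_prfs[[task]] <- prfs_by_task[[other]]
    out <- tryCatch(
      predict_jnd(swapped, swapped_prfs, task, base, target = 1, tol = tol),
      error = function(e) structure(NA_real_, measurable = FALSE)
    )
    out
  } else {
    predict_jnd(model, prfs, task, base, target = memory_cost, tol = tol)
  }
}
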