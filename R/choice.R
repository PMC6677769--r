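#' Probability of choosing the right-hand patch
#'
#' Computes the trial-by-trial probability that the observer reports the
#' right-hand dot patch as having the higher cued feature. Per-area
#' responses to the left and right patch stimuli are weighted by the
#' task-appropriate readout weights; the difference plus a side bias is
#' passed through a cumulative normal; a lapse rate mixes in guessing:
#' \deqn{P_{right} = \lambda/2 + (1 - \lambda)\Phi(\Sigma_{right} -
#'   \Sigma_{left} + \beta_{bias})}
#'
#' Model variants: with `noise_mode = "poisson"` the Gaussian scale is the
#' square root of the mean unweighted population response of the two
#' patches; with a selection exponent \eqn{\rho} area responses are
#' sign-preservingly raised to \eqn{\rho} before weighting and the
#' \eqn{\rho}-th root of the aggregate is taken; history coefficients add
#' stay/switch terms driven by the previous trial's choice and accuracy.
#' On post-cued catch trials the weights of the post-cued feature's task
#' are used and the decision variable is divided by the model's
#' working-memory cost factor.
#'
#' @param model A [readout_model()].
#' @param prfs A [prf_set()] shared by both tasks, or a list with elements
#'   `contrast` and `coherence` holding per-task sets.
#' @param trials A trials tibble with stimulus columns `stim_con_left`,
#'   `stim_con_right`, `stim_coh_left`, `stim_coh_right` and a `task`
#'   column; optionally `is_catch`, `post_cue`, `prev_choice`,
#'   `prev_correct`.
#' @return Numeric vector of probabilities in \eqn{[\lambda/2, 1-\lambda/2]}.
#' @export
choice_probability <- function(model, prfs, trials) {
  stopifnot(inherits(model, "readout_model"))
  check_prob(model$lapse, "lapse")
  need <- c("task", "stim_con_left", "stim_con_right",
            "stim_coh_left", "stim_coh_right")
  missing <- setdiff(need, names(trials))
  if (length(missing) > 0) {
    abort(paste0("trials is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyNA(trials[need[-1]])) abort("trials contain unset stimulus strengths")

  prfs_by_task <- normalize_prfs(prfs, model$areas)
  n <- nrow(trials)

  # effective task: post-cued catch trials are read out with the other
  # task's weights (and response functions)
  eff_task <- trials$task
  catch <- rep(FALSE, n)
  if (all(c("is_catch", "post_cue") %in% names(trials))) {
    catch <- trials$is_catch & trials$post_cue != "none"
    eff_task[catch] <- trials$post_cue[catch]
  }

  eta <- numeric(n)
  sigma <- rep(1, n)
  for (tk in c("contrast", "coherence")) {
    idx <- eff_task == tk
    if (!any(idx)) next
    ps <- prfs_by_task[[tk]]
    Rl <- area_response_matrix(ps, trials$stim_con_left[idx],
                               trials$stim_coh_left[idx])
    Rr <- area_response_matrix(ps, trials$stim_con_right[idx],
                               trials$stim_coh_right[idx])
    if (sum(idx) == 1) { Rl <- matrix(Rl, nrow = 1); Rr <- matrix(Rr, nrow = 1) }
    w <- model$weights[[tk]][model$areas]
    rho <- model$selection_rho
    if (!is.null(rho)) {
      spow <- function(x, p) sign(x) * abs(x)^p
      u <- (spow(Rr, rho) - spow(Rl, rho)) %*% w + model$beta_bias
      eta[idx] <- spow(u, 1 / rho)
    } else {
      eta[idx] <- (Rr - Rl) %*% w + model$beta_bias
    }
    if (model$noise_mode == "poisson") {
      v <- (rowMeans(Rr) + rowMeans(Rl)) / 2
      sigma[idx] <- sqrt(pmax(v, 1e-8))
    }
  }

  if (!is.null(model$history)) {
    hb <- model$history
    pc <- trials$prev_choice %||% rep("none", n)
    pk <- trials$prev_correct %||% rep(NA, n)
    pk[is.na(pk)] <- FALSE
    eta <- eta +
      hb[["beta_left_correct"]]    * as.numeric(pc == "left" & pk) +
      hb[["beta_right_correct"]]   * as.numeric(pc == "right" & pk) +
      hb[["beta_left_incorrect"]]  * as.numeric(pc == "left" & !pk) +
      hb[["beta_right_incorrect"]] * as.numeric(pc == "right" & !pk)
  }

  if (any(catch) && model$memory_cost != 1) {
    sigma[catch] <- sigma[catch] * model$memory_cost
  }

  model$lapse / 2 + (1 - model$lapse) * pnorm(eta / sigma)
}

# accept a single prf_set for both tasks or per-task sets; check coverage
normalize_prfs <- function(prfs, areas) {
  if (inherits(prfs, "prf_set")) {
    prfs <- list(contrast = prfs, coherence = prfs)
  }
  stopifnot(all(c("contrast", "coherence") %in% names(prfs)))
  for (tk in c("contrast", "coherence")) {
    missing <- setdiff(areas, names(prfs[[tk]]))
    if (length(missing) > 0) {
      abort(paste0("prf set for ", tk, " task lacks area(s): ",
                   paste(missing, collapse = ", ")))
    }
    prfs[[tk]] <- prf_set(prfs[[tk]][areas])
  }
  prfs
}

#' Bernoulli log-likelihood of observed choices under a readout model
#'
#' @inheritParams choice_probability
#' @param trials Trials tibble including a `choice` column (`"left"` /
#'   `"right"`).
#' @return Total log-likelihood in nats.
#' @export
choice_loglik <- function(model, prfs, trials) {
  keep <- trials$choice %in% c("left", "right")
  trials <- trials[keep, , drop = FALSE]
  p <- choice_probability(model, prfs, trials)
  y <- as.numeric(trials$choice == "right")
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(y * log(p) + (1 - y) * log(1 - p))
}
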