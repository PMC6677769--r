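#' Fit a readout linking model by maximum likelihood
#'
#' Maximizes the Bernoulli log-likelihood of observed choices over the
#' readout weights, side bias, and any optional history or selection
#' parameters, with the lapse rate held fixed (it is estimated separately
#' from suprathreshold trials, see [estimate_lapse()]). Uses bounded
#' quasi-Newton optimization (`L-BFGS-B`) with seeded random restarts to
#' avoid local minima; per-trial area responses are precomputed once so
#' each objective evaluation is a pair of matrix-vector products.
#'
#' @param trials Trials tibble with stimulus, `task`, and `choice` columns.
#'   Trials without a left/right choice are dropped.
#' @param prfs A [prf_set()] or per-task list (see [choice_probability()]).
#' @param readout_mode `"flexible"` (independent weights per task) or
#'   `"fixed"` (one shared weight per area).
#' @param noise_mode `"additive"` or `"poisson"`.
#' @param areas Areas to read out (default: all areas of `prfs`).
#' @param history If `TRUE`, add four stay/switch bias parameters driven by
#'   the previous trial's side and accuracy.
#' @param selection If `TRUE`, add an efficient-selection exponent
#'   \eqn{\rho \ge 1}.
#' @param lapse Fixed lapse probability.
#' @param memory_cost Fixed working-memory cost factor for post-cued catch
#'   trials (default 1).
#' @param n_restarts Number of random restarts (the first start is at zero).
#' @param seed Seed for the restart draws.
#' @param weight_bound,bias_bound Box constraints on weights and bias.
#' @return A `readout_fit` object: the fitted [readout_model()], the
#'   training log-likelihood (nats), restart count, convergence flag, and
#'   the implied per-area noise table.
#' @export
fit_readout <- function(trials, prfs,
                        readout_mode = c("flexible", "fixed"),
                        noise_mode = c("additive", "poisson"),
                        areas = NULL, history = FALSE, selection = FALSE,
                        lapse = 0, memory_cost = 1,
                        n_restarts = 10, seed = NULL,
                        weight_bound = 50, bias_bound = 10) {
  readout_mode <- match.arg(readout_mode)
  noise_mode <- match.arg(noise_mode)
  trials <- trials[trials$choice %in% c("left", "right"), , drop = FALSE]
  if (nrow(trials) == 0) abort("no trials with a left/right choice")
  if (readout_mode == "flexible" &&
      !all(c("contrast", "coherence") %in% unique(trials$task))) {
    warn("flexible readout fitted with only one task present in the data")
  }
  if (length(unique(trials$choice)) == 1) {
    warn("all trials share the same choice; weights will sit at a bound")
  }

  prfs_by_task <- normalize_prfs(
    prfs, areas %||% names(if (inherits(prfs, "prf_set")) prfs else prfs[[1]]))
  areas <- areas %||% names(prfs_by_task$contrast)
  A <- length(areas)
  n <- nrow(trials)
  y <- as.numeric(trials$choice == "right")

  eff_task <- trials$task
  catch <- rep(FALSE, n)
  if (all(c("is_catch", "post_cue") %in% names(trials))) {
    catch <- trials$is_catch & trials$post_cue != "none"
    eff_task[catch] <- trials$post_cue[catch]
  }

  cache <- lapply(c(contrast = "contrast", coherence = "coherence"), function(tk) {
    idx <- which(eff_task == tk)
    if (length(idx) == 0) return(NULL)
    ps <- prf_set(prfs_by_task[[tk]][areas])
    Rl <- area_response_matrix(ps, trials$stim_con_left[idx], trials$stim_coh_left[idx])
    Rr <- area_response_matrix(ps, trials$stim_con_right[idx], trials$stim_coh_right[idx])
    if (length(idx) == 1) { Rl <- matrix(Rl, 1); Rr <- matrix(Rr, 1) }
    sig <- if (noise_mode == "poisson") {
      sqrt(pmax((rowMeans(Rr) + rowMeans(Rl)) / 2, 1e-8))
    } else rep(1, length(idx))
    list(idx = idx, Rl = Rl, Rr = Rr, D = Rr - Rl, sigma = sig)
  })

  H <- NULL
  if (history) {
    pc <- trials$prev_choice %||% rep("none", n)
    pk <- trials$prev_correct %||% rep(NA, n)
    pk[is.na(pk)] <- FALSE
    H <- cbind(as.numeric(pc == "left" & pk), as.numeric(pc == "right" & pk),
               as.numeric(pc == "left" & !pk), as.numeric(pc == "right" & !pk))
  }
  sigma_all <- rep(1, n)
  for (tk in c("contrast", "coherence")) {
    if (!is.null(cache[[tk]])) sigma_all[cache[[tk]]$idx] <- cache[[tk]]$sigma
  }
  sigma_all <- sigma_all * ifelse(catch, memory_cost, 1)

  n_w <- if (readout_mode == "fixed") A else 2L * A
  n_par <- n_w + 1L + (if (history) 4L else 0L) + (if (selection) 1L else 0L)
  lower <- c(rep(-weight_bound, n_w), -bias_bound,
             if (history) rep(-bias_bound, 4), if (selection) 1)
  upper <- c(rep(weight_bound, n_w), bias_bound,
             if (history) rep(bias_bound, 4), if (selection) 5)

  unpack <- function(par) {
    w_con <- par[seq_len(A)]
    w_coh <- if (readout_mode == "fixed") w_con else par[A + seq_len(A)]
    bias <- par[n_w + 1]
    hb <- if (history) par[n_w + 1 + 1:4] else NULL
    rho <- if (selection) par[n_par] else NULL
    list(w = list(contrast = w_con, coherence = w_coh), bias = bias,
         hb = hb, rho = rho)
  }

  negll <- function(par) {
    p <- unpack(par)
    eta <- numeric(n)
    for (tk in c("contrast", "coherence")) {
      cc <- cache[[tk]]
      if (is.null(cc)) next
      if (!is.null(p$rho)) {
        spow <- function(x, q) sign(x) * abs(x)^q
        u <- (spow(cc$Rr, p$rho) - spow(cc$Rl, p$rho)) %*% p$w[[tk]] + p$bias
        eta[cc$idx] <- spow(u, 1 / p$rho)
      } else {
        eta[cc$idx] <- cc$D %*% p$w[[tk]] + p$bias
      }
    }
    if (history) eta <- eta + H %*% p$hb
    eta <- eta / sigma_all
    pr <- lapse / 2 + (1 - lapse) * pnorm(eta)
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    -sum(y * log(pr) + (1 - y) * log(1 - pr))
  }

  starts <- with_seed_if(seed, {
    s0 <- rep(0, n_par)
    if (selection) s0[n_par] <- 1
    c(list(s0), purrr::map(seq_len(max(n_restarts - 1, 0)), function(i) {
      s <- c(runif(n_w, -2, 2), runif(1, -1, 1),
             if (history) runif(4, -0.5, 0.5), if (selection) runif(1, 1, 3))
      s
    }))
  })

  fits <- purrr::map(starts, function(s) {
    tryCatch(
      optim(s, negll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500, factr = 1e4)),
      error = function(e) list(value = Inf, convergence = 99L, par = s)
    )
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  p <- unpack(best$par)

  model <- readout_model(
    areas = areas,
    weights = if (readout_mode == "fixed") {
      stats::setNames(p$w$contrast, areas)
    } else {
      list(contrast = stats::setNames(p$w$contrast, areas),
           coherence = stats::setNames(p$w$coherence, areas))
    },
    beta_bias = p$bias, lapse = lapse, readout_mode = readout_mode,
    noise_mode = noise_mode,
    selection_rho = p$rho,
    history = if (history) stats::setNames(p$hb, c(
      "beta_left_correct", "beta_right_correct",
      "beta_left_incorrect", "beta_right_incorrect")),
    memory_cost = memory_cost
  )

  structure(
    list(model = model, prfs = prfs_by_task, loglik = -best$value,
         n_restarts = length(starts),
         converged = any(vapply(fits, `[[`, numeric(1), "convergence") == 0),
         implied_noise = implied_noise(model), n_trials = n),
    class = "readout_fit"
  )
}

#' @export
print.readout_fit <- function(x, ...) {
  cat(sprintf("<readout_fit> loglik = %.2f nats on %d trials (%d params, %s)\n",
              x$loglik, x$n_trials, n_free_params(x$model),
              if (x$converged) "converged" else "not converged"))
  print(x$model)
  invisible(x)
}

#' Predicted choice probabilities from a fitted readout model
#'
#' @param object A `readout_fit`.
#' @param newdata Trials tibble.
#' @param ... Unused.
#' @return Vector of P(choose right).
#' @export
predict.readout_fit <- function(object, newdata, ...) {
  choice_probability(object$model, object$prfs, newdata)
}
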