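#' Fit a cumulative-normal psychometric function to choice data
#'
#' Maximum-likelihood fit of P(choose right) as a function of the signed
#' stimulus difference `x = stim_right - stim_left` in the judged feature:
#' \deqn{P(x) = \lambda/2 + (1 - \lambda)\Phi((x - \mu)/\sigma)}
#' The fit uses the trial-level Bernoulli likelihood (binning is for
#' display only). The goodness of fit is the pseudo-r2 against an
#' intercept-only model,
#' \eqn{r^2_{pseudo} = 1 - \log(L_{model})/\log(L_{null})},
#' optionally evaluated on held-out trials.
#'
#' @param trials Trials tibble with `choice` and stimulus columns.
#' @param feature `"contrast"` or `"coherence"`; defaults to the modal
#'   `task` of the trials.
#' @param eval_trials Optional held-out trials on which to evaluate
#'   `r2_pseudo` (the null model is fit on the training trials).
#' @param n_restarts Seeded multi-start count.
#' @param seed Seed for the restarts.
#' @return A `cumnormal_fit`: `mu`, `sigma`, `lambda`, `loglik` (nats),
#'   `r2_pseudo`, `n`, `separation` flag (complete separation drives
#'   `sigma` to its lower bound).
#' @export
fit_cum_normal <- function(trials, feature = NULL, eval_trials = NULL,
                           n_restarts = 5, seed = 1) {
  trials <- trials[trials$choice %in% c("left", "right"), , drop = FALSE]
  feature <- feature %||% names(which.max(table(trials$task)))
  x <- signed_difference(trials, feature)
  y <- as.numeric(trials$choice == "right")
  if (length(unique(x[y == 1])) < 1 || length(unique(x)) < 2) {
    abort("need at least 2 distinct stimulus differences with both outcomes")
  }

  nll <- function(par) {
    p <- par[3] / 2 + (1 - par[3]) * pnorm((x - par[1]) / par[2])
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  lower <- c(-1, 1e-5, 0); upper <- c(1, 1, 0.5)
  starts <- with_seed_if(seed, c(
    list(c(0, max(sd(x), 0.01), 0.02)),
    purrr::map(seq_len(max(n_restarts - 1, 0)),
               function(i) c(runif(1, -0.1, 0.1), runif(1, 0.005, 0.5),
                             runif(1, 0, 0.2)))
  ))
  fits <- purrr::map(starts, function(s) {
    tryCatch(optim(s, nll, method = "L-BFGS-B", lower = lower, upper = upper),
             error = function(e) list(value = Inf, par = s))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  mu <- best$par[1]; sigma <- best$par[2]; lambda <- best$par[3]

  # evaluation set (default: training data)
  ev <- eval_trials
  if (!is.null(ev)) {
    ev <- ev[ev$choice %in% c("left", "right"), , drop = FALSE]
    xe <- signed_difference(ev, feature)
    ye <- as.numeric(ev$choice == "right")
  } else {
    xe <- x; ye <- y
  }
  ll_model <- bernoulli_ll(lambda / 2 + (1 - lambda) * pnorm((xe - mu) / sigma), ye)
  p_null <- mean(y)
  ll_null <- bernoulli_ll(rep(p_null, length(ye)), ye)
  r2 <- 1 - ll_model / ll_null

  structure(
    list(mu = mu, sigma = sigma, lambda = lambda, loglik = -best$value,
         r2_pseudo = r2, n = length(y), feature = feature,
         separation = sigma <= 1e-5 + 1e-12,
         data = tibble(x = x, y = y)),
    class = "cumnormal_fit"
  )
}

signed_difference <- function(trials, feature) {
  if (feature == "contrast") {
    trials$stim_con_right - trials$stim_con_left
  } else {
    trials$stim_coh_right - trials$stim_coh_left
  }
}

bernoulli_ll <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

#' @export
print.cumnormal_fit <- function(x, ...) {
  cat(sprintf(
    "<cumnormal_fit %s> mu=%.4f sigma=%.4f lambda=%.3f loglik=%.2f r2_pseudo=%.3f (n=%d)\n",
    x$feature, x$mu, x$sigma, x$lambda, x$loglik, x$r2_pseudo, x$n))
  invisible(x)
}

#' Fit a Weibull percent-correct function and read off the JND
#'
#' Maximum-likelihood fit of
#' \deqn{P_{correct}(x) = \gamma + (1 - \gamma - \lambda)(1 -
#'   e^{-(x/\tau)^\beta})}
#' to correct/incorrect outcomes at positive target increments `x`, with
#' the guess rate fixed at 0.5 (2AFC) and the lapse rate fixed at its
#' empirical estimate. The just-noticeable difference is the increment at
#' which d' = 1, i.e. the ~76%-correct point
#' (\eqn{\Phi(1/\sqrt 2) \approx 0.760}), obtained by inverting the fitted
#' curve.
#'
#' @param x Positive increments (cued-feature deltas), or a trials tibble
#'   (then `correct` is taken from its `correct` column and `x` from the
#'   cued feature's delta).
#' @param correct Logical outcomes (ignored when `x` is a tibble).
#' @param lambda Fixed lapse rate.
#' @param base_strength Base strength used for the measurability rule
#'   (`tau + base > 1` at the fit bound means the threshold exceeded the
#'   displayable range).
#' @param n_restarts,seed Multi-start control.
#' @return A `weibull_fit`: `tau`, `beta_slope`, `gamma`, `lambda`,
#'   `loglik`, `jnd`, `measurable`, `n`, `flag_no_errors`.
#' @export
fit_weibull <- function(x, correct = NULL, lambda = 0, base_strength = 0,
                        n_restarts = 5, seed = 1) {
  if (is.data.frame(x)) {
    d <- x
    xx <- ifelse(d$task == "contrast", d$delta_con, d$delta_coh)
    correct <- d$correct
    x <- xx
  }
  keep <- !is.na(correct) & x > 0
  x <- x[keep]; y <- as.numeric(correct[keep])
  if (length(x) == 0) abort("no trials with positive increments")
  gamma <- 0.5

  nll <- function(par) {
    p <- weibull_pc(x, par[1], par[2], gamma, lambda)
    -bernoulli_ll(p, y)
  }
  lower <- c(1e-4, 0.1); upper <- c(1, 10)
  starts <- with_seed_if(seed, c(
    list(c(stats::median(x), 3)),
    purrr::map(seq_len(max(n_restarts - 1, 0)),
               function(i) c(exp(runif(1, log(1e-3), log(0.5))), runif(1, 0.5, 6)))
  ))
  fits <- purrr::map(starts, function(s) {
    tryCatch(optim(pmin(pmax(s, lower), upper), nll, method = "L-BFGS-B",
                   lower = lower, upper = upper),
             error = function(e) list(value = Inf, par = s))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  tau <- best$par[1]; beta <- best$par[2]
  no_errors <- all(y == 1)

  jnd <- weibull_jnd(tau, beta, gamma, lambda)
  measurable <- is.finite(jnd) && (tau + base_strength) <= 1 &&
    tau < upper[1] - 1e-9

  structure(
    list(tau = tau, beta_slope = beta, gamma = gamma, lambda = lambda,
         loglik = -best$value, jnd = jnd, measurable = measurable,
         n = length(x), flag_no_errors = no_errors,
         base_strength = base_strength),
    class = "weibull_fit"
  )
}

#' Weibull percent-correct curve and JND inversion
#'
#' `weibull_pc()` evaluates the 2AFC Weibull percent-correct function;
#' `weibull_jnd()` inverts it at a target probability (default the d' = 1
#' point, ~76% correct).
#'
#' @param x Increment(s).
#' @param tau,beta,gamma,lambda Weibull parameters.
#' @param p_target Percent-correct criterion defining the JND.
#' @return Probability correct, or the increment reaching `p_target`
#'   (`Inf` if the curve cannot reach it).
#' @export
weibull_pc <- function(x, tau, beta, gamma = 0.5, lambda = 0) {
  gamma + (1 - gamma - lambda) * (1 - exp(-(x / tau)^beta))
}

#' @rdname weibull_pc
#' @export
weibull_jnd <- function(tau, beta, gamma = 0.5, lambda = 0,
                        p_target = pnorm(1 / sqrt(2))) {
  frac <- (p_target - gamma) / (1 - gamma - lambda)
  if (frac >= 1) return(Inf)
  if (frac <= 0) return(0)
  tau * (-log(1 - frac))^(1 / beta)
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf(
    "<weibull_fit> tau=%.4f beta=%.2f lambda=%.3f jnd=%.4f (%s, n=%d)\n",
    x$tau, x$beta_slope, x$lambda, x$jnd,
    if (x$measurable) "measurable" else "not measurable", x$n))
  invisible(x)
}

#' Fit the full per-observer set of Weibull thresholds
#'
#' Replicates the session threshold structure: one fit per base strength
#' and task on regular runs (4 bases x 2 tasks), one per task for the
#' cued trials of catch runs (single base), and one per reported feature
#' for the post-cued catch trials themselves - 12 fits in total.
#'
#' @param trials A completed trials tibble (with `is_catch_run`).
#' @param lambda Fixed lapse rate passed to every fit.
#' @return Tibble with `condition` (`regular`, `catch_control`, `catch`),
#'   `task`, `base_strength`, `jnd`, `tau`, `beta_slope`, `measurable`,
#'   `n_trials`.
#' @export
weibull_fit_table <- function(trials, lambda = 0) {
  stopifnot("is_catch_run" %in% names(trials))
  done <- trials[trials$choice %in% c("left", "right"), , drop = FALSE]
  base_of <- function(d) ifelse(d$task == "contrast", d$base_con, d$base_coh)

  regular <- done |>
    dplyr::filter(!.data$is_catch_run) |>
    dplyr::mutate(base_strength = base_of(dplyr::pick(dplyr::everything()))) |>
    dplyr::group_by(.data$task, .data$base_strength) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_weibull(dplyr::mutate(d, task = key$task), lambda = lambda,
                       base_strength = key$base_strength)
      weibull_row(f)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(condition = "regular")

  control <- done |>
    dplyr::filter(.data$is_catch_run, !.data$is_catch) |>
    dplyr::mutate(base_strength = base_of(dplyr::pick(dplyr::everything()))) |>
    dplyr::group_by(.data$task, .data$base_strength) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_weibull(dplyr::mutate(d, task = key$task), lambda = lambda,
                       base_strength = key$base_strength)
      weibull_row(f)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(condition = "catch_control")

  catch <- done |>
    dplyr::filter(.data$is_catch_run, .data$is_catch) |>
    dplyr::mutate(
      task = .data$post_cue,  # reported feature
      base_strength = ifelse(.data$post_cue == "contrast",
                             .data$base_con, .data$base_coh)
    ) |>
    dplyr::group_by(.data$task, .data$base_strength) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_weibull(dplyr::mutate(d, task = key$task), lambda = lambda,
                       base_strength = key$base_strength)
      weibull_row(f)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(condition = "catch")

  dplyr::bind_rows(regular, control, catch) |>
    dplyr::select("condition", "task", "base_strength", "jnd", "tau",
                  "beta_slope", "measurable", "n_trials")
}

weibull_row <- function(f) {
  tibble(jnd = f$jnd, tau = f$tau, beta_slope = f$beta_slope,
         measurable = f$measurable, n_trials = f$n)
}

#' Empirical lapse rate from suprathreshold trials
#'
#' Under the lapse model, asymptotic accuracy is `1 - lambda/2`, so the
#' lapse rate is estimated as twice the error rate on trials whose cued
#' increment is far above threshold (at least +15% contrast or +40%
#' coherence, i.e. at least twice threshold), clipped to `[0, 1]`. The raw
#' error rate is reported alongside.
#'
#' @param trials Completed trials tibble.
#' @param suprathreshold_con,suprathreshold_coh Increment cutoffs.
#' @return List with `lambda`, `error_rate`, `n_trials`.
#' @export
estimate_lapse <- function(trials, suprathreshold_con = 0.15,
                           suprathreshold_coh = 0.40) {
  done <- trials[trials$choice %in% c("left", "right") & !trials$is_catch, ,
                 drop = FALSE]
  supra <- (done$task == "contrast" & done$delta_con >= suprathreshold_con) |
    (done$task == "coherence" & done$delta_coh >= suprathreshold_coh)
  if (!any(supra)) abort("no suprathreshold trials; lapse rate is undefined")
  err <- mean(!done$correct[supra])
  list(lambda = min(max(2 * err, 0), 1), error_rate = err,
       n_trials = sum(supra))
}

#' Weber-law slope of JNDs against base strength
#'
#' Least-squares slope of `log(jnd)` on `log(base)`; Weber's law predicts
#' a slope of 1. Non-measurable JNDs are excluded with a warning.
#'
#' @param jnds Tibble with `base_strength`, `jnd`, and optionally
#'   `measurable` columns.
#' @return Slope (unitless, log-log), with the intercept as an attribute.
#' @export
weber_slope <- function(jnds) {
  if ("measurable" %in% names(jnds) && any(!jnds$measurable)) {
    warn(sprintf("excluding %d non-measurable JND(s)", sum(!jnds$measurable)))
    jnds <- jnds[jnds$measurable, , drop = FALSE]
  }
  if (length(unique(jnds$base_strength)) < 2) {
    abort("need measurable JNDs at >= 2 distinct base strengths")
  }
  fit <- lm(log(jnd) ~ log(base_strength), data = jnds)
  structure(unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))
}

#' Working-memory cost factor from catch-trial thresholds
#'
#' The catch-trial cost is the ratio of the threshold measured on
#' post-cued catch trials to the threshold on regular trials of the same
#' runs; it is invariant to percent-vs-proportion units.
#'
#' @param jnd_catch,jnd_control JND values (stimulus units), e.g. from
#'   [weibull_fit_table()].
#' @return The unitless cost factor.
#' @export
catch_cost <- function(jnd_catch, jnd_control) {
  if (!is.finite(jnd_catch) || !is.finite(jnd_control) || jnd_control <= 0) {
    abort("catch cost is undefined for non-measurable thresholds")
  }
  jnd_catch / jnd_control
}
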