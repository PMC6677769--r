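#' Tidy methods for fitted objects
#'
#' Broom-style `tidy()` returns one row per parameter (or per weight);
#' `glance()` returns a one-row model summary.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name flexreadout-tidiers
NULL

#' @rdname flexreadout-tidiers
#' @method tidy cumnormal_fit
#' @export
tidy.cumnormal_fit <- function(x, ...) {
  tibble(term = c("mu", "sigma", "lambda"),
         estimate = c(x$mu, x$sigma, x$lambda))
}

#' @rdname flexreadout-tidiers
#' @method glance cumnormal_fit
#' @export
glance.cumnormal_fit <- function(x, ...) {
  tibble(logLik = x$loglik, r2_pseudo = x$r2_pseudo, nobs = x$n,
         feature = x$feature, separation = x$separation)
}

#' @rdname flexreadout-tidiers
#' @method tidy weibull_fit
#' @export
tidy.weibull_fit <- function(x, ...) {
  tibble(term = c("tau", "beta_slope", "gamma", "lambda"),
         estimate = c(x$tau, x$beta_slope, x$gamma, x$lambda))
}

#' @rdname flexreadout-tidiers
#' @method glance weibull_fit
#' @export
glance.weibull_fit <- function(x, ...) {
  tibble(logLik = x$loglik, jnd = x$jnd, measurable = x$measurable,
         nobs = x$n)
}

#' @rdname flexreadout-tidiers
#' @method tidy readout_fit
#' @export
tidy.readout_fit <- function(x, ...) {
  m <- x$model
  tasks <- if (m$readout_mode == "fixed") "both" else c("contrast", "coherence")
  w <- purrr::map_dfr(tasks, function(tk) {
    ww <- m$weights[[if (tk == "both") "contrast" else tk]]
    tibble(term = paste0("beta_", m$areas), task = tk,
           estimate = unname(ww[m$areas]))
  })
  dplyr::bind_rows(w, tibble(term = "beta_bias", task = "both",
                             estimate = m$beta_bias))
}

#' @rdname flexreadout-tidiers
#' @method glance readout_fit
#' @export
glance.readout_fit <- function(x, ...) {
  tibble(logLik = x$loglik, nobs = x$n_trials,
         n_params = n_free_params(x$model),
         readout_mode = x$model$readout_mode,
         noise_mode = x$model$noise_mode,
         converged = x$converged, n_restarts = x$n_restarts)
}

#' @rdname flexreadout-tidiers
#' @method tidy model_comparison_result
#' @export
tidy.model_comparison_result <- function(x, ...) {
  tibble(fold = seq_len(x$n_folds), loglik = x$fold_logliks)
}

#' @rdname flexreadout-tidiers
#' @method glance model_comparison_result
#' @export
glance.model_comparison_result <- function(x, ...) {
  tibble(model = x$model_label, total_cv_loglik = x$total_cv_loglik,
         cd = x$cd, n_folds = x$n_folds, nobs = x$n_trials)
}

#' @rdname flexreadout-tidiers
#' @method tidy prf_task_fit
#' @export
tidy.prf_task_fit <- function(x, ...) {
  x$params |>
    tidyr::pivot_longer(c("alpha_con", "alpha_coh", "alpha_task"),
                        names_to = "term", values_to = "estimate") |>
    dplyr::select("area", "task", "term", "estimate")
}
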