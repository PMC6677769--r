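#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of fitted objects:
#' psychometric curves with equal-count binned choice proportions,
#' Weibull percent-correct curves with the JND marked, staircase level
#' traces, per-condition FIR responses, and readout weight maps
#' (contrast-task vs coherence-task weights per area).
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @param n_bins Number of equal-count display bins for choice data.
#' @return A ggplot object.
#' @name flexreadout-autoplot
NULL

#' @rdname flexreadout-autoplot
#' @method autoplot cumnormal_fit
#' @export
autoplot.cumnormal_fit <- function(object, n_bins = 9, ...) {
  d <- object$data
  qs <- stats::quantile(d$x, probs = seq(0, 1, length.out = n_bins + 1))
  binned <- d |>
    dplyr::mutate(bin = cut(.data$x, unique(qs), include.lowest = TRUE)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(x = mean(.data$x), p = mean(.data$y), n = dplyr::n(),
                     .groups = "drop")
  grid <- tibble(x = seq(min(d$x), max(d$x), length.out = 200))
  grid$p <- object$lambda / 2 +
    (1 - object$lambda) * pnorm((grid$x - object$mu) / object$sigma)
  ggplot2::ggplot(binned, ggplot2::aes(x = .data$x, y = .data$p)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::geom_line(data = grid) +
    ggplot2::labs(x = sprintf("%s difference (right - left)", object$feature),
                  y = "P(choose right)", size = "trials") +
    ggplot2::theme_minimal()
}

#' @rdname flexreadout-autoplot
#' @method autoplot weibull_fit
#' @export
autoplot.weibull_fit <- function(object, ...) {
  grid <- tibble(x = seq(1e-4, max(object$tau * 3, object$jnd * 1.5),
                         length.out = 200))
  grid$p <- weibull_pc(grid$x, object$tau, object$beta_slope,
                       object$gamma, object$lambda)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$x, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$jnd, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = pnorm(1 / sqrt(2)), linetype = "dotted") +
    ggplot2::labs(x = "target increment", y = "P(correct)") +
    ggplot2::theme_minimal()
}

#' @rdname flexreadout-autoplot
#' @method autoplot pest_trace
#' @export
autoplot.pest_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$trial, y = .data$level)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(ggplot2::aes(color = .data$correct), size = 0.8) +
    ggplot2::labs(x = "trial", y = "staircase level", color = "correct") +
    ggplot2::theme_minimal()
}

#' @rdname flexreadout-autoplot
#' @method autoplot deconvolution_result
#' @export
autoplot.deconvolution_result <- function(object, ...) {
  ggplot2::ggplot(object$fir_responses,
                  ggplot2::aes(x = .data$lag, y = .data$response,
                               group = .data$condition_id)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "lag (volumes)", y = "response (psc)") +
    ggplot2::theme_minimal()
}

#' @rdname flexreadout-autoplot
#' @method autoplot readout_fit
#' @export
autoplot.readout_fit <- function(object, ...) {
  m <- object$model
  d <- tibble(area = m$areas,
              contrast_weight = unname(m$weights$contrast[m$areas]),
              coherence_weight = unname(m$weights$coherence[m$areas]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$contrast_weight,
                                  y = .data$coherence_weight,
                                  label = .data$area)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey70") +
    ggplot2::geom_vline(xintercept = 0, color = "grey70") +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8) +
    ggplot2::labs(x = "contrast task weight", y = "coherence task weight") +
    ggplot2::theme_minimal()
}
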