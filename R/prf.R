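#' Population response function for one cortical area
#'
#' Parameterizes the mean BOLD response (percent signal change) of a visual
#' area to a random-dot patch as the sum of a Naka-Rushton contrast term, a
#' saturating-exponential coherence term, and an additive task offset:
#'
#' \deqn{R(s_{con}, s_{coh}) = \alpha_{con} \frac{s_{con}^{1.9}}{s_{con}^{1.6} +
#'   \sigma^{1.6}} + \alpha_{coh} (1 - e^{-s_{coh}/\kappa}) + \alpha_{task}}
#'
#' The coherence exponent is negative so that the term saturates at
#' \eqn{\alpha_{coh}} and reaches 63.2\% of it at \eqn{s_{coh} = \kappa}.
#'
#' @param area Area label (e.g. "V1", "MT").
#' @param alpha_con Contrast amplitude (psc).
#' @param sigma_con Contrast semi-saturation constant (> 0, contrast units).
#' @param alpha_coh Coherence asymptotic amplitude (psc).
#' @param kappa Coherence scale constant (> 0, coherence units).
#' @param alpha_task Additive offset (psc), absorbing task engagement.
#' @return An object of class `prf`.
#' @export
prf <- function(area, alpha_con, sigma_con, alpha_coh, kappa, alpha_task = 0) {
  stopifnot(sigma_con > 0, kappa > 0)
  structure(
    list(area = area, alpha_con = alpha_con, sigma_con = sigma_con,
         alpha_coh = alpha_coh, kappa = kappa, alpha_task = alpha_task,
         exp_num = 1.9, exp_den = 1.6),
    class = "prf"
  )
}

#' @export
print.prf <- function(x, ...) {
  cat(sprintf(
    "<prf %s> alpha_con=%.3g sigma_con=%.3g alpha_coh=%.3g kappa=%.3g alpha_task=%.3g\n",
    x$area, x$alpha_con, x$sigma_con, x$alpha_coh, x$kappa, x$alpha_task))
  invisible(x)
}

# unit-amplitude contrast shape
nr_shape <- function(s, sigma_con, exp_num = 1.9, exp_den = 1.6) {
  s^exp_num / (s^exp_den + sigma_con^exp_den)
}

# unit-amplitude coherence shape (saturating exponential)
satexp_shape <- function(s, kappa) 1 - exp(-s / kappa)

#' Evaluate a population response function
#'
#' @param x A [prf()] object.
#' @param contrast,coherence Stimulus strengths as proportions in `[0, 1]`
#'   (vectorized).
#' @return Response in percent signal change.
#' @export
area_response <- function(x, contrast, coherence) {
  stopifnot(inherits(x, "prf"))
  if (any(contrast < 0 | contrast > 1 | coherence < 0 | coherence > 1)) {
    abort("stimulus strengths must lie in [0, 1]")
  }
  x$alpha_con * nr_shape(contrast, x$sigma_con, x$exp_num, x$exp_den) +
    x$alpha_coh * satexp_shape(coherence, x$kappa) +
    x$alpha_task
}

#' Linear slope of the coherence response function
#'
#' The coherence amplitude and scale are not interpretable in isolation, so
#' sensitivity is summarized as the least-squares linear slope of the
#' saturating-exponential coherence curve evaluated on an even grid over
#' coherence `[0, 1]`.
#'
#' @param x A [prf()] object.
#' @param n_grid Number of evenly spaced grid points (default 101).
#' @return Slope in psc per unit coherence.
#' @export
coherence_linear_slope <- function(x, n_grid = 101) {
  stopifnot(inherits(x, "prf"), x$kappa > 0)
  s <- seq(0, 1, length.out = n_grid)
  f <- x$alpha_coh * satexp_shape(s, x$kappa)
  sum((s - mean(s)) * (f - mean(f))) / sum((s - mean(s))^2)
}

# alpha_coh that yields a requested linear slope at a given kappa
alpha_coh_for_slope <- function(slope, kappa, n_grid = 101) {
  unit <- coherence_linear_slope(prf("x", 0, 1, 1, kappa), n_grid)
  slope / unit
}

#' Construct a set of population response functions
#'
#' @param ... [prf()] objects.
#' @return A named list of class `prf_set`, keyed by area.
#' @export
prf_set <- function(...) {
  prfs <- list(...)
  if (length(prfs) == 1 && is.list(prfs[[1]]) && !inherits(prfs[[1]], "prf")) {
    prfs <- prfs[[1]]
  }
  stopifnot(all(vapply(prfs, inherits, logical(1), "prf")))
  names(prfs) <- vapply(prfs, `[[`, character(1), "area")
  structure(prfs, class = "prf_set")
}

#' Passive-viewing population response functions for eight visual areas
#'
#' Default parameterization of contrast and coherence responses measured
#' during passive viewing: contrast amplitudes decline from V1 to MT while
#' coherence sensitivity (the linear slope of the coherence curve) peaks in
#' MT. Coherence amplitudes are chosen so that the linear slope of each
#' near-linear coherence curve (`kappa = 3`) matches the stated per-area
#' slope; the contrast semi-saturation is shared across areas.
#'
#' @param areas Subset of areas to include (default all eight).
#' @param sigma_con Shared contrast semi-saturation constant.
#' @param kappa Shared coherence scale constant.
#' @return A [prf_set()].
#' @export
passive_prf_set <- function(areas = NULL, sigma_con = 0.5, kappa = 3) {
  alpha_con <- c(V1 = 1.68, V2 = 0.69, V3 = 0.63, V4 = 0.61,
                 V3A = 0.35, V3B = 0.24, V7 = 0.32, MT = 0.22)
  coh_slope <- c(V1 = 0.07, V2 = 0.16, V3 = 0.18, V4 = 0.11,
                 V3A = 0.25, V3B = 0.14, V7 = 0.20, MT = 0.34)
  areas <- areas %||% names(alpha_con)
  stopifnot(all(areas %in% names(alpha_con)))
  prf_set(lapply(areas, function(a) {
    prf(a, alpha_con = alpha_con[[a]], sigma_con = sigma_con,
        alpha_coh = alpha_coh_for_slope(coh_slope[[a]], kappa),
        kappa = kappa, alpha_task = 0)
  }))
}

#' Weighted readout of a set of area responses
#'
#' Linearly weights per-area responses to a stimulus into a scalar decision
#' signal: \eqn{\sum_a \beta_a R_a(s)}.
#'
#' @param prfs A [prf_set()].
#' @param weights Named numeric vector of per-area weights covering every
#'   area in `prfs`.
#' @param contrast,coherence Stimulus strengths (vectorized).
#' @return Unitless scalar readout (vectorized over stimuli).
#' @export
readout_response <- function(prfs, weights, contrast, coherence) {
  stopifnot(inherits(prfs, "prf_set"))
  missing <- setdiff(names(prfs), names(weights))
  if (length(missing) > 0) {
    abort(paste0("missing readout weight for area(s): ",
                 paste(missing, collapse = ", ")))
  }
  resp <- vapply(names(prfs),
                 function(a) area_response(prfs[[a]], contrast, coherence) *
                   weights[[a]],
                 numeric(length(contrast)))
  if (is.null(dim(resp))) sum(resp) else rowSums(resp)
}

# matrix of per-area responses: n_stimuli x n_areas
area_response_matrix <- function(prfs, contrast, coherence) {
  vapply(prfs, function(p) area_response(p, contrast, coherence),
         numeric(length(contrast)))
}

#' Serialize / deserialize population response function sets
#'
#' `write_prf_set()` stores one record per area and task; `read_prf_set()`
#' restores the nested structure losslessly (full double precision).
#'
#' @param x For writing: a [prf_set()] or a named list of per-task sets.
#' @param path File path (JSON).
#' @return `read_prf_set()` returns what was written.
#' @export
write_prf_set <- function(x, path) {
  unpack <- function(ps) lapply(unclass(ps), function(p) unclass(p))
  payload <- if (inherits(x, "prf_set")) unpack(x) else lapply(x, unpack)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_prf_set
#' @export
read_prf_set <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  pack <- function(lst) {
    prf_set(lapply(lst, function(p) {
      prf(p$area, p$alpha_con, p$sigma_con, p$alpha_coh, p$kappa, p$alpha_task)
    }))
  }
  if (!is.null(payload[[1]]$area)) pack(payload) else lapply(payload, pack)
}
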