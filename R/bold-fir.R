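#' Build a finite-impulse-response (FIR) design matrix
#'
#' Constructs the `n x (k * c)` stimulus convolution matrix of the FIR
#' deconvolution GLM `y = X beta + eps`. Each block of `k` columns
#' corresponds to one condition: the first column of the block has a 1 at
#' the starting volume of every occurrence of that condition, and each
#' subsequent column is the previous one shifted down by one row (a
#' Toeplitz block). Responses are truncated at the end of the timeseries
#' (no wraparound). The matrix is stored sparse.
#'
#' @param events Event tibble with 0-based `onset_volume` and
#'   `condition_id` columns.
#' @param k Response window length in volumes.
#' @param c Number of conditions; defaults to `max(condition_id) + 1`.
#' @param n Number of volumes; defaults to the `n_volumes` attribute.
#' @return An object of class `fir_design`: list with the sparse `matrix`,
#'   `k`, `c`, `n`, and `condition_labels`.
#' @export
build_fir_design <- function(events, k, c = NULL, n = NULL) {
  n <- n %||% attr(events, "n_volumes")
  c <- c %||% (max(events$condition_id) + 1L)
  if (is.null(n)) abort("`n` must be given or attached to events")
  if (any(events$onset_volume < 0 | events$onset_volume >= n)) {
    abort("event onsets must lie in [0, n)")
  }
  if (any(events$condition_id < 0 | events$condition_id >= c)) {
    abort("condition ids must lie in [0, c)")
  }
  rows <- integer(0); cols <- integer(0)
  for (j in seq_len(c) - 1L) {
    ons <- events$onset_volume[events$condition_id == j]
    if (length(ons) == 0) next
    for (lag in seq_len(k) - 1L) {
      r <- ons + lag
      r <- r[r < n]
      rows <- c(rows, r + 1L)
      cols <- c(cols, rep.int(j * k + lag + 1L, length(r)))
    }
  }
  X <- Matrix::sparseMatrix(i = rows, j = cols, x = 1, dims = c(n, k * c))
  labels <- if ("condition" %in% names(events)) {
    events$condition[match(seq_len(c) - 1L, events$condition_id)]
  } else {
    sprintf("cond%d", seq_len(c) - 1L)
  }
  structure(list(matrix = X, k = as.integer(k), c = as.integer(c),
                 n = as.integer(n), condition_labels = labels),
            class = "fir_design")
}

#' @export
print.fir_design <- function(x, ...) {
  cat(sprintf("<fir_design> %d volumes x (%d lags x %d conditions) = %d columns\n",
              x$n, x$k, x$c, x$k * x$c))
  invisible(x)
}

#' Deconvolve event-related responses by ordinary least squares
#'
#' Solves the FIR GLM `y = X beta + eps` for the per-condition event
#' related responses, accounting linearly for overlap in time. If the
#' design is rank deficient, a minimum-norm (pseudo-inverse) solution is
#' used with a warning. Diagnostics mirror the standard multicollinearity
#' check on randomized designs: the fraction of off-diagonal Gram-matrix
#' entries exceeding 10% of the corresponding diagonal entries.
#'
#' @param y A `bold_timeseries` tibble (or numeric vector) of length
#'   `design$n`.
#' @param design A [build_fir_design()] object.
#' @return A `deconvolution_result`: tibble `fir_responses` (`condition_id`,
#'   `condition`, `lag`, `response`), plus `residual_variance`,
#'   `design_rank`, and `offdiag_flag`.
#' @export
deconvolve <- function(y, design) {
  stopifnot(inherits(design, "fir_design"))
  yv <- if (is.data.frame(y)) y$psc else as.numeric(y)
  if (length(yv) != design$n) {
    abort(sprintf("timeseries length %d does not match design n = %d",
                  length(yv), design$n))
  }
  if (any(!is.finite(yv))) abort("timeseries contains non-finite values")
  X <- design$matrix
  G <- as.matrix(Matrix::crossprod(X))
  Xty <- as.numeric(Matrix::crossprod(X, yv))

  ch <- tryCatch(chol(G), error = function(e) NULL)
  if (!is.null(ch)) {
    beta <- backsolve(ch, forwardsolve(t(ch), Xty))
    rank <- ncol(G)
  } else {
    warn("FIR design is rank deficient; using the minimum-norm solution")
    sv <- svd(G)
    tol <- max(dim(G)) * .Machine$double.eps * sv$d[1]
    pos <- sv$d > tol
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% Xty) / sv$d[pos])
    beta <- as.numeric(beta)
    rank <- sum(pos)
  }

  resid <- yv - as.numeric(X %*% beta)
  dg <- diag(G)
  off <- abs(G) > 0.10 * outer(dg, dg, pmin)
  diag(off) <- FALSE
  frac_off <- mean(off[dg > 0, dg > 0])

  fir <- tibble(
    condition_id = rep(seq_len(design$c) - 1L, each = design$k),
    condition = rep(design$condition_labels, each = design$k),
    lag = rep(seq_len(design$k) - 1L, times = design$c),
    response = beta
  )
  structure(
    list(fir_responses = fir,
         residual_variance = sum(resid^2) / max(design$n - rank, 1),
         design_rank = rank,
         offdiag_flag = frac_off > 0.001 || rank < ncol(G),
         k = design$k, c = design$c),
    class = "deconvolution_result"
  )
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat(sprintf("<deconvolution_result> %d conditions x %d lags, rank %d, resid var %.4g\n",
              x$c, x$k, x$design_rank, x$residual_variance))
  invisible(x)
}

#' Reduce an FIR response to a scalar amplitude against a canonical HRF
#'
#' Least-squares scaling of the unit-peak canonical kernel to the
#' estimated event-related response: the closed-form solution is
#' `<fir, hrf> / <hrf, hrf>`. Amplitudes are linear in the response.
#'
#' @param fir_response Numeric vector of FIR response samples.
#' @param hrf Canonical kernel, peak-normalized (see [canonical_hrf()]).
#'   Truncated or zero-padded to the response length.
#' @return Scalar amplitude (psc).
#' @export
fit_hrf_amplitude <- function(fir_response, hrf) {
  if (all(hrf == 0)) abort("canonical kernel is all zero")
  k <- length(fir_response)
  h <- if (length(hrf) >= k) hrf[seq_len(k)] else c(hrf, rep(0, k - length(hrf)))
  sum(fir_response * h) / sum(h * h)
}

#' Scalar amplitudes for every condition of a deconvolution result
#'
#' @param decon A [deconvolve()] result.
#' @param hrf Canonical kernel.
#' @return Tibble `condition_id`, `condition`, `amplitude`.
#' @export
amplitude_table <- function(decon, hrf = canonical_hrf()) {
  stopifnot(inherits(decon, "deconvolution_result"))
  decon$fir_responses |>
    dplyr::group_by(.data$condition_id, .data$condition) |>
    dplyr::summarise(amplitude = fit_hrf_amplitude(.data$response, hrf),
                     .groups = "drop")
}
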