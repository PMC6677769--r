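#' Canonical hemodynamic response kernel
#'
#' A difference-of-two-gamma-density kernel (positive lobe peaking near
#' 5-6 s, undershoot near 15 s) sampled at the acquisition TR and
#' normalized so its maximum amplitude is exactly 1. Only the unit-peak
#' contract matters downstream: FIR responses are reduced to scalar
#' amplitudes by least-squares scaling of this kernel, so amplitudes are
#' in units of peak percent signal change.
#'
#' @param tr_s Sampling interval in seconds.
#' @param duration_s Kernel support in seconds.
#' @param shape1,rate1 Gamma parameters of the positive lobe.
#' @param shape2,rate2 Gamma parameters of the undershoot.
#' @param undershoot_ratio Relative amplitude of the undershoot.
#' @return Numeric vector of kernel samples (first sample at t = 0), peak 1.
#' @export
canonical_hrf <- function(tr_s = 0.5, duration_s = 40.5,
                          shape1 = 6, rate1 = 1,
                          shape2 = 16, rate2 = 1,
                          undershoot_ratio = 1 / 6) {
  t <- seq(0, duration_s - tr_s, by = tr_s)
  h <- dgamma(t, shape1, rate1) - undershoot_ratio * dgamma(t, shape2, rate2)
  h / max(h)
}
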