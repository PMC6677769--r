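#' Derive a stage-specific random seed from a top-level seed
#'
#' Every stochastic stage of the pipeline draws its random stream from the
#' top-level seed plus a stage label, so adding a stage never perturbs the
#' streams of earlier stages.
#'
#' @param seed Integer top-level seed.
#' @param stage Character stage label.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483647L)
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# round stimulus strengths to the nearest grid value; ties round down
round_to_base <- function(x, bases) {
  bases <- sort(bases)
  vapply(x, function(v) {
    d <- abs(bases - v)
    bases[which(d == min(d))[1]]
  }, numeric(1))
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name))
  }
  invisible(x)
}

`%||%` <- rlang::`%||%`
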