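#' Synthetic observers for staircase simulation
#'
#' `weibull_observer()` returns a psychometric function giving the
#' probability of a correct 2AFC response at increment `x`:
#' \deqn{P(x) = \gamma + (1 - \gamma - \lambda)(1 - e^{-(x/\tau)^\beta})}
#' `step_observer()` is a deterministic observer that is always correct at
#' or above its threshold and always wrong below it (useful as a
#' convergence oracle).
#'
#' @param tau Threshold parameter (63% point above guessing).
#' @param beta Slope parameter.
#' @param gamma Guess rate (0.5 for 2AFC).
#' @param lambda Lapse rate.
#' @return A function `x -> P(correct)`.
#' @export
weibull_observer <- function(tau = 0.10, beta = 3, gamma = 0.5, lambda = 0) {
  stopifnot(tau > 0, beta > 0)
  function(x) gamma + (1 - gamma - lambda) * (1 - exp(-(x / tau)^beta))
}

#' @rdname weibull_observer
#' @param threshold Step location for the deterministic observer.
#' @export
step_observer <- function(threshold) {
  function(x) as.numeric(x >= threshold)
}

new_pest_state <- function(level, step, target = 0.82, wald = 1,
                           min_step = 1e-3, min_level = 1e-3, max_level = 1) {
  list(level = min(max(level, min_level), max_level), step = step,
       target = target, wald = wald, min_step = min_step,
       min_level = min_level, max_level = max_level,
       dir = 0L, same = 0L, doubled = FALSE, doubled_before_rev = FALSE,
       n = 0, c = 0, at_bound = FALSE)
}

# one PEST update after observing `correct` at the current level.
# Classic rules: halve the step on a reversal; keep the step for the second
# step in a direction; double from the third step on, except that the step
# immediately after a reversal that followed a doubling is not doubled.
pest_update <- function(st, correct) {
  st$n <- st$n + 1
  st$c <- st$c + as.numeric(correct)
  dev <- st$c - st$n * st$target
  newdir <- 0L
  if (dev >= st$wald) newdir <- -1L          # above target: make it harder
  else if (dev <= -st$wald) newdir <- 1L     # below target: make it easier
  if (newdir == 0L) return(st)

  if (st$dir != 0L && newdir != st$dir) {    # reversal
    st$doubled_before_rev <- st$doubled
    st$step <- max(st$step / 2, st$min_step)
    st$same <- 1L
    st$doubled <- FALSE
  } else {
    st$same <- st$same + 1L
    if (st$same >= 3L) {
      if (st$same == 3L && st$doubled_before_rev) {
        st$doubled <- FALSE
      } else {
        st$step <- st$step * 2
        st$doubled <- TRUE
      }
    } else {
      st$doubled <- FALSE
    }
  }
  st$dir <- newdir
  st$level <- st$level + newdir * st$step
  st$at_bound <- st$level >= st$max_level
  st$level <- min(max(st$level, st$min_level), st$max_level)
  st$n <- 0; st$c <- 0
  st
}

#' Run a PEST adaptive staircase against a synthetic observer
#'
#' Implements the classic PEST procedure: trials accumulate at the current
#' level until a Wald sequential test decides performance is reliably
#' above or below the target probability, at which point the level steps
#' down or up. Step sizes halve on reversals and double after repeated
#' same-direction steps, with a minimum step floor. Levels are confined to
#' the displayable range (`level + base <= 1` when a base strength is
#' given).
#'
#' @param observer A function `level -> P(correct)`, e.g.
#'   [weibull_observer()].
#' @param n_trials Number of trials to run.
#' @param target Percent-correct level to hold (default 0.82).
#' @param base_level Base stimulus strength; caps the level at
#'   `1 - base_level`.
#' @param init_level,init_step Starting level and step size.
#' @param wald Wald test deviation bound (trials of evidence required
#'   before a step).
#' @param min_step Minimum step size.
#' @param seed Integer seed.
#' @return A tibble of class `pest_trace` with one row per trial: `trial`,
#'   `level`, `correct`, `step`, plus attributes `final_state` and
#'   `diverged` (`TRUE` if the staircase was driven to the upper bound,
#'   as happens for an observer at chance everywhere).
#' @export
run_pest_staircase <- function(observer, n_trials = 500, target = 0.82,
                               base_level = 0, init_level = 0.25,
                               init_step = init_level / 2, wald = 1,
                               min_step = 1e-3, seed = NULL) {
  stopifnot(is.function(observer), n_trials >= 1)
  check_prob(target, "target")
  max_level <- 1 - base_level
  if (max_level <= 0) abort("base_level leaves no displayable increment")
  with_seed_if(seed, {
    st <- new_pest_state(init_level, init_step, target, wald,
                         min_step, max_level = max_level)
    level <- numeric(n_trials); correct <- logical(n_trials)
    stepv <- numeric(n_trials); bound <- logical(n_trials)
    for (t in seq_len(n_trials)) {
      level[t] <- st$level
      stepv[t] <- st$step
      correct[t] <- runif(1) < observer(st$level)
      st <- pest_update(st, correct[t])
      bound[t] <- st$at_bound
    }
    out <- tibble(trial = seq_len(n_trials), level = level,
                  correct = correct, step = stepv)
    class(out) <- c("pest_trace", class(out))
    attr(out, "final_state") <- st
    # a staircase pinned at the upper bound over the last quarter has
    # diverged (observer at chance everywhere)
    tail_idx <- seq.int(max(1, n_trials - n_trials %/% 4), n_trials)
    attr(out, "diverged") <- mean(bound[tail_idx]) > 0.5
    out
  })
}

#' Reset the PEST step size to one third of the current level
#'
#' The step size is periodically reset to a third of the running threshold
#' to allow the staircase to track long-term fluctuation across runs.
#'
#' @param state A PEST state (attribute `final_state` of a `pest_trace`).
#' @return The state with the step reset.
#' @export
pest_reset_step <- function(state) {
  state$step <- max(state$level / 3, state$min_step)
  state$dir <- 0L; state$same <- 0L
  state$doubled <- FALSE; state$doubled_before_rev <- FALSE
  state$n <- 0; state$c <- 0
  state
}
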