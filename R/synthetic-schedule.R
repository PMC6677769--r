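#' Configuration of the two-feature motion-visibility task
#'
#' Defaults reproduce the task structure of the study the package
#' simulates: base increments of +7.5/+15/+30/+60% contrast above a 25%
#' baseline and +15/+30/+45/+60% coherence above 0%, fixed menus of
#' un-cued target increments, 2/5 of behavioral runs containing rare (1/7)
#' post-cued catch trials at a single base increment (+30% contrast, +40%
#' coherence), and inter-trial intervals drawn from an exponential with
#' mean 6 s truncated to 2-11 s. Scan-mode schedules emit onset volumes at
#' a TR of 0.5 s and contain no catch runs.
#'
#' @param base_con_increments,base_coh_increments Base stimulus strength
#'   increments (proportions above baseline).
#' @param baseline_con,baseline_coh Continuous baseline stimulus strengths.
#' @param delta_con_menu,delta_coh_menu Menus of target increments for the
#'   un-cued feature (proportions; include 0).
#' @param catch_run_fraction Fraction of runs containing catch trials.
#' @param catch_trial_prob Per-trial catch probability within catch runs.
#' @param catch_base_con,catch_base_coh The single base increment used on
#'   catch runs.
#' @param iti_mean_s,iti_range_s Mean and (min, max) of the truncated
#'   exponential inter-trial interval, seconds.
#' @param trials_per_run,n_runs Schedule size.
#' @param staircase_target Percent-correct level the adaptive staircase
#'   holds on the cued feature.
#' @param mode `"behavior"` (no event schedule) or `"scan"` (event onsets
#'   at `tr_s`, no catch runs).
#' @param tr_s Repetition time in seconds.
#' @param trial_duration_s Stimulus + delay + response duration, seconds.
#' @param baseline_period_s Adaptation period at the start of each run.
#' @return A list of class `task_config`.
#' @export
task_config <- function(base_con_increments = c(0.075, 0.15, 0.30, 0.60),
                        base_coh_increments = c(0.15, 0.30, 0.45, 0.60),
                        baseline_con = 0.25, baseline_coh = 0,
                        delta_con_menu = c(0, 1.8, 2.5, 3.5, 4.9, 6.9, 9.5, 13.3, 18.5) / 100,
                        delta_coh_menu = c(0, 5.0, 6.9, 9.6, 13.4, 18.6, 25.9, 36.1, 50.2) / 100,
                        catch_run_fraction = 2 / 5,
                        catch_trial_prob = 1 / 7,
                        catch_base_con = 0.30, catch_base_coh = 0.40,
                        iti_mean_s = 6, iti_range_s = c(2, 11),
                        trials_per_run = 28, n_runs = 10,
                        staircase_target = 0.82,
                        mode = c("behavior", "scan"),
                        tr_s = 0.5, trial_duration_s = 2,
                        baseline_period_s = 30) {
  mode <- match.arg(mode)
  check_prob(catch_run_fraction, "catch_run_fraction")
  check_prob(catch_trial_prob, "catch_trial_prob")
  check_prob(staircase_target, "staircase_target")
  if (length(iti_range_s) != 2 || iti_range_s[1] > iti_range_s[2]) {
    abort("`iti_range_s` must be (min, max) with min <= max")
  }
  if (iti_mean_s < iti_range_s[1] || iti_mean_s > iti_range_s[2]) {
    abort("`iti_mean_s` must lie within `iti_range_s`")
  }
  if (any(baseline_con + base_con_increments > 1) ||
      any(baseline_coh + base_coh_increments > 1)) {
    abort("base stimulus strengths exceed the displayable range [0, 1]")
  }
  stopifnot(trials_per_run >= 1, n_runs >= 1, tr_s > 0)
  structure(as.list(environment()), class = "task_config")
}

#' Draw truncated-exponential inter-trial intervals
#'
#' Samples from an exponential distribution truncated to a range, with the
#' rate chosen so the truncated mean matches the requested mean. Uses the
#' inverse CDF, so a fixed seed gives a fixed sequence.
#'
#' @param n Number of draws.
#' @param mean_s Desired mean of the truncated distribution.
#' @param range_s Length-2 numeric (min, max).
#' @return Numeric vector of intervals in seconds.
#' @export
rtrunc_exp <- function(n, mean_s = 6, range_s = c(2, 11)) {
  a <- range_s[1]; b <- range_s[2]
  # the truncated-exponential mean lies strictly between a and (a + b) / 2
  stopifnot(a < b, mean_s > a, mean_s < (a + b) / 2)
  trunc_mean <- function(r) {
    d <- b - a
    a + 1 / r - d * exp(-r * d) / (1 - exp(-r * d))
  }
  # mean of the truncated exponential is decreasing in the rate
  rate <- uniroot(function(r) trunc_mean(r) - mean_s,
                  interval = c(1e-6, 50), tol = 1e-12)$root
  u <- runif(n)
  a - log(1 - u * (1 - exp(-rate * (b - a)))) / rate
}

condition_label <- function(con_idx, coh_idx, task) {
  sprintf("con%d_coh%d_task%s", con_idx, coh_idx, task)
}

#' Generate a task schedule (trials with choices unset)
#'
#' Runs alternate between the contrast and the coherence task. Within
#' regular runs, the base contrast and coherence increments of each trial
#' are drawn independently and uniformly from their grids, so every
#' condition is equally likely to follow every other. The target side for
#' each feature is assigned independently. In behavior mode, the
#' configured fraction of runs are catch runs: they use a single base
#' increment and each trial is post-cued with the configured probability.
#' Un-cued target increments are drawn from the fixed menus; cued
#' increments are drawn from the non-zero menu entries as placeholders and
#' are replaced trial-by-trial when an adaptive staircase is attached in
#' [simulate_observer()].
#'
#' @param cfg A [task_config()].
#' @param seed Integer seed.
#' @return A list with `trials` (tibble, one row per trial, choices unset)
#'   and `events` (tibble of `onset_volume`, `condition_id`, `condition`;
#'   `NULL` in behavior mode). Scan-mode events carry attributes
#'   `n_volumes` and `tr_s`.
#' @export
generate_task_schedule <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "task_config"))
  with_seed_if(seed, generate_schedule_impl(cfg))
}

generate_schedule_impl <- function(cfg) {
  bases_con <- cfg$baseline_con + cfg$base_con_increments
  bases_coh <- cfg$baseline_coh + cfg$base_coh_increments
  n_con <- length(bases_con); n_coh <- length(bases_coh)

  run_task <- rep(c("contrast", "coherence"), length.out = cfg$n_runs)
  n_catch_runs <- if (cfg$mode == "scan") 0L else round(cfg$catch_run_fraction * cfg$n_runs)
  # spread catch runs over both tasks
  is_catch_run <- rep(FALSE, cfg$n_runs)
  if (n_catch_runs > 0) {
    is_catch_run[sample.int(cfg$n_runs, n_catch_runs)] <- TRUE
  }

  trials <- purrr::map_dfr(seq_len(cfg$n_runs), function(r) {
    nt <- cfg$trials_per_run
    task <- run_task[r]
    if (is_catch_run[r]) {
      con_idx <- rep(which.min(abs(cfg$base_con_increments - cfg$catch_base_con)) - 1L, nt)
      coh_idx <- rep(which.min(abs(cfg$base_coh_increments - cfg$catch_base_coh)) - 1L, nt)
      base_con <- rep(cfg$baseline_con + cfg$catch_base_con, nt)
      base_coh <- rep(cfg$baseline_coh + cfg$catch_base_coh, nt)
      is_catch <- runif(nt) < cfg$catch_trial_prob
    } else {
      con_idx <- sample.int(n_con, nt, replace = TRUE) - 1L
      coh_idx <- sample.int(n_coh, nt, replace = TRUE) - 1L
      base_con <- bases_con[con_idx + 1L]
      base_coh <- bases_coh[coh_idx + 1L]
      is_catch <- rep(FALSE, nt)
    }
    other <- if (task == "contrast") "coherence" else "contrast"
    delta_con <- if (task == "contrast") {
      sample(cfg$delta_con_menu[cfg$delta_con_menu > 0], nt, replace = TRUE)
    } else {
      sample(cfg$delta_con_menu, nt, replace = TRUE)
    }
    delta_coh <- if (task == "coherence") {
      sample(cfg$delta_coh_menu[cfg$delta_coh_menu > 0], nt, replace = TRUE)
    } else {
      sample(cfg$delta_coh_menu, nt, replace = TRUE)
    }
    delta_con <- pmin(delta_con, 1 - base_con)
    delta_coh <- pmin(delta_coh, 1 - base_coh)
    tibble(
      run_id = r, task = task, is_catch_run = is_catch_run[r],
      con_idx = con_idx, coh_idx = coh_idx,
      base_con = base_con, base_coh = base_coh,
      delta_con = delta_con, delta_coh = delta_coh,
      target_side_con = sample(c("left", "right"), nt, replace = TRUE),
      target_side_coh = sample(c("left", "right"), nt, replace = TRUE),
      is_catch = is_catch,
      post_cue = ifelse(is_catch, other, "none"),
      iti_s = rtrunc_exp(nt, cfg$iti_mean_s, cfg$iti_range_s)
    )
  })

  trials <- trials |>
    dplyr::mutate(
      trial_id = dplyr::row_number(),
      stim_con_left = .data$base_con +
        ifelse(.data$target_side_con == "left", .data$delta_con, 0),
      stim_con_right = .data$base_con +
        ifelse(.data$target_side_con == "right", .data$delta_con, 0),
      stim_coh_left = .data$base_coh +
        ifelse(.data$target_side_coh == "left", .data$delta_coh, 0),
      stim_coh_right = .data$base_coh +
        ifelse(.data$target_side_coh == "right", .data$delta_coh, 0),
      choice = "none", correct = NA,
      prev_choice = "none", prev_correct = NA
    ) |>
    dplyr::select("trial_id", dplyr::everything())

  events <- NULL
  if (cfg$mode == "scan") {
    events <- trials |>
      dplyr::group_by(.data$run_id) |>
      dplyr::mutate(
        onset_s = cfg$baseline_period_s +
          dplyr::lag(cumsum(cfg$trial_duration_s + .data$iti_s), default = 0)
      ) |>
      dplyr::ungroup()
    run_len_s <- events |>
      dplyr::group_by(.data$run_id) |>
      dplyr::summarise(len = max(.data$onset_s) + cfg$trial_duration_s + 40.5) |>
      dplyr::pull(.data$len)
    run_vols <- ceiling(run_len_s / cfg$tr_s)
    run_offset_vol <- cumsum(c(0, run_vols[-length(run_vols)]))
    events <- events |>
      dplyr::mutate(
        onset_volume = run_offset_vol[.data$run_id] +
          as.integer(round(.data$onset_s / cfg$tr_s)),
        condition_id = (as.integer(.data$task == "coherence") *
                          n_coh + .data$coh_idx) * n_con + .data$con_idx,
        condition = condition_label(.data$con_idx, .data$coh_idx, .data$task)
      ) |>
      dplyr::select("onset_volume", "condition_id", "condition")
    attr(events, "n_volumes") <- sum(run_vols)
    attr(events, "tr_s") <- cfg$tr_s
    attr(events, "n_conditions") <- 2L * n_con * n_coh
  }

  list(trials = trials, events = events)
}
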