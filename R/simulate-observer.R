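#' Simulate an observer's trial-by-trial choices from a linking model
#'
#' Draws each choice as a Bernoulli sample with P(right) given by
#' [choice_probability()] under a ground-truth [readout_model()], using the
#' task-appropriate weights (the post-cued feature's weights on catch
#' trials). Fills in correctness against the target side of the judged
#' feature and the previous-trial fields used by the stay/switch history
#' variant (reset at the first trial of each run).
#'
#' When a staircase configuration is supplied, the cued feature's target
#' increment is controlled trial-by-trial by an independent PEST staircase
#' per (task, base strength) pair — 8 staircases for the default 4-base,
#' 2-task design — updated only on trials with feedback (non-catch), with
#' the step size reset to a third of the current level every third run.
#'
#' @param trials A schedule tibble from [generate_task_schedule()] (choices
#'   unset).
#' @param truth Ground-truth [readout_model()].
#' @param prfs A [prf_set()] or per-task list.
#' @param seed Integer seed.
#' @param staircase `NULL` for menu-drawn increments, or a list of PEST
#'   settings as produced by [staircase_settings()].
#' @return The trials tibble with `choice`, `correct`, `prev_choice`,
#'   `prev_correct` (and, under staircasing, `delta_*` and `stim_*`)
#'   filled in. Staircase level traces are attached as attribute
#'   `staircase_levels`.
#' @export
simulate_observer <- function(trials, truth, prfs, seed = 1, staircase = NULL) {
  stopifnot(inherits(truth, "readout_model"))
  if (anyNA(trials[c("stim_con_left", "stim_con_right",
                     "stim_coh_left", "stim_coh_right")])) {
    abort("schedule has unset stimuli")
  }
  with_seed_if(seed, {
    if (is.null(staircase) && is.null(truth$history)) {
      simulate_vectorized(trials, truth, prfs)
    } else {
      simulate_sequential(trials, truth, prfs, staircase)
    }
  })
}

#' PEST settings for staircased observer simulation
#'
#' @param init_level_con,init_level_coh Initial levels for the contrast and
#'   coherence staircases (defaults 25% and 85%).
#' @param target Percent-correct level the staircases hold.
#' @param wald Wald test deviation bound.
#' @param min_step Minimum step size.
#' @param init_step_frac Initial step as a fraction of the initial level.
#' @param reset_every_runs Reset the step to a third of the level at the
#'   start of every this-many-th run.
#' @return A list of settings for [simulate_observer()].
#' @export
staircase_settings <- function(init_level_con = 0.25, init_level_coh = 0.85,
                               target = 0.82, wald = 1, min_step = 1e-3,
                               init_step_frac = 0.5, reset_every_runs = 3) {
  list(init_level_con = init_level_con, init_level_coh = init_level_coh,
       target = target, wald = wald, min_step = min_step,
       init_step_frac = init_step_frac, reset_every_runs = reset_every_runs)
}

judged_feature <- function(task, is_catch, post_cue) {
  ifelse(is_catch & post_cue != "none", post_cue, task)
}

score_choices <- function(trials) {
  judged <- judged_feature(trials$task, trials$is_catch, trials$post_cue)
  target <- ifelse(judged == "contrast", trials$target_side_con,
                   trials$target_side_coh)
  trials$correct <- trials$choice == target
  trials
}

fill_prev_fields <- function(trials) {
  trials |>
    dplyr::group_by(.data$run_id) |>
    dplyr::mutate(
      prev_choice = dplyr::lag(.data$choice, default = "none"),
      prev_correct = dplyr::lag(.data$correct, default = NA)
    ) |>
    dplyr::ungroup()
}

simulate_vectorized <- function(trials, truth, prfs) {
  p <- choice_probability(truth, prfs, trials)
  trials$choice <- ifelse(runif(nrow(trials)) < p, "right", "left")
  trials <- score_choices(trials)
  fill_prev_fields(trials)
}

simulate_sequential <- function(trials, truth, prfs, staircase) {
  n <- nrow(trials)
  target_p <- staircase$target %||% 0.82
  states <- list()
  level_trace <- rep(NA_real_, n)
  prev_choice <- "none"; prev_correct <- NA
  last_run <- trials$run_id[1]

  get_state <- function(task, base) {
    key <- paste(task, signif(base, 8), sep = "@")
    if (is.null(states[[key]])) {
      init <- if (task == "contrast") staircase$init_level_con else staircase$init_level_coh
      init <- min(init, 1 - base)
      states[[key]] <<- new_pest_state(
        level = init, step = init * staircase$init_step_frac,
        target = target_p, wald = staircase$wald,
        min_step = staircase$min_step, max_level = 1 - base)
    }
    list(key = key, st = states[[key]])
  }

  for (i in seq_len(n)) {
    tr <- trials[i, ]
    if (tr$run_id != last_run) {
      prev_choice <- "none"; prev_correct <- NA
      if (!is.null(staircase) &&
          (tr$run_id - 1) %% staircase$reset_every_runs == 0 && tr$run_id > 1) {
        states <- lapply(states, pest_reset_step)
      }
      last_run <- tr$run_id
    }

    if (!is.null(staircase)) {
      base <- if (tr$task == "contrast") tr$base_con else tr$base_coh
      gs <- get_state(tr$task, base)
      lvl <- gs$st$level
      level_trace[i] <- lvl
      if (tr$task == "contrast") {
        trials$delta_con[i] <- lvl
        trials$stim_con_left[i] <- tr$base_con +
          if (tr$target_side_con == "left") lvl else 0
        trials$stim_con_right[i] <- tr$base_con +
          if (tr$target_side_con == "right") lvl else 0
      } else {
        trials$delta_coh[i] <- lvl
        trials$stim_coh_left[i] <- tr$base_coh +
          if (tr$target_side_coh == "left") lvl else 0
        trials$stim_coh_right[i] <- tr$base_coh +
          if (tr$target_side_coh == "right") lvl else 0
      }
      tr <- trials[i, ]
    }

    tr$prev_choice <- prev_choice
    tr$prev_correct <- prev_correct
    p <- choice_probability(truth, prfs, tr)
    choice <- if (runif(1) < p) "right" else "left"
    judged <- judged_feature(tr$task, tr$is_catch, tr$post_cue)
    target <- if (judged == "contrast") tr$target_side_con else tr$target_side_coh
    correct <- choice == target

    trials$choice[i] <- choice
    trials$correct[i] <- correct
    trials$prev_choice[i] <- prev_choice
    trials$prev_correct[i] <- prev_correct
    prev_choice <- choice
    prev_correct <- correct

    if (!is.null(staircase) && !tr$is_catch) {
      base <- if (tr$task == "contrast") tr$base_con else tr$base_coh
      gs <- get_state(tr$task, base)
      states[[gs$key]] <- pest_update(gs$st, correct)
    }
  }
  attr(trials, "staircase_levels") <- level_trace
  trials
}
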