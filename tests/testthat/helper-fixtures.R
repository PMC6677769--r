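# Shared fixtures: a two-area observer with realistic sensitivity and
# independent brute-force oracles for the linking-model computations.

fx_prfs2 <- function() passive_prf_set(c("V1", "MT"))

fx_truth2 <- function(lapse = 0.03, beta_bias = 0.1, memory_cost = 2.83,
                      noise_mode = "additive") {
  readout_model(
    c("V1", "MT"),
    weights = list(contrast = c(V1 = 12, MT = -2),
                   coherence = c(V1 = -1, MT = 18)),
    beta_bias = beta_bias, lapse = lapse, readout_mode = "flexible",
    noise_mode = noise_mode, memory_cost = memory_cost
  )
}

fx_trials <- function(n_runs = 20, trials_per_run = 50, seed = 1,
                      staircase = FALSE, truth = fx_truth2(),
                      prfs = fx_prfs2(), catch_run_fraction = 2 / 5) {
  cfg <- task_config(trials_per_run = trials_per_run, n_runs = n_runs,
                     catch_run_fraction = catch_run_fraction)
  sc <- generate_task_schedule(cfg, seed = stage_seed(seed, "sched"))
  simulate_observer(sc$trials, truth, prfs,
                    seed = stage_seed(seed, "obs"),
                    staircase = if (staircase) staircase_settings())
}

# one-row trial tibble for choice-probability tests
fx_trial_row <- function(task = "contrast",
                         con_l = 0.4, con_r = 0.4, coh_l = 0.15, coh_r = 0.15,
                         is_catch = FALSE, post_cue = "none",
                         prev_choice = "none", prev_correct = NA) {
  tibble::tibble(task = task,
                 stim_con_left = con_l, stim_con_right = con_r,
                 stim_coh_left = coh_l, stim_coh_right = coh_r,
                 is_catch = is_catch, post_cue = post_cue,
                 prev_choice = prev_choice, prev_correct = prev_correct)
}

# Monte-Carlo oracle for the choice probability: simulates the noisy
# decision variable directly from the model equations with plain
# arithmetic, independently of choice_probability()'s vectorized path.
mc_choice_prob <- function(model, prfs, trial, n_draws = 2e5) {
  resp1 <- function(p, con, coh) {
    p$alpha_con * con^1.9 / (con^1.6 + p$sigma_con^1.6) +
      p$alpha_coh * (1 - exp(-coh / p$kappa)) + p$alpha_task
  }
  prfs_t <- if (inherits(prfs, "prf_set")) {
    list(contrast = prfs, coherence = prfs)
  } else prfs
  tk <- trial$task
  if (isTRUE(trial$is_catch) && trial$post_cue != "none") tk <- trial$post_cue
  ps <- prfs_t[[tk]]
  w <- model$weights[[tk]]
  rho <- model$selection_rho
  spow <- function(x, p) sign(x) * abs(x)^p
  rR <- vapply(model$areas, function(a) {
    resp1(ps[[a]], trial$stim_con_right, trial$stim_coh_right)
  }, numeric(1))
  rL <- vapply(model$areas, function(a) {
    resp1(ps[[a]], trial$stim_con_left, trial$stim_coh_left)
  }, numeric(1))
  if (!is.null(rho)) {
    u <- sum(w[model$areas] * (spow(rR, rho) - spow(rL, rho))) + model$beta_bias
    eta <- spow(u, 1 / rho)
  } else {
    eta <- sum(w[model$areas] * (rR - rL)) + model$beta_bias
  }
  if (!is.null(model$history) && trial$prev_choice != "none") {
    pk <- isTRUE(trial$prev_correct)
    eta <- eta +
      model$history[["beta_left_correct"]] * (trial$prev_choice == "left" && pk) +
      model$history[["beta_right_correct"]] * (trial$prev_choice == "right" && pk) +
      model$history[["beta_left_incorrect"]] * (trial$prev_choice == "left" && !pk) +
      model$history[["beta_right_incorrect"]] * (trial$prev_choice == "right" && !pk)
  }
  sig <- 1
  if (model$noise_mode == "poisson") {
    sig <- sqrt(max((mean(rR) + mean(rL)) / 2, 1e-8))
  }
  if (isTRUE(trial$is_catch) && trial$post_cue != "none") {
    sig <- sig * model$memory_cost
  }
  hit <- mean(eta / sig + rnorm(n_draws) > 0)
  model$lapse / 2 + (1 - model$lapse) * hit
}

# exhaustive grid-search oracle for the predicted JND
grid_jnd <- function(model, prfs, task, base, target = 1, step = 1e-5) {
  prfs_t <- if (inherits(prfs, "prf_set")) {
    list(contrast = prfs, coherence = prfs)
  } else prfs
  ps <- prfs_t[[task]]
  w <- model$weights[[task]]
  base_level <- base[[task]]
  deltas <- seq(0, 1 - base_level, by = step)
  W <- function(d) {
    if (task == "contrast") {
      readout_response(ps, w, base[["contrast"]] + d,
                       rep(base[["coherence"]], length(d)))
    } else {
      readout_response(ps, w, rep(base[["contrast"]], length(d)),
                       base[["coherence"]] + d)
    }
  }
  vals <- W(deltas) - W(0)
  hit <- which(vals >= target)
  if (length(hit) == 0) return(NA_real_)
  deltas[hit[1]]
}
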