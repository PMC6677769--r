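#' Validate a pipeline configuration
#'
#' Parses a YAML file (or takes a list), fills defaults, and rejects
#' unknown keys. The defaults reproduce the study conditions: the base
#' increment grids, 2/5 catch runs with 1/7 catch trials, truncated
#' exponential ITIs with mean 6 s on 2-11 s, a TR of 0.5 s with an
#' 81-volume FIR response window (so the full 32-condition scan grid has
#' 81 x 32 = 2592 design columns), ten cross-validation folds, and a
#' two-area (V1, MT) ground-truth observer with a flexible readout, a 3%
#' lapse rate, and a working-memory cost of 2.83 on catch trials.
#'
#' @param raw Path to a YAML config, a YAML string, or a list. An empty or
#'   `NULL` input yields the full default configuration.
#' @return A `pipeline_config` list with sections `seed`, `task`, `truth`,
#'   `fitting`, `comparison`, `bold`, `output_dir`.
#' @export
validate_config <- function(raw = NULL) {
  defaults <- list(
    seed = 1L,
    output_dir = "flexreadout-output",
    task = list(
      base_con_increments = c(0.075, 0.15, 0.30, 0.60),
      base_coh_increments = c(0.15, 0.30, 0.45, 0.60),
      baseline_con = 0.25, baseline_coh = 0,
      catch_run_fraction = 2 / 5, catch_trial_prob = 1 / 7,
      iti_mean_s = 6, iti_range_s = c(2, 11),
      trials_per_run = 50, n_runs = 80,
      staircase_target = 0.82, mode = "behavior",
      tr_s = 0.5, use_staircase = TRUE
    ),
    truth = list(
      areas = c("V1", "MT"),
      weights = list(contrast = c(V1 = 12, MT = -2),
                     coherence = c(V1 = -1, MT = 18)),
      beta_bias = 0.1, lapse = 0.03, readout_mode = "flexible",
      noise_mode = "additive", memory_cost = 2.83
    ),
    fitting = list(n_restarts = 5, weight_bound = 50, bias_bound = 10),
    comparison = list(
      n_folds = 10,
      variants = list(
        flexible = list(readout_mode = "flexible", noise_mode = "additive"),
        fixed = list(readout_mode = "fixed", noise_mode = "additive")
      )
    ),
    bold = list(enabled = FALSE, k = 81, noise_sd = 0.3, areas = c("V1", "MT"))
  )

  user <- raw
  if (is.character(raw)) {
    user <- if (file.exists(raw)) yaml::read_yaml(raw) else yaml::yaml.load(raw)
  }
  user <- user %||% list()
  if (!is.list(user)) abort("config must parse to a mapping")

  merged <- merge_config(defaults, user, path = "")
  check_prob(merged$task$catch_trial_prob, "task.catch_trial_prob")
  check_prob(merged$task$catch_run_fraction, "task.catch_run_fraction")
  check_prob(merged$truth$lapse, "truth.lapse")
  if (merged$task$iti_range_s[1] > merged$task$iti_range_s[2]) {
    abort("task.iti_range_s is inverted")
  }
  merged$task_cfg <- do.call(task_config, merged$task[
    setdiff(names(merged$task), "use_staircase")])
  merged$n_design_columns <- merged$bold$k *
    (2L * length(merged$task$base_con_increments) *
       length(merged$task$base_coh_increments))
  structure(merged, class = "pipeline_config")
}

merge_config <- function(defaults, user, path) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s",
                  paste0(sub("^\\.", "", paste0(path, ".", unknown)),
                         collapse = ", ")))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(user[[k]]) && k != "variants" && k != "weights") {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, ".", k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Run the full simulate-fit-compare pipeline
#'
#' Executes the stages: simulate behavior (schedule + observer choices,
#' optionally staircased), estimate the lapse rate, fit descriptive
#' psychometric functions and the Weibull threshold table, optionally
#' simulate and deconvolve BOLD data and refit the population response
#' functions, fit all requested linking-model variants, and compare them
#' by cross-validated log-likelihood and Tjur's CD. Every stochastic
#' stage derives its stream from the top-level seed plus a stage label,
#' and all artifacts are written under `output_dir` together with a
#' machine-readable JSON report stamped with the config hash and seed.
#'
#' @param cfg A `pipeline_config` from [validate_config()].
#' @return The report list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed
  report <- list(config_hash = rlang::hash(unclass(cfg)), seed = seed,
                 stages = character(0))
  stage <- function(name, code) {
    t0 <- Sys.time()
    out <- tryCatch(code, error = function(e) {
      jsonlite::write_json(report, file.path(cfg$output_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, na = "null",
                           force = TRUE)
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    message(sprintf("[%s] seed=%d elapsed=%.2fs", name, seed,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    report$stages <<- c(report$stages, name)
    out
  }

  truth <- readout_model(
    areas = cfg$truth$areas,
    weights = if (cfg$truth$readout_mode == "fixed") {
      unlist(cfg$truth$weights$contrast)
    } else {
      list(contrast = unlist(cfg$truth$weights$contrast),
           coherence = unlist(cfg$truth$weights$coherence))
    },
    beta_bias = cfg$truth$beta_bias, lapse = cfg$truth$lapse,
    readout_mode = cfg$truth$readout_mode, noise_mode = cfg$truth$noise_mode,
    memory_cost = cfg$truth$memory_cost
  )
  prfs <- passive_prf_set(cfg$truth$areas)

  sched <- stage("simulate-behavior", {
    sc <- generate_task_schedule(cfg$task_cfg, stage_seed(seed, "schedule"))
    tr <- simulate_observer(
      sc$trials, truth, prfs, seed = stage_seed(seed, "observer"),
      staircase = if (isTRUE(cfg$task$use_staircase)) {
        staircase_settings(target = cfg$task$staircase_target)
      })
    write_trials(tr, file.path(cfg$output_dir, "trials.csv"))
    if (!is.null(sc$events)) {
      write_events(sc$events, file.path(cfg$output_dir, "events.csv"))
    }
    list(trials = tr, events = sc$events)
  })
  trials <- sched$trials

  lapse <- stage("estimate-lapse", {
    tryCatch(estimate_lapse(trials)$lambda, error = function(e) cfg$truth$lapse)
  })
  report$lapse <- lapse

  psycho <- stage("fit-psychometric", {
    fits <- list(
      contrast = fit_cum_normal(trials[trials$task == "contrast", ]),
      coherence = fit_cum_normal(trials[trials$task == "coherence", ])
    )
    thresholds <- weibull_fit_table(trials, lambda = lapse)
    write_fits_json(c(fits, list(thresholds = thresholds)),
                    file.path(cfg$output_dir, "fits.json"))
    list(fits = fits, thresholds = thresholds)
  })
  report$psychometric <- list(
    r2_pseudo = purrr::map_dbl(psycho$fits, "r2_pseudo"),
    n_weibull_fits = nrow(psycho$thresholds)
  )

  if (isTRUE(cfg$bold$enabled)) {
    bold_out <- stage("simulate-and-fit-bold", {
      scan_cfg <- do.call(task_config, utils::modifyList(
        cfg$task[setdiff(names(cfg$task), "use_staircase")],
        list(mode = "scan")))
      sc <- generate_task_schedule(scan_cfg, stage_seed(seed, "scan-schedule"))
      write_events(sc$events, file.path(cfg$output_dir, "events.csv"))
      hrf <- canonical_hrf(tr_s = cfg$task$tr_s)
      purrr::map(cfg$bold$areas, function(a) {
        amp_tab <- condition_amplitude_table(prfs[[a]], scan_cfg)
        y <- simulate_bold_timeseries(
          sc$events, amplitudes = amp_tab$amplitude, hrf = hrf,
          noise_sd = cfg$bold$noise_sd, area = a, hemisphere = "left",
          seed = stage_seed(seed, paste0("bold-", a)))
        write_bold(y, file.path(cfg$output_dir, sprintf("bold_%s_left.csv", a)))
        design <- build_fir_design(sc$events, k = cfg$bold$k,
                                   c = attr(sc$events, "n_conditions"))
        amps <- amplitude_table(deconvolve(y, design), hrf) |>
          dplyr::left_join(amp_tab[, c("condition_id", "task",
                                       "base_con", "base_coh")],
                           by = "condition_id")
        fit <- fit_response_functions(amps, prfs[[a]])
        list(area = a, amplitudes = amps, fit = fit$params)
      }) |> stats::setNames(cfg$bold$areas)
    })
    all_amps <- purrr::map_dfr(bold_out, function(b) {
      dplyr::mutate(b$amplitudes, area = b$area)
    })
    readr::write_csv(
      all_amps[, c("area", "base_con", "base_coh", "task", "amplitude")],
      file.path(cfg$output_dir, "amplitudes.csv"))
    jsonlite::write_json(purrr::map(bold_out, "fit"),
                         file.path(cfg$output_dir, "prf_fits.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    report$bold <- purrr::map(bold_out, function(b) {
      list(area = b$area, sse = sum(b$fit$sse))
    })
  }

  comparison <- stage("compare-models", {
    compare_readout_models(
      trials, prfs, cfg$comparison$variants, lapse = lapse,
      n_folds = cfg$comparison$n_folds,
      seed = stage_seed(seed, "cv-folds"),
      n_restarts = cfg$fitting$n_restarts)
  })
  report$comparison <- list(
    summary = comparison$summary,
    ratio_table = comparison$ratio_table
  )
  jsonlite::write_json(
    list(summary = comparison$summary, ratio_table = comparison$ratio_table),
    file.path(cfg$output_dir, "comparison.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", matrix = "rowmajor")

  jsonlite::write_json(report, file.path(cfg$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows", matrix = "rowmajor", force = TRUE)
  invisible(report)
}
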