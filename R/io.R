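#' Read and write trial tables
#'
#' The on-disk schema has one row per trial with columns `trial_id`,
#' `run_id`, `task`, `base_con`, `base_coh`, `delta_con`, `delta_coh`,
#' `target_side_con`, `target_side_coh`, `stim_con_left`, `stim_con_right`,
#' `stim_coh_left`, `stim_coh_right`, `is_catch`, `post_cue`, `choice`,
#' `correct`. Proportions are decimals; enums lowercase. Internal-only
#' columns (previous-trial fields, run bookkeeping) are recomputed on
#' read.
#'
#' @param trials Trials tibble.
#' @param path CSV file path.
#' @return `read_trials()` returns the trials tibble with previous-trial
#'   fields refilled.
#' @export
write_trials <- function(trials, path) {
  cols <- c("trial_id", "run_id", "task", "base_con", "base_coh",
            "delta_con", "delta_coh", "target_side_con", "target_side_coh",
            "stim_con_left", "stim_con_right", "stim_coh_left",
            "stim_coh_right", "is_catch", "post_cue", "choice", "correct")
  extra <- intersect("is_catch_run", names(trials))
  readr::write_csv(trials[, c(cols, extra)], path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"is_catch_run" %in% names(out)) {
    out <- out |>
      dplyr::group_by(.data$run_id) |>
      dplyr::mutate(is_catch_run = any(.data$is_catch)) |>
      dplyr::ungroup()
  }
  fill_prev_fields(out)
}

#' Read and write event schedules
#'
#' Columns: `onset_volume` (0-based), `condition_id` (0-based), and the
#' condition label `conA_cohB_taskT`.
#'
#' @param events Events tibble.
#' @param path CSV file path.
#' @param n_volumes,tr_s Restored as attributes on read (stored in the
#'   header comment on write).
#' @export
write_events <- function(events, path) {
  hdr <- sprintf("# n_volumes=%d tr_s=%g",
                 attr(events, "n_volumes") %||% NA_integer_,
                 attr(events, "tr_s") %||% 0.5)
  writeLines(hdr, path)
  readr::write_csv(events[, c("onset_volume", "condition_id", "condition")],
                   path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path, n_volumes = NULL, tr_s = NULL) {
  hdr <- readLines(path, n = 1)
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  m <- regmatches(hdr, regexec("n_volumes=([0-9NA]+) tr_s=([0-9.]+)", hdr))[[1]]
  attr(out, "n_volumes") <- n_volumes %||%
    (if (length(m) == 3 && m[2] != "NA") as.integer(m[2]) else NULL)
  attr(out, "tr_s") <- tr_s %||% (if (length(m) == 3) as.numeric(m[3]) else 0.5)
  out
}

#' Read and write BOLD timeseries
#'
#' Columns: `volume_index` (0-based) and `psc` (percent signal change).
#' Files are conventionally named `bold_<area>_<hemi>.csv`.
#'
#' @param bold A `bold_timeseries` tibble.
#' @param path CSV file path.
#' @export
write_bold <- function(bold, path) {
  readr::write_csv(bold[, c("volume_index", "psc")], path)
  invisible(path)
}

#' @rdname write_bold
#' @param area,hemisphere,tr_s Metadata attached on read.
#' @export
read_bold <- function(path, area = NA_character_, hemisphere = NA_character_,
                      tr_s = 0.5) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (any(!is.finite(out$psc))) abort("BOLD timeseries contains non-finite values")
  class(out) <- c("bold_timeseries", class(out))
  attr(out, "area") <- area
  attr(out, "hemisphere") <- hemisphere
  attr(out, "tr_s") <- tr_s
  out
}

#' Write psychometric fits to JSON
#'
#' One record per fit: type, grouping keys, parameters, log-likelihood,
#' pseudo-r2 and measurability flag where applicable.
#'
#' @param fits A list of `cumnormal_fit` / `weibull_fit` objects or a
#'   [weibull_fit_table()] tibble.
#' @param path JSON file path.
#' @export
write_fits_json <- function(fits, path) {
  serialize_one <- function(f) {
    if (inherits(f, "cumnormal_fit")) {
      list(type = "cum_normal", feature = f$feature, mu = f$mu,
           sigma = f$sigma, lambda = f$lambda, loglik = f$loglik,
           r2_pseudo = f$r2_pseudo, n = f$n)
    } else if (inherits(f, "weibull_fit")) {
      list(type = "weibull", tau = f$tau, beta_slope = f$beta_slope,
           gamma = f$gamma, lambda = f$lambda, loglik = f$loglik,
           jnd = f$jnd, measurable = f$measurable, n = f$n)
    } else {
      f
    }
  }
  payload <- if (is.data.frame(fits)) fits else purrr::map(fits, serialize_one)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
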