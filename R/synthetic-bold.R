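#' Simulate a BOLD timeseries by linear summation of event responses
#'
#' Each event contributes its amplitude times the canonical kernel shifted
#' to the event onset; overlapping responses sum linearly (the assumption
#' the deconvolution analysis inverts). Responses are truncated at the end
#' of the timeseries, and i.i.d. Gaussian noise of a given standard
#' deviation is added.
#'
#' @param events Event tibble with `onset_volume` (0-based) and
#'   `condition_id` (0-based), as from [generate_task_schedule()] in scan
#'   mode; alternatively it may carry a per-event `amplitude` column.
#' @param amplitudes Named or plain numeric vector of per-condition
#'   amplitudes indexed by `condition_id + 1`; ignored if `events` has an
#'   `amplitude` column.
#' @param hrf Response kernel (peak-normalized), e.g. [canonical_hrf()].
#' @param noise_sd Standard deviation of additive Gaussian noise (psc).
#' @param n_volumes Timeseries length; defaults to the `n_volumes`
#'   attribute of `events`.
#' @param area,hemisphere Optional labels attached to the result.
#' @param seed Integer seed for the noise draws.
#' @return A tibble of class `bold_timeseries` with `volume_index`
#'   (0-based) and `psc`, with attributes `tr_s`, `area`, `hemisphere`.
#' @export
simulate_bold_timeseries <- function(events, amplitudes = NULL,
                                     hrf = canonical_hrf(), noise_sd = 0,
                                     n_volumes = attr(events, "n_volumes"),
                                     area = NA_character_,
                                     hemisphere = NA_character_,
                                     seed = NULL) {
  if (is.null(n_volumes)) abort("`n_volumes` must be given or attached to events")
  k <- length(hrf)
  if (k > n_volumes) abort("kernel is longer than the timeseries")
  amp <- if ("amplitude" %in% names(events)) {
    events$amplitude
  } else {
    if (is.null(amplitudes)) abort("per-condition `amplitudes` required")
    if (anyNA(match(events$condition_id, seq_along(amplitudes) - 1L))) {
      abort("amplitudes missing for some conditions in the schedule")
    }
    amplitudes[events$condition_id + 1L]
  }
  if (any(events$onset_volume < 0 | events$onset_volume >= n_volumes)) {
    abort("event onsets must lie in [0, n_volumes)")
  }
  y <- numeric(n_volumes)
  for (i in seq_len(nrow(events))) {
    on <- events$onset_volume[i]
    len <- min(k, n_volumes - on)
    idx <- on + seq_len(len)
    y[idx] <- y[idx] + amp[i] * hrf[seq_len(len)]
  }
  if (noise_sd > 0) {
    y <- y + with_seed_if(seed, rnorm(n_volumes, 0, noise_sd))
  }
  out <- tibble(volume_index = seq_len(n_volumes) - 1L, psc = y)
  class(out) <- c("bold_timeseries", class(out))
  attr(out, "tr_s") <- attr(events, "tr_s") %||% 0.5
  attr(out, "area") <- area
  attr(out, "hemisphere") <- hemisphere
  out
}

#' Per-trial response amplitudes seen by one hemisphere
#'
#' Lateralized stimuli drive only contralateral retinotopic cortex: the
#' left hemisphere responds to the right-hemifield patch and vice versa.
#' Given trial stimuli, this returns the amplitude each trial evokes in an
#' area of the chosen hemisphere, evaluated through that area's population
#' response function at the contralateral patch's stimulus strengths.
#'
#' @param trials Trials tibble with `stim_*` columns.
#' @param p A [prf()] for the area.
#' @param hemisphere `"left"` or `"right"`.
#' @return Numeric vector of per-trial amplitudes (psc).
#' @export
hemifield_amplitudes <- function(trials, p, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  contra <- if (hemisphere == "left") "right" else "left"
  area_response(p,
                trials[[paste0("stim_con_", contra)]],
                trials[[paste0("stim_coh_", contra)]])
}

#' Expected per-condition amplitudes under a population response function
#'
#' @param p A [prf()].
#' @param cfg A [task_config()] defining the base grids.
#' @return A tibble `condition_id`, `condition`, `task`, `base_con`,
#'   `base_coh`, `amplitude` covering the full scan condition grid.
#' @export
condition_amplitude_table <- function(p, cfg = task_config()) {
  bases_con <- cfg$baseline_con + cfg$base_con_increments
  bases_coh <- cfg$baseline_coh + cfg$base_coh_increments
  grid <- tidyr::expand_grid(
    task = c("contrast", "coherence"),
    coh_idx = seq_along(bases_coh) - 1L,
    con_idx = seq_along(bases_con) - 1L
  ) |>
    dplyr::mutate(
      base_con = bases_con[.data$con_idx + 1L],
      base_coh = bases_coh[.data$coh_idx + 1L],
      condition_id = (as.integer(.data$task == "coherence") *
                        length(bases_coh) + .data$coh_idx) *
        length(bases_con) + .data$con_idx,
      condition = condition_label(.data$con_idx, .data$coh_idx, .data$task),
      amplitude = area_response(p, .data$base_con, .data$base_coh)
    ) |>
    dplyr::arrange(.data$condition_id) |>
    dplyr::select("condition_id", "condition", "task",
                  "base_con", "base_coh", "amplitude")
  grid
}
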