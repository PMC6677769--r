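#' Fit gain and offset changes of population response functions
#'
#' Given scalar response amplitudes on the (base contrast x base coherence
#' x task) grid, fits per-task contrast gain, coherence gain, and additive
#' task offset with the shape parameters (`sigma_con`, `kappa`) held at
#' their passive-viewing values so the response functions keep their
#' shape. With the shapes fixed, the model
#' `amplitude = alpha_con * g(s_con) + alpha_coh * h(s_coh) + alpha_task`
#' is linear in the three free parameters per task (six per area), so the
#' least-squares problem is solved exactly.
#'
#' @param amps Amplitude tibble with columns `base_con`, `base_coh`,
#'   `task`, `amplitude`.
#' @param init_prf A [prf()] supplying the fixed `sigma_con` and `kappa`
#'   (and the area label).
#' @return A list of class `prf_task_fit`: per-task [prf()] objects
#'   (`contrast`, `coherence`), the residual sum of squares `sse`, and a
#'   `params` tibble.
#' @export
fit_response_functions <- function(amps, init_prf) {
  stopifnot(inherits(init_prf, "prf"))
  need <- c("base_con", "base_coh", "task", "amplitude")
  stopifnot(all(need %in% names(amps)))
  fits <- lapply(c(contrast = "contrast", coherence = "coherence"), function(tk) {
    d <- amps[amps$task == tk, , drop = FALSE]
    cells <- nrow(dplyr::distinct(d[, c("base_con", "base_coh")]))
    if (cells < 3) {
      abort(sprintf("need at least 3 distinct (base_con, base_coh) cells for the %s task", tk))
    }
    g <- nr_shape(d$base_con, init_prf$sigma_con, init_prf$exp_num, init_prf$exp_den)
    h <- satexp_shape(d$base_coh, init_prf$kappa)
    fit <- lm(d$amplitude ~ g + h)
    co <- coef(fit)
    co[is.na(co)] <- 0
    list(prf = prf(init_prf$area,
                   alpha_con = unname(co["g"]), sigma_con = init_prf$sigma_con,
                   alpha_coh = unname(co["h"]), kappa = init_prf$kappa,
                   alpha_task = unname(co["(Intercept)"])),
         sse = sum(fit$residuals^2))
  })
  params <- purrr::map_dfr(names(fits), function(tk) {
    p <- fits[[tk]]$prf
    tibble(area = p$area, task = tk, alpha_con = p$alpha_con,
           alpha_coh = p$alpha_coh, alpha_task = p$alpha_task,
           sse = fits[[tk]]$sse)
  })
  structure(list(contrast = fits$contrast$prf, coherence = fits$coherence$prf,
                 sse = sum(params$sse), params = params),
            class = "prf_task_fit")
}

#' @export
print.prf_task_fit <- function(x, ...) {
  cat("<prf_task_fit>\n")
  print(x$params)
  invisible(x)
}

#' Chi-square check of condition-transition balance
#'
#' For a randomized schedule, every condition should be equally likely to
#' be followed by any condition. For each condition, tabulates the
#' condition of the following trial and tests the distribution against
#' uniform with a chi-square test.
#'
#' @param events Event tibble with `condition_id` (or a trials tibble with
#'   a `condition_id`-like column named via `cond_col`).
#' @param cond_col Column holding the condition labels.
#' @param min_transitions Rows with fewer following trials than this get
#'   `NA` p-values and are flagged.
#' @return Tibble `condition`, `n_following`, `p_value`, `flagged`.
#' @export
check_condition_balance <- function(events, cond_col = "condition_id",
                                    min_transitions = 5) {
  cond <- events[[cond_col]]
  if (length(unique(cond)) < 2) abort("need at least 2 conditions")
  lev <- sort(unique(cond))
  from <- cond[-length(cond)]
  to <- cond[-1]
  purrr::map_dfr(lev, function(cd) {
    follow <- to[from == cd]
    if (length(follow) < min_transitions) {
      return(tibble(condition = cd, n_following = length(follow),
                    p_value = NA_real_, flagged = TRUE))
    }
    counts <- table(factor(follow, levels = lev))
    p <- suppressWarnings(chisq.test(counts)$p.value)
    tibble(condition = cd, n_following = length(follow),
           p_value = p, flagged = FALSE)
  })
}

#' Bin staircase-valued stimuli back onto the base-strength grid
#'
#' The deconvolution analysis assigns each trial to the nearest base
#' strength (base + increment rounded to the grid; ties round down toward
#' the base) before condition assignment.
#'
#' @param x Stimulus strengths.
#' @param bases Base strength grid.
#' @return `x` rounded to the grid.
#' @export
bin_to_base_grid <- function(x, bases) round_to_base(x, bases)
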