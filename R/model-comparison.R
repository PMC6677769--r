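#' Stratified cross-validation folds
#'
#' Randomly partitions trials into folds, stratified by task and base
#' strength cell so every fold contains both tasks and all conditions.
#' Deterministic under a fixed seed.
#'
#' @param trials Trials tibble.
#' @param n_folds Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold assignments in `1:n_folds`.
#' @export
make_cv_folds <- function(trials, n_folds = 10, seed = 1) {
  stopifnot(n_folds >= 2)
  strata <- paste(trials$task, trials$base_con, trials$base_coh)
  fold <- integer(nrow(trials))
  with_seed_if(seed, {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Cross-validated log-likelihood of a choice model
#'
#' Fits the model on each training complement and evaluates the Bernoulli
#' log-likelihood of the held-out fold's choices; fold log-likelihoods sum
#' to the total. Also reports the cross-validated Tjur coefficient of
#' discrimination computed from the held-out predictions.
#'
#' @param trials Trials tibble (rows without a left/right choice are
#'   dropped).
#' @param fit_fn Function `trials -> fitted object`.
#' @param predict_fn Function `(fitted, trials) -> P(right)`; defaults to
#'   `predict()`.
#' @param n_folds Number of folds (default 10).
#' @param seed Seed controlling the fold partition.
#' @param model_label Label carried into the result.
#' @return A `model_comparison_result`: `fold_logliks`, `total_cv_loglik`,
#'   `cd`, `n_folds`, `fold_seed`, `n_trials`, `model_label`, and the
#'   held-out `predictions` tibble.
#' @export
crossval_loglik <- function(trials, fit_fn, predict_fn = NULL,
                            n_folds = 10, seed = 1, model_label = "model") {
  trials <- trials[trials$choice %in% c("left", "right"), , drop = FALSE]
  predict_fn <- predict_fn %||% function(obj, d) predict(obj, d)
  fold <- make_cv_folds(trials, n_folds, seed)
  n_min <- min(table(fold))
  if (n_min < 2) {
    abort(sprintf("fold %s has too few trials to fit",
                  names(which.min(table(fold)))))
  }
  preds <- rep(NA_real_, nrow(trials))
  fold_ll <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    test <- fold == f
    fitted <- tryCatch(
      fit_fn(trials[!test, , drop = FALSE]),
      error = function(e) abort(sprintf("fold %d failed to fit: %s", f,
                                        conditionMessage(e)))
    )
    p <- predict_fn(fitted, trials[test, , drop = FALSE])
    preds[test] <- p
    fold_ll[f] <- bernoulli_ll(p, as.numeric(trials$choice[test] == "right"))
  }
  structure(
    list(model_label = model_label, fold_logliks = fold_ll,
         total_cv_loglik = sum(fold_ll),
         cd = tjur_cd(preds, trials$choice),
         n_folds = n_folds, fold_seed = seed, n_trials = nrow(trials),
         predictions = tibble(fold = fold, p_right = preds,
                              choice = trials$choice)),
    class = "model_comparison_result"
  )
}

#' @export
print.model_comparison_result <- function(x, ...) {
  cat(sprintf("<model_comparison_result '%s'> CV loglik = %.2f nats (%d folds), CD = %.3f\n",
              x$model_label, x$total_cv_loglik, x$n_folds, x$cd))
  invisible(x)
}

#' Cross-validated log-likelihood ratio between two models
#'
#' The difference in total cross-validated log-likelihood,
#' `total(a) - total(b)` (nats): positive values favor `a`. A difference
#' above ~10 nats indicates a substantial improvement. Requires both
#' results to come from the same trials and fold partition.
#'
#' @param a,b `model_comparison_result` objects.
#' @return Log-likelihood ratio in nats.
#' @export
loglik_ratio <- function(a, b) {
  stopifnot(inherits(a, "model_comparison_result"),
            inherits(b, "model_comparison_result"))
  if (a$n_trials != b$n_trials || a$n_folds != b$n_folds ||
      a$fold_seed != b$fold_seed) {
    abort("results were computed on different trials or fold partitions")
  }
  a$total_cv_loglik - b$total_cv_loglik
}

#' Tjur's coefficient of discrimination
#'
#' The mean predicted probability of a rightward choice on trials where
#' the observer chose right, minus the mean on trials where the observer
#' chose left: `CD = mu_right - mu_left`. 1 for perfect prediction, 0 at
#' chance; interpretable like r2 for binary decisions.
#'
#' @param p_right Predicted probabilities of choosing right.
#' @param choices Character vector of `"left"` / `"right"` choices (or a
#'   logical vector of right choices).
#' @return CD in `[-1, 1]`.
#' @export
tjur_cd <- function(p_right, choices) {
  right <- if (is.logical(choices)) choices else choices == "right"
  keep <- !is.na(p_right) & (if (is.logical(choices)) TRUE
                             else choices %in% c("left", "right"))
  right <- right[keep]; p <- p_right[keep]
  if (!any(right) || all(right)) {
    abort("both choice classes must be present to compute Tjur's CD")
  }
  mean(p[right]) - mean(p[!right])
}

#' Compare a set of readout model variants by cross-validation
#'
#' Convenience wrapper: cross-validates each named model specification on
#' the same fold partition and tabulates totals, CDs, and the pairwise
#' log-likelihood ratio table.
#'
#' @param trials Trials tibble.
#' @param prfs [prf_set()] or per-task list.
#' @param specs Named list of specification lists passed to
#'   [fit_readout()] (fields `readout_mode`, `noise_mode`, `history`,
#'   `selection`).
#' @param lapse Fixed lapse rate.
#' @param n_folds,seed Cross-validation controls.
#' @param n_restarts Restarts per fold fit.
#' @return List with `results` (named `model_comparison_result`s),
#'   `summary` tibble, and `ratio_table` (matrix of row minus column
#'   total CV log-likelihoods).
#' @export
compare_readout_models <- function(trials, prfs, specs, lapse = 0,
                                   n_folds = 10, seed = 1, n_restarts = 3) {
  results <- purrr::imap(specs, function(sp, label) {
    fit_fn <- function(d) {
      fit_readout(d, prfs,
                  readout_mode = sp$readout_mode %||% "flexible",
                  noise_mode = sp$noise_mode %||% "additive",
                  history = isTRUE(sp$history),
                  selection = isTRUE(sp$selection),
                  lapse = lapse, n_restarts = n_restarts,
                  seed = stage_seed(seed, paste0("fit-", label)))
    }
    crossval_loglik(trials, fit_fn, n_folds = n_folds, seed = seed,
                    model_label = label)
  })
  totals <- vapply(results, `[[`, numeric(1), "total_cv_loglik")
  ratio <- outer(totals, totals, `-`)
  dimnames(ratio) <- list(names(results), names(results))
  list(
    results = results,
    summary = tibble(
      model = names(results),
      total_cv_loglik = unname(totals),
      cd = vapply(results, `[[`, numeric(1), "cd"),
      n_folds = n_folds
    ),
    ratio_table = ratio
  )
}
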