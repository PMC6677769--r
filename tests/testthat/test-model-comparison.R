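test_that("Tjur's CD matches hand computations and its invariances", {
  expect_equal(tjur_cd(c(1, 1, 0, 0), c("right", "right", "left", "left")), 1)
  expect_equal(tjur_cd(rep(0.5, 4), c("right", "right", "left", "left")), 0)
  # hand computation: mu_right = 0.7, mu_left = 0.25
  expect_equal(tjur_cd(c(0.8, 0.6, 0.3, 0.2), c("right", "right", "left", "left")),
               0.45)
  # invariant to trial order and dataset duplication
  p <- c(0.8, 0.6, 0.3, 0.2); ch <- c("right", "right", "left", "left")
  o <- sample(4)
  expect_equal(tjur_cd(p[o], ch[o]), tjur_cd(p, ch))
  expect_equal(tjur_cd(rep(p, 2), rep(ch, 2)), tjur_cd(p, ch))
  expect_error(tjur_cd(c(0.5, 0.6), c("right", "right")), "both")
})

test_that("a constant-0.5 model scores N log(1/2) for any fold count", {
  tr <- fx_trials(n_runs = 4, trials_per_run = 40, seed = 3)
  fit_const <- function(d) structure(list(), class = "const_model")
  pred_const <- function(obj, d) rep(0.5, nrow(d))
  for (k in c(2, 5)) {
    res <- crossval_loglik(tr, fit_const, pred_const, n_folds = k, seed = 1)
    expect_equal(res$total_cv_loglik, nrow(tr) * log(0.5), tolerance = 1e-12)
    expect_equal(sum(res$fold_logliks), res$total_cv_loglik)
  }
})

test_that("fold assignment is deterministic, stratified, and partitions exactly once", {
  tr <- fx_trials(n_runs = 10, trials_per_run = 50, seed = 17)
  f1 <- make_cv_folds(tr, 10, seed = 4)
  f2 <- make_cv_folds(tr, 10, seed = 4)
  expect_identical(f1, f2)
  expect_equal(sort(unique(f1)), 1:10)
  expect_equal(length(f1), nrow(tr))
  # each fold contains both tasks
  for (f in 1:10) {
    expect_setequal(unique(tr$task[f1 == f]), c("contrast", "coherence"))
  }
  expect_false(identical(f1, make_cv_folds(tr, 10, seed = 5)))
})

test_that("loglik_ratio is antisymmetric and guards against fold mismatch", {
  tr <- fx_trials(n_runs = 4, trials_per_run = 40, seed = 3)
  fit_const <- function(d) structure(list(), class = "const_model")
  pred_const <- function(obj, d) rep(0.5, nrow(d))
  pred_biased <- function(obj, d) rep(0.6, nrow(d))
  a <- crossval_loglik(tr, fit_const, pred_const, n_folds = 5, seed = 1)
  b <- crossval_loglik(tr, fit_const, pred_biased, n_folds = 5, seed = 1)
  expect_equal(loglik_ratio(a, a), 0)
  expect_equal(loglik_ratio(a, b), -loglik_ratio(b, a))
  b2 <- crossval_loglik(tr, fit_const, pred_biased, n_folds = 5, seed = 2)
  expect_error(loglik_ratio(a, b2), "fold")
})

test_that("nesting: fixed-readout training likelihood never beats flexible", {
  tr <- fx_trials(n_runs = 8, trials_per_run = 50, seed = 23,
                  catch_run_fraction = 0)
  prfs <- fx_prfs2()
  flex <- fit_readout(tr, prfs, "flexible", lapse = 0.03, n_restarts = 3, seed = 1)
  fixed <- fit_readout(tr, prfs, "fixed", lapse = 0.03, n_restarts = 3, seed = 1)
  expect_gte(flex$loglik, fixed$loglik - 1e-6)
})

test_that("cross-validation prefers the true flexible readout over fixed", {
  tr <- fx_trials(n_runs = 30, trials_per_run = 60, seed = 31,
                  catch_run_fraction = 0)
  cmp <- compare_readout_models(
    tr, fx_prfs2(),
    specs = list(flexible = list(readout_mode = "flexible"),
                 fixed = list(readout_mode = "fixed")),
    lapse = 0.03, n_folds = 5, seed = 2, n_restarts = 2)
  expect_gt(cmp$ratio_table["flexible", "fixed"], 10)
  expect_equal(cmp$ratio_table["flexible", "fixed"],
               -cmp$ratio_table["fixed", "flexible"])
  expect_gt(cmp$summary$cd[cmp$summary$model == "flexible"], 0.2)
})

test_that("extra stay/switch parameters do not help when the truth has no history", {
  ratios <- vapply(1:3, function(s) {
    tr <- fx_trials(n_runs = 16, trials_per_run = 50, seed = 100 + s,
                    catch_run_fraction = 0)
    cmp <- compare_readout_models(
      tr, fx_prfs2(),
      specs = list(base = list(readout_mode = "flexible"),
                   history = list(readout_mode = "flexible", history = TRUE)),
      lapse = 0.03, n_folds = 4, seed = s, n_restarts = 2)
    cmp$ratio_table["history", "base"]
  }, numeric(1))
  # no reliable advantage for the overparameterized model
  expect_lt(median(ratios), 2)
})
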