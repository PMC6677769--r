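test_that("choice probability has the right trivial limits", {
  truth <- fx_truth2(lapse = 0, beta_bias = 0)
  prfs <- fx_prfs2()
  expect_equal(choice_probability(truth, prfs, fx_trial_row()), 0.5)
  truth_l <- fx_truth2(lapse = 1)
  expect_equal(choice_probability(truth_l, prfs,
                                  fx_trial_row(con_r = 0.9, con_l = 0.3)), 0.5)
  # probabilities live in [lambda/2, 1 - lambda/2]
  truth2 <- fx_truth2(lapse = 0.1)
  tr <- fx_trial_row(con_r = 0.99, con_l = 0.3)
  p <- choice_probability(truth2, prfs, tr)
  expect_lte(p, 1 - 0.05 + 1e-12)
  expect_gte(p, 0.05 - 1e-12)
})

test_that("choice probability matches the Monte-Carlo decision-variable oracle", {
  prfs <- fx_prfs2()
  pts <- withr::with_seed(101, {
    purrr::map(1:8, function(i) {
      list(
        model = readout_model(
          c("V1", "MT"),
          weights = list(contrast = c(V1 = runif(1, -5, 15), MT = runif(1, -5, 5)),
                         coherence = c(V1 = runif(1, -5, 5), MT = runif(1, -5, 20))),
          beta_bias = runif(1, -1, 1), lapse = runif(1, 0, 0.2),
          noise_mode = sample(c("additive", "poisson"), 1),
          selection_rho = if (i %% 3 == 0) runif(1, 1, 2.5),
          history = if (i %% 4 == 0) {
            c(beta_left_correct = runif(1, -0.5, 0.5),
              beta_right_correct = runif(1, -0.5, 0.5),
              beta_left_incorrect = runif(1, -0.5, 0.5),
              beta_right_incorrect = runif(1, -0.5, 0.5))
          }),
        trial = fx_trial_row(
          task = sample(c("contrast", "coherence"), 1),
          con_l = runif(1, 0.25, 0.6), con_r = runif(1, 0.25, 0.6),
          coh_l = runif(1, 0, 0.5), coh_r = runif(1, 0, 0.5),
          prev_choice = sample(c("none", "left", "right"), 1),
          prev_correct = sample(c(TRUE, FALSE), 1))
      )
    })
  })
  withr::with_seed(202, {
    for (pt in pts) {
      p_impl <- choice_probability(pt$model, prfs, pt$trial)
      n_mc <- 2e5
      p_mc <- mc_choice_prob(pt$model, prfs, pt$trial, n_draws = n_mc)
      se <- sqrt(p_impl * (1 - p_impl) / n_mc) * (1 - pt$model$lapse)
      expect_lt(abs(p_impl - p_mc), 3 * se + 1e-4)
    }
  })
})

test_that("additive offsets cancel in additive mode but not under selection", {
  prfs <- fx_prfs2()
  prfs_off <- prf_set(lapply(unclass(prfs), function(p) {
    p$alpha_task <- 0.36; p
  }))
  tr <- fx_trial_row(con_l = 0.35, con_r = 0.5, coh_l = 0.1, coh_r = 0.3)
  m_add <- fx_truth2(lapse = 0)
  expect_equal(choice_probability(m_add, prfs, tr),
               choice_probability(m_add, prfs_off, tr), tolerance = 1e-12)
  m_sel <- m_add; m_sel$selection_rho <- 2
  expect_false(isTRUE(all.equal(choice_probability(m_sel, prfs, tr),
                                choice_probability(m_sel, prfs_off, tr))))
})

test_that("parameter counts match the model structure", {
  areas8 <- c("V1", "V2", "V3", "V4", "V3A", "V3B", "V7", "MT")
  w8 <- stats::setNames(rep(1, 8), areas8)
  flex8 <- readout_model(areas8, list(contrast = w8, coherence = w8))
  expect_equal(n_free_params(flex8), 17L)
  fixed8 <- readout_model(areas8, w8, readout_mode = "fixed")
  expect_equal(n_free_params(fixed8), 9L)
  flex2 <- fx_truth2()
  expect_equal(n_free_params(flex2), 5L)
  hist2 <- flex2
  hist2$history <- c(beta_left_correct = 0, beta_right_correct = 0,
                     beta_left_incorrect = 0, beta_right_incorrect = 0)
  expect_equal(n_free_params(hist2), 9L)
})

test_that("fit_readout recovers a two-area flexible truth", {
  truth <- fx_truth2(lapse = 0.03)
  tr <- fx_trials(n_runs = 40, trials_per_run = 100, seed = 55,
                  catch_run_fraction = 0)
  fit <- fit_readout(tr, fx_prfs2(), "flexible", lapse = 0.03,
                     n_restarts = 3, seed = 9)
  expect_true(fit$converged)
  est <- tidy(fit)
  truth_vals <- c(12, -2, -1, 18, 0.1)
  rel <- abs(est$estimate - truth_vals) / pmax(abs(truth_vals), 1)
  expect_lt(median(rel), 0.15)
  # the reported loglik equals the recomputed likelihood on the data
  expect_equal(fit$loglik, choice_loglik(fit$model, fx_prfs2(), tr),
               tolerance = 1e-8)
})

test_that("implied noise is the reciprocal weight magnitude", {
  m <- readout_model(c("V1", "MT"),
                     list(contrast = c(V1 = 1, MT = 0.5),
                          coherence = c(V1 = 0, MT = -2)))
  noise <- implied_noise(m)
  expect_equal(noise$sigma_implied[noise$task == "contrast" & noise$area == "V1"], 1)
  expect_equal(noise$sigma_implied[noise$task == "contrast" & noise$area == "MT"], 2)
  expect_equal(noise$sigma_implied[noise$task == "coherence" & noise$area == "V1"], Inf)
  expect_equal(noise$sign[noise$task == "coherence" & noise$area == "MT"], -1)
})

test_that("rescaling responses and weights together leaves choice probabilities unchanged", {
  prfs <- fx_prfs2()
  a <- 3.7
  prfs_scaled <- prf_set(lapply(unclass(prfs), function(p) {
    p$alpha_con <- p$alpha_con * a; p$alpha_coh <- p$alpha_coh * a; p
  }))
  m <- fx_truth2(lapse = 0.02)
  m_scaled <- m
  m_scaled$weights <- lapply(m$weights, function(w) w / a)
  tr <- fx_trial_row(con_l = 0.3, con_r = 0.55, coh_l = 0.1, coh_r = 0.4)
  expect_equal(choice_probability(m, prfs, tr),
               choice_probability(m_scaled, prfs_scaled, tr), tolerance = 1e-12)
})

test_that("predicted JND matches closed forms and the grid-search oracle", {
  # single linear coherence channel with weighted slope 2: JND = 0.5
  lin <- prf_set(prf("MT", alpha_con = 0, sigma_con = 0.5,
                     alpha_coh = 2000, kappa = 1000))
  m <- readout_model("MT", list(contrast = c(MT = 1), coherence = c(MT = 1)))
  j <- predict_jnd(m, lin, "coherence", c(contrast = 0, coherence = 0))
  expect_equal(as.numeric(j), 0.5, tolerance = 1e-3)

  truth <- fx_truth2()
  prfs <- fx_prfs2()
  for (base in list(c(contrast = 0.325, coherence = 0.15),
                    c(contrast = 0.55, coherence = 0.45))) {
    for (tk in c("contrast", "coherence")) {
      j <- predict_jnd(truth, prfs, tk, base)
      g <- grid_jnd(truth, prfs, tk, base)
      # the grid oracle overshoots by at most one 1e-5 step
      expect_lt(abs(as.numeric(j) - g), 1e-4)
    }
  }
})

test_that("simulated 2AFC accuracy at base + JND is about 76% correct", {
  truth <- fx_truth2(lapse = 0, beta_bias = 0)
  prfs <- fx_prfs2()
  base <- c(contrast = 0.4, coherence = 0.15)
  # the ~76%-correct criterion corresponds to a readout difference of
  # 1/sqrt(2) noise SDs under the probit link
  j <- predict_jnd(truth, prfs, "contrast", base, target = 1 / sqrt(2))
  n <- 20000
  tr <- fx_trial_row(con_l = base[["contrast"]],
                     con_r = base[["contrast"]] + as.numeric(j),
                     coh_l = base[["coherence"]], coh_r = base[["coherence"]])
  p <- choice_probability(truth, prfs, tr)
  sim <- withr::with_seed(6, mean(runif(n) < p))
  expect_lt(abs(sim - pnorm(1 / sqrt(2))), 0.02)
})

test_that("catch-trial JND predictions: wrong readout and memory cost", {
  truth <- fx_truth2()
  prfs <- fx_prfs2()
  base <- c(contrast = 0.55, coherence = 0.40)
  # memory cost of 1 reduces to the ordinary prediction
  j1 <- predict_catch_jnd(truth, prfs, "contrast", base, mode = "memory_cost",
                          memory_cost = 1)
  expect_equal(as.numeric(j1), as.numeric(predict_jnd(truth, prfs, "contrast", base)))
  # a linear channel doubles its JND under a cost of 2
  lin <- prf_set(prf("MT", 0, 0.5, 2000, 1000))
  m <- readout_model("MT", list(contrast = c(MT = 4), coherence = c(MT = 4)))
  j_cost <- predict_catch_jnd(m, lin, "coherence", c(contrast = 0, coherence = 0),
                              mode = "memory_cost", memory_cost = 2)
  j_base <- predict_jnd(m, lin, "coherence", c(contrast = 0, coherence = 0))
  expect_equal(as.numeric(j_cost), 2 * as.numeric(j_base), tolerance = 1e-3)
  # a readout orthogonal to the probed feature makes the task impossible
  m_orth <- readout_model(
    c("V1", "MT"),
    weights = list(contrast = c(V1 = 12, MT = -2),
                   coherence = c(V1 = 0, MT = 0)))
  j_imp <- predict_catch_jnd(m_orth, prfs, "contrast", base,
                             mode = "wrong_readout")
  expect_true(is.na(j_imp))
  expect_false(attr(j_imp, "measurable"))
})

test_that("Poisson noise flattens psychometric performance at high base strengths", {
  prfs <- fx_prfs2()
  add <- fx_truth2(lapse = 0, beta_bias = 0)
  poi <- fx_truth2(lapse = 0, beta_bias = 0, noise_mode = "poisson")
  lo <- c(contrast = 0.325, coherence = 0.15)
  hi <- c(contrast = 0.85, coherence = 0.15)
  j_add_lo <- as.numeric(predict_jnd(add, prfs, "contrast", lo))
  j_add_hi <- as.numeric(predict_jnd(add, prfs, "contrast", hi))
  j_poi_lo <- as.numeric(predict_jnd(poi, prfs, "contrast", lo))
  j_poi_hi <- as.numeric(predict_jnd(poi, prfs, "contrast", hi))
  # both worsen with base strength, but Poisson noise on a saturating
  # response function worsens disproportionately
  expect_gt(j_poi_hi / j_poi_lo, j_add_hi / j_add_lo)
})

test_that("readout models round-trip through JSON", {
  tmp <- withr::local_tempfile(fileext = ".json")
  m <- fx_truth2()
  m$history <- c(beta_left_correct = 0.1, beta_right_correct = -0.2,
                 beta_left_incorrect = 0.05, beta_right_incorrect = 0)
  write_readout_model(m, tmp)
  back <- read_readout_model(tmp)
  expect_equal(back$weights, m$weights, tolerance = 0)
  expect_equal(back$history, m$history, tolerance = 0)
  expect_equal(back$memory_cost, m$memory_cost)
})
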