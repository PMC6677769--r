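sim_cumnormal_trials <- function(n, mu, sigma, lambda, seed, base = 0.4) {
  withr::with_seed(seed, {
    x <- runif(n, -0.2, 0.2)
    p <- lambda / 2 + (1 - lambda) * pnorm((x - mu) / sigma)
    tibble::tibble(
      task = "contrast",
      stim_con_left = base - pmin(x, 0), stim_con_right = base + pmax(x, 0),
      stim_coh_left = 0.15, stim_coh_right = 0.15,
      choice = ifelse(runif(n) < p, "right", "left")
    )
  })
}

test_that("cumulative-normal fits recover parameters and are symmetric at mu = 0", {
  d <- sim_cumnormal_trials(20000, mu = 0.02, sigma = 0.05, lambda = 0.04,
                            seed = 31)
  fit <- fit_cum_normal(d)
  expect_equal(fit$mu, 0.02, tolerance = 0.1)
  expect_equal(fit$sigma, 0.05, tolerance = 0.1)
  expect_equal(fit$lambda, 0.04, tolerance = 0.5)
  expect_gt(fit$r2_pseudo, 0.3)
  expect_true(all(abs(tidy(fit)$estimate - c(fit$mu, fit$sigma, fit$lambda)) == 0))

  d0 <- sim_cumnormal_trials(4000, mu = 0, sigma = 0.05, lambda = 0, seed = 32)
  fit0 <- fit_cum_normal(d0)
  se_mu <- fit0$sigma / sqrt(nrow(d0))
  expect_lt(abs(fit0$mu), max(4 * se_mu, 0.005))
})

test_that("pseudo-r2 is zero when the model matches the intercept-only model", {
  # stimulus-independent choices: the best psychometric fit collapses to
  # the null and the likelihood ratio term is ~1
  d <- withr::with_seed(5, {
    tibble::tibble(task = "contrast",
                   stim_con_left = 0.4, stim_con_right = 0.4,
                   stim_coh_left = 0.15, stim_coh_right = 0.15,
                   choice = sample(c("left", "right"), 2000, replace = TRUE))
  })
  d$stim_con_right <- d$stim_con_right + rep(c(-0.01, 0.01), 1000)
  fit <- fit_cum_normal(d)
  expect_equal(fit$r2_pseudo, 0, tolerance = 0.02)
})

test_that("the Weibull curve passes its definitional points and the JND is ~76%", {
  # at x = tau the curve reaches gamma + (1-gamma-lambda)(1 - 1/e)
  expect_equal(weibull_pc(0.08, tau = 0.08, beta = 3, gamma = 0.5, lambda = 0),
               0.5 + 0.5 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(0.5 + 0.5 * (1 - exp(-1)), 0.816, tolerance = 1e-3)
  # the JND inversion hits the d' = 1 percent-correct criterion exactly
  for (lam in c(0, 0.01, 0.02)) {
    j <- weibull_jnd(0.08, 3, 0.5, lam)
    pc <- weibull_pc(j, 0.08, 3, 0.5, lam)
    expect_equal(pc, pnorm(1 / sqrt(2)), tolerance = 1e-10)
    expect_true(pc >= 0.75 && pc <= 0.77)
  }
})

test_that("Weibull threshold recovery from simulated outcomes", {
  sim <- function(seed, n = 10000, tau = 0.08, beta = 3) {
    withr::with_seed(seed, {
      x <- runif(n, 0.005, 0.3)
      correct <- runif(n) < weibull_pc(x, tau, beta)
      fit_weibull(x, correct, lambda = 0, seed = seed)
    })
  }
  fit <- sim(41)
  expect_equal(fit$tau, 0.08, tolerance = 0.05)
  # median relative error across seeds stays below 10% at n = 2000
  errs <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      x <- runif(2000, 0.005, 0.3)
      correct <- runif(2000) < weibull_pc(x, 0.08, 3)
      abs(fit_weibull(x, correct, lambda = 0, seed = s)$tau - 0.08) / 0.08
    })
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("likelihoods are proper and worsen when parameters are clamped off the MLE", {
  withr::with_seed(11, {
    x <- runif(2000, 0.005, 0.3)
    correct <- runif(2000) < weibull_pc(x, 0.08, 3)
  })
  fit <- fit_weibull(x, correct, lambda = 0)
  expect_lt(fit$loglik, 0)
  clamped <- -sum(log(ifelse(correct,
                             weibull_pc(x, fit$tau * 2, fit$beta_slope),
                             1 - weibull_pc(x, fit$tau * 2, fit$beta_slope))))
  expect_gt(clamped, -fit$loglik)
})

test_that("a full session yields the 12-fit threshold table", {
  tr <- fx_trials(n_runs = 30, trials_per_run = 60, seed = 77, staircase = TRUE)
  wt <- weibull_fit_table(tr, lambda = 0.03)
  expect_equal(nrow(wt), 12L)
  expect_equal(sum(wt$condition == "regular"), 8L)
  expect_equal(sum(wt$condition == "catch_control"), 2L)
  expect_equal(sum(wt$condition == "catch"), 2L)
  # catch fits are grouped by the reported (post-cued) feature
  expect_setequal(wt$task[wt$condition == "catch"], c("contrast", "coherence"))
})

test_that("lapse estimation doubles the suprathreshold error rate", {
  # observer limited only by lapses: suprathreshold accuracy is 1 - lambda/2
  lam <- 0.06
  tr <- withr::with_seed(13, {
    n <- 6000
    tibble::tibble(
      task = "contrast", is_catch = FALSE,
      delta_con = 0.2, delta_coh = 0,
      choice = "right",
      correct = runif(n) > lam / 2
    )
  })
  est <- estimate_lapse(tr)
  expect_equal(est$lambda, lam, tolerance = 3 * sqrt(lam / 2 / 6000) * 2 / lam)
  expect_equal(est$error_rate * 2, est$lambda)
  # no errors above threshold gives zero
  tr$correct <- TRUE
  expect_equal(estimate_lapse(tr)$lambda, 0)
  expect_error(estimate_lapse(dplyr::mutate(tr, delta_con = 0.01)),
               "undefined")
})

test_that("weber_slope is the closed-form least-squares slope", {
  # proportional JNDs: slope exactly 1; constant JNDs: slope exactly 0
  j1 <- tibble::tibble(base_strength = c(0.1, 0.2, 0.4, 0.8),
                       jnd = 0.1 * c(0.1, 0.2, 0.4, 0.8), measurable = TRUE)
  expect_equal(as.numeric(weber_slope(j1)), 1, tolerance = 1e-12)
  j0 <- dplyr::mutate(j1, jnd = 0.05)
  expect_equal(as.numeric(weber_slope(j0)), 0, tolerance = 1e-12)
  # group-mean contrast JNDs on the printed base grid
  jg <- tibble::tibble(base_strength = c(32.5, 40, 55, 85),
                       jnd = c(4.6, 4.8, 5.5, 7.5), measurable = TRUE)
  x <- log(jg$base_strength); y <- log(jg$jnd)
  closed_form <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(as.numeric(weber_slope(jg)), closed_form, tolerance = 1e-12)
  expect_equal(closed_form, 0.517, tolerance = 1e-2)
  # non-measurable JNDs are excluded with a warning
  jm <- dplyr::mutate(j1, measurable = c(TRUE, TRUE, TRUE, FALSE))
  expect_warning(weber_slope(jm), "non-measurable")
  expect_error(suppressWarnings(
    weber_slope(dplyr::mutate(j1, measurable = FALSE))), "distinct")
})

test_that("catch cost is the threshold ratio and is unit invariant", {
  expect_equal(catch_cost(1, 1), 1)
  expect_equal(catch_cost(15.9, 5.3), 3.0)
  expect_equal(catch_cost(0.159, 0.053), catch_cost(15.9, 5.3))
  expect_error(catch_cost(NA, 5.3), "undefined")
  expect_error(catch_cost(Inf, 5.3), "undefined")
})
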