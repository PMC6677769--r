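test_that("FIR design blocks are shifted unit indicators (Toeplitz construction)", {
  ev <- tibble::tibble(onset_volume = 0L, condition_id = 0L)
  d <- build_fir_design(ev, k = 3, c = 1, n = 5)
  X <- as.matrix(d$matrix)
  expect_equal(X, cbind(c(1, 0, 0, 0, 0), c(0, 1, 0, 0, 0), c(0, 0, 1, 0, 0)))
  # truncation at the end, no wraparound
  ev2 <- tibble::tibble(onset_volume = 3L, condition_id = 0L)
  X2 <- as.matrix(build_fir_design(ev2, k = 3, c = 1, n = 5)$matrix)
  expect_equal(colSums(X2), c(1, 1, 0))
  expect_error(build_fir_design(tibble::tibble(onset_volume = 9L,
                                               condition_id = 0L),
                                k = 3, c = 1, n = 5), "onsets")
})

test_that("the full scan grid gives 2592 design columns (81 lags x 32 conditions)", {
  cfg <- task_config(mode = "scan", trials_per_run = 40, n_runs = 2)
  sc <- generate_task_schedule(cfg, seed = 1)
  d <- build_fir_design(sc$events, k = 81, c = 32)
  expect_equal(ncol(d$matrix), 2592L)
  expect_equal(d$k * d$c, 2592L)
})

test_that("randomized schedules give full-rank designs with a clean Gram matrix", {
  cfg <- task_config(base_con_increments = c(0.15, 0.30),
                     base_coh_increments = c(0.15, 0.30),
                     mode = "scan", trials_per_run = 100, n_runs = 2)
  sc <- generate_task_schedule(cfg, seed = 12)
  d <- build_fir_design(sc$events, k = 25)
  dec <- deconvolve(rnorm(d$n), d)
  expect_equal(dec$design_rank, ncol(d$matrix))
  expect_false(dec$offdiag_flag)
})

test_that("zero-noise simulated BOLD is inverted exactly by deconvolution", {
  cfg <- task_config(base_con_increments = c(0.15, 0.60),
                     base_coh_increments = c(0.15, 0.60),
                     mode = "scan", trials_per_run = 60, n_runs = 2)
  sc <- generate_task_schedule(cfg, seed = 7)
  hrf <- canonical_hrf(duration_s = 20)
  amps <- seq(0.4, 1.8, length.out = 8)
  y <- simulate_bold_timeseries(sc$events, amplitudes = amps, hrf = hrf)
  d <- build_fir_design(sc$events, k = length(hrf))
  dec <- deconvolve(y, d)
  # recovered responses equal the injected scaled kernels
  for (cid in unique(sc$events$condition_id)) {
    fir <- dec$fir_responses$response[dec$fir_responses$condition_id == cid]
    expect_equal(fir, amps[cid + 1] * hrf, tolerance = 1e-8)
  }
  expect_lt(dec$residual_variance, 1e-16)
  # amplitude reduction then recovers the amplitudes exactly
  at <- amplitude_table(dec, hrf)
  expect_equal(at$amplitude, amps[at$condition_id + 1], tolerance = 1e-8)
})

test_that("two overlapping events sum sample-wise (brute-force convolution)", {
  hrf <- canonical_hrf(duration_s = 10)
  ev <- tibble::tibble(onset_volume = c(2L, 6L), condition_id = c(0L, 1L))
  y <- simulate_bold_timeseries(ev, amplitudes = c(1.0, 2.5), hrf = hrf,
                                n_volumes = 40)
  manual <- numeric(40)
  manual[2 + seq_along(hrf)] <- hrf
  manual[6 + seq_along(hrf)] <- manual[6 + seq_along(hrf)] + 2.5 * hrf
  expect_equal(y$psc, manual)
  # single event, amplitude one, zero noise: the shifted kernel itself
  y1 <- simulate_bold_timeseries(ev[1, ], amplitudes = 1, hrf = hrf,
                                 n_volumes = 40)
  shifted <- numeric(40); shifted[2 + seq_along(hrf)] <- hrf
  expect_equal(y1$psc, shifted)
  expect_error(simulate_bold_timeseries(ev, amplitudes = c(1, 1), hrf = hrf,
                                        n_volumes = 5), "longer")
})

test_that("noise-only timeseries yield FIR responses with mean near zero", {
  cfg <- task_config(base_con_increments = c(0.15, 0.60),
                     base_coh_increments = 0.30,
                     mode = "scan", trials_per_run = 60, n_runs = 2)
  sc <- generate_task_schedule(cfg, seed = 3)
  d <- build_fir_design(sc$events, k = 21)
  sd_noise <- 0.5
  resp <- withr::with_seed(99, {
    replicate(30, {
      dec <- deconvolve(rnorm(d$n, 0, sd_noise), d)
      mean(dec$fir_responses$response)
    })
  })
  se <- sd(resp) / sqrt(length(resp))
  expect_lt(abs(mean(resp)), 3 * se + 1e-3)
})

test_that("fit_hrf_amplitude is the exact least-squares scalar and is linear", {
  hrf <- canonical_hrf(duration_s = 15)
  expect_equal(fit_hrf_amplitude(2.0 * hrf, hrf), 2.0, tolerance = 1e-12)
  # orthogonal response gives zero
  orth <- rep(c(1, -1), length.out = length(hrf))
  orth <- orth - hrf * sum(orth * hrf) / sum(hrf^2)
  expect_equal(fit_hrf_amplitude(orth, hrf), 0, tolerance = 1e-12)
  # linearity
  fir <- 1.3 * hrf + 0.2
  expect_equal(fit_hrf_amplitude(3 * fir, hrf), 3 * fit_hrf_amplitude(fir, hrf))
  expect_error(fit_hrf_amplitude(hrf, rep(0, length(hrf))), "zero")
  # noisy recovery: unbiased around the true scale
  amps <- withr::with_seed(4, {
    replicate(100, fit_hrf_amplitude(1.5 * hrf + rnorm(length(hrf), 0, 0.1), hrf))
  })
  expect_lt(abs(mean(amps) - 1.5), 3 * sd(amps) / sqrt(100))
})

test_that("response-function refits recover generating parameters exactly without noise", {
  p0 <- passive_prf_set("V1")$V1
  cfg <- task_config()
  # noiseless amplitudes from known gains and offsets, different per task
  truth <- list(contrast = c(a_con = 1.68, a_coh = 0.25, a_task = 0.36),
                coherence = c(a_con = 1.55, a_coh = 0.30, a_task = 0.29))
  at <- condition_amplitude_table(p0, cfg)
  at$amplitude <- purrr::map_dbl(seq_len(nrow(at)), function(i) {
    tp <- truth[[at$task[i]]]
    tp["a_con"] * at$base_con[i]^1.9 / (at$base_con[i]^1.6 + p0$sigma_con^1.6) +
      tp["a_coh"] * (1 - exp(-at$base_coh[i] / p0$kappa)) + tp["a_task"]
  })
  fit <- fit_response_functions(at, p0)
  expect_equal(fit$contrast$alpha_con, 1.68, tolerance = 1e-6)
  expect_equal(fit$contrast$alpha_coh, 0.25, tolerance = 1e-6)
  expect_equal(fit$contrast$alpha_task, 0.36, tolerance = 1e-6)
  expect_equal(fit$coherence$alpha_task, 0.29, tolerance = 1e-6)
  expect_lt(fit$sse, 1e-12)
  # six free parameters in total: 3 per task condition
  expect_equal(nrow(fit$params) * 3, 6)

  # constant amplitudes: gains vanish, the offset absorbs the constant
  at$amplitude <- 0.7
  fit2 <- fit_response_functions(at, p0)
  expect_equal(fit2$contrast$alpha_con, 0, tolerance = 1e-9)
  expect_equal(fit2$contrast$alpha_coh, 0, tolerance = 1e-9)
  expect_equal(fit2$contrast$alpha_task, 0.7, tolerance = 1e-9)
})

test_that("hemisphere amplitude maps are driven by the contralateral patch", {
  p <- passive_prf_set("V1")$V1
  tr <- fx_trial_row(con_l = 0.3, con_r = 0.8, coh_l = 0.1, coh_r = 0.6)
  left <- hemifield_amplitudes(tr, p, "left")
  right <- hemifield_amplitudes(tr, p, "right")
  expect_equal(left, area_response(p, 0.8, 0.6))
  expect_equal(right, area_response(p, 0.3, 0.1))
  expect_false(isTRUE(all.equal(left, right)))
})

test_that("staircased strengths bin to the nearest base with ties rounding down", {
  bases <- c(0.325, 0.40, 0.55, 0.85)
  # 0.70 is exactly midway between 0.55 and 0.85: ties go to the lower base
  expect_equal(bin_to_base_grid(c(0.33, 0.42, 0.70, 0.99), bases),
               c(0.325, 0.40, 0.55, 0.85))
})
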