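test_that("latent pattern banks realize the requested shared fraction", {
  null_bank <- make_latent_patterns(20, 20, 2000, shared_frac = 0, seed = 3)
  r0 <- cor(t(null_bank$patterns_L1), t(null_bank$patterns_L2))
  expect_lt(abs(mean(r0)), 0.03)   # 400 independent pairs

  bank <- make_latent_patterns(20, 20, 5000, shared_frac = 0.5, seed = 4)
  r5 <- cor(t(bank$patterns_L1), t(bank$patterns_L2))
  expect_lt(abs(mean(r5) - 0.5), 0.03)

  hi <- make_latent_patterns(10, 10, 2000, shared_frac = 0.9, seed = 5)
  lo <- make_latent_patterns(10, 10, 2000, shared_frac = 0.1, seed = 5)
  expect_gt(mean(cor(t(hi$patterns_L1), t(hi$patterns_L2))),
            mean(cor(t(lo$patterns_L1), t(lo$patterns_L2))))

  # rows have unit variance in expectation
  expect_lt(abs(mean(apply(bank$patterns_L1, 1, var)) - 1), 0.1)
  expect_error(make_latent_patterns(5, 5, 100, shared_frac = 1), "\\[0, 1\\)")
  expect_error(make_latent_patterns(5, 5, 1, shared_frac = 0.5), ">= 2")
})

test_that("the noiseless forward model is the HRF-convolved boxcar", {
  sched <- event_schedule(1, data.frame(onset = 4, duration = 3,
                                        condition = "CW", item_id = 1), 60)
  bank <- make_latent_patterns(1, 1, 2, 0, seed = 1)
  bank$patterns_L1[1, ] <- c(1, 2)   # known amplitudes
  hrf <- double_gamma_hrf()
  run <- simulate_bold_run(sched, bank, hrf = hrf, tr_s = 2,
                           noise_model = list(sd = 0, ar1_coef = 0,
                                              drift_slope = 0))
  oracle <- convolved_regressor_naive(4, 3, hrf, 2, 30)
  expect_equal(unname(run$data[1, ]), oracle, tolerance = 1e-12)
  expect_equal(unname(run$data[2, ]), 2 * oracle, tolerance = 1e-12)
  expect_gt(max(run$data[1, ]), 0)
})

test_that("the forward model is linear in events", {
  base <- data.frame(onset = c(4, 40), duration = 3, condition = "CW",
                     item_id = 1:2)
  bank <- make_latent_patterns(2, 2, 3, 0.2, seed = 2)
  noise0 <- list(sd = 0, ar1_coef = 0, drift_slope = 0)
  both <- simulate_bold_run(event_schedule(1, base, 80), bank, noise_model = noise0)
  one <- simulate_bold_run(event_schedule(1, base[1, ], 80), bank, noise_model = noise0)
  two <- simulate_bold_run(event_schedule(1, base[2, ], 80), bank, noise_model = noise0)
  expect_equal(both$data, one$data + two$data, tolerance = 1e-12)
})

test_that("AR(1) noise has the requested lag-1 autocorrelation", {
  # an unmodeled condition evokes no signal, leaving pure noise
  sched <- event_schedule(1, data.frame(onset = 1, duration = 1,
                                        condition = "EW", item_id = 1),
                          20000)
  bank <- make_latent_patterns(1, 1, 2, 0, seed = 1)
  run <- simulate_bold_run(sched, bank, tr_s = 2,
                           noise_model = list(sd = 1, ar1_coef = 0.3,
                                              drift_slope = 0), seed = 6)
  x <- run$data[1, ]
  expect_equal(length(x), 10000)
  lag1 <- cor(x[-1], x[-length(x)])
  expect_lt(abs(lag1 - 0.3), 0.05)
  expect_lt(abs(sd(x) - 1), 0.05)  # marginal, not innovation, sd
})

test_that("events without a pattern row are rejected", {
  sched <- event_schedule(1, data.frame(onset = 4, duration = 3,
                                        condition = "CW", item_id = 7), 60)
  bank <- make_latent_patterns(2, 2, 3, 0, seed = 1)
  expect_error(simulate_bold_run(sched, bank), "no pattern row")
})

test_that("learning series follow the power law exactly without noise", {
  s <- simulate_learning_series(2000, 0.5, 9, noise_sd_ms = 0, floor_ms = 1,
                                seed = 1)
  expect_equal(s$rt_ms, 2000 * (1:9)^(-0.5), tolerance = 1e-12)
  expect_equal(s$rt_ms[2], 2000 / sqrt(2))
  flat <- simulate_learning_series(1800, 0, 9, noise_sd_ms = 0, seed = 1)
  expect_equal(flat$rt_ms, rep(1800, 9))
  expect_true(all(s$accuracy >= 0 & s$accuracy <= 1))
  expect_true(all(diff(simulate_learning_series(2000, 0.3, 12,
                                                noise_sd_ms = 0,
                                                seed = 2)$accuracy) >= -0.1))
  expect_error(simulate_learning_series(-5, 0.3), "positive")
  expect_error(simulate_learning_series(2000, 0.3, n_sessions = 2), ">= 3")
})

test_that("noisy learning series are unbiased at session one", {
  first <- vapply(1:200, function(i) {
    simulate_learning_series(2000, 0.3, 9, noise_sd_ms = 50, floor_ms = 100,
                             seed = i)$rt_ms[1]
  }, numeric(1))
  expect_lt(abs(mean(first) - 2000), 10)
})

test_that("cohort truth realizes the requested brain-behavior link", {
  co0 <- simulate_cohort(1000, link_strength = 0, seed = 21, imaging = FALSE)
  expect_lt(abs(cor(co0$truth$true_shared_frac, co0$truth$true_b)), 0.07)
  co6 <- simulate_cohort(1000, link_strength = 0.6, seed = 22, imaging = FALSE)
  expect_lt(abs(cor(co6$truth$true_shared_frac, co6$truth$true_b) - 0.6), 0.07)
  expect_error(simulate_cohort(10, link_strength = 1.5), "\\[-1, 1\\]")
  expect_error(simulate_cohort(3), ">= 4")
})

test_that("cohorts are bitwise reproducible from their seed", {
  d <- cohort_design(n_runs = 2L, n_items = 3L, n_voxels_roi = 6L)
  a <- simulate_cohort(4, design = d, seed = 17)
  b <- simulate_cohort(4, design = d, seed = 17)
  expect_identical(a$truth, b$truth)
  expect_identical(a$subjects[[1]]$runs[[1]]$data,
                   b$subjects[[1]]$runs[[1]]$data)
  expect_identical(a$subjects[[2]]$behavior, b$subjects[[2]]$behavior)
  c <- simulate_cohort(4, design = d, seed = 18)
  expect_false(identical(a$subjects[[1]]$runs[[1]]$data,
                         c$subjects[[1]]$runs[[1]]$data))
})
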