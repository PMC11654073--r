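noise_off <- list(sd = 0, ar1_coef = 0, drift_slope = 0)

test_that("noiseless runs are recovered to numerical precision", {
  sched <- generate_schedule_exp1(n_runs = 1, n_trials_per_run = 8, seed = 3)[[1]]
  bank <- make_latent_patterns(8, 8, 40, 0.3, seed = 4)
  run <- simulate_bold_run(sched, bank, noise_model = noise_off)
  X <- build_design_matrix(sched, 2, ncol(run$data))
  betas <- fit_glm(run, X)
  ord <- order(betas$items$item_id)
  scale <- max(abs(bank$patterns_L1))
  expect_lt(max(abs(betas$betas[ord, ] - bank$patterns_L1)) / scale, 1e-6)
})

test_that("a linear drift with a drift nuisance column leaves recovery exact", {
  sched <- generate_schedule_exp1(n_runs = 1, n_trials_per_run = 5, seed = 5)[[1]]
  bank <- make_latent_patterns(5, 5, 10, 0.3, seed = 6)
  run <- simulate_bold_run(sched, bank,
                           noise_model = list(sd = 0, ar1_coef = 0,
                                              drift_slope = 0.4))
  n_tp <- ncol(run$data)
  X <- build_design_matrix(sched, 2, n_tp,
                           nuisance = matrix(seq_len(n_tp), ncol = 1))
  betas <- fit_glm(run, X)
  ord <- order(betas$items$item_id)
  scale <- max(abs(bank$patterns_L1))
  expect_lt(max(abs(betas$betas[ord, ] - bank$patterns_L1)) / scale, 1e-6)
})

test_that("OLS betas are unbiased under observation noise", {
  sched <- generate_schedule_exp1(n_runs = 1, n_trials_per_run = 4, seed = 7)[[1]]
  bank <- make_latent_patterns(4, 4, 6, 0.3, seed = 8)
  X <- build_design_matrix(sched, 2, ceiling(sched$total_duration_s / 2))
  errs <- vapply(1:200, function(i) {
    run <- simulate_bold_run(sched, bank,
                             noise_model = list(sd = 1, ar1_coef = 0,
                                                drift_slope = 0), seed = i)
    betas <- fit_glm(run, X)
    mean(betas$betas[order(betas$items$item_id), ] - bank$patterns_L1)
  }, numeric(1))
  expect_lt(abs(mean(errs)), 3 * sd(errs) / sqrt(length(errs)))
})

test_that("rank-deficient designs fail naming the collinear columns", {
  sched <- generate_schedule_exp1(n_runs = 1, n_trials_per_run = 3, seed = 9)[[1]]
  bank <- make_latent_patterns(3, 3, 4, 0, seed = 1)
  run <- simulate_bold_run(sched, bank, noise_model = noise_off)
  n_tp <- ncol(run$data)
  dup <- matrix(rep(sin(seq_len(n_tp)), 2), ncol = 2,
                dimnames = list(NULL, c("dup_a", "dup_b")))
  X <- build_design_matrix(sched, 2, n_tp, nuisance = dup)
  expect_error(fit_glm(run, X), "rank deficient.*dup")
})

test_that("filtering both sides equals augmenting the design with the drift basis", {
  sched <- generate_schedule_exp1(n_runs = 1, n_trials_per_run = 5, seed = 11)[[1]]
  bank <- make_latent_patterns(5, 5, 8, 0.4, seed = 12)
  run <- simulate_bold_run(sched, bank,
                           noise_model = list(sd = 0.8, ar1_coef = 0.3,
                                              drift_slope = 0.2), seed = 13)
  n_tp <- ncol(run$data)
  X <- build_design_matrix(sched, 2, n_tp)
  filtered <- fit_glm(run, X, highpass_s = 100)

  # Frisch-Waugh oracle: task columns plus the same drift basis, plain OLS
  B <- pslearn:::dct_drift_basis(n_tp, 2, 100)
  task <- X$matrix[, X$of_interest, drop = FALSE]
  coefs <- qr.coef(qr(cbind(task, B)), t(run$data))
  expect_equal(unname(filtered$betas),
               unname(coefs[seq_len(ncol(task)), , drop = FALSE]),
               tolerance = 1e-8)
})

test_that("averaging across runs is an element-wise mean over matched items", {
  items <- data.frame(label = c("CW:1", "CW:2"), condition = "CW", item_id = 1:2)
  mk <- function(vals) {
    structure(list(betas = matrix(vals, 2, 3), items = items,
                   run_index = 1L, condition = "CW"),
              class = "item_beta_set")
  }
  same <- average_across_runs(list(mk(1:6), mk(1:6), mk(1:6)))
  expect_equal(same$patterns, matrix(1:6, 2, 3))
  expect_equal(same$n_runs_averaged, 3)
  mixed <- average_across_runs(list(mk(rep(0, 6)), mk(rep(1, 6)), mk(rep(2, 6))))
  expect_true(all(mixed$patterns == 1))

  other <- mk(1:6)
  other$items$item_id <- c(1L, 3L)
  other$items$label <- c("CW:1", "CW:3")
  expect_error(average_across_runs(list(mk(1:6), other)), "mismatched items")
})

test_that("run-averaging reduces noise variance as 1/n_runs", {
  sched <- generate_schedule_exp1(n_runs = 1, n_trials_per_run = 3, seed = 14)[[1]]
  bank <- make_latent_patterns(3, 3, 5, 0, seed = 15)
  bank$patterns_L1[] <- 0  # noise-only betas
  X <- build_design_matrix(sched, 2, ceiling(sched$total_duration_s / 2))
  single <- c()
  averaged <- c()
  for (i in 1:60) {
    sets <- lapply(1:3, function(r) {
      run <- simulate_bold_run(sched, bank,
                               noise_model = list(sd = 1, ar1_coef = 0,
                                                  drift_slope = 0),
                               seed = 100 * i + r)
      fit_glm(run, X)
    })
    single <- c(single, sets[[1]]$betas)
    averaged <- c(averaged, average_across_runs(sets)$patterns)
  }
  ratio <- var(averaged) / var(single)
  expect_lt(abs(ratio - 1 / 3), 0.12)
})
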