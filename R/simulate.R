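# Synthetic-data generators: latent multivoxel patterns, forward BOLD model,
# behavioral learning series, and whole cohorts with a known brain-behavior link.

#' Latent item patterns with controlled cross-language similarity
#'
#' Draws one common voxel vector `c` (unit variance) and builds every item
#' pattern, in both languages, as `sqrt(rho) * c + sqrt(1 - rho) * e` with
#' independent unit-variance item noise `e`. The expected Pearson correlation
#' between any native-language (L1) pattern and any novel-language (L2)
#' pattern is therefore exactly `rho`, the shared-signal fraction.
#'
#' @param n_items_L1,n_items_L2 item counts per language.
#' @param n_voxels voxels per pattern (at least 2).
#' @param shared_frac shared-signal proportion `rho` in `[0, 1)`.
#' @param seed integer seed.
#'
#' @return An object of class `latent_pattern_bank`: list with
#'   `patterns_L1`, `patterns_L2` (items x voxels), `n_voxels`,
#'   `shared_frac`, `seed`.
#' @export
make_latent_patterns <- function(n_items_L1, n_items_L2, n_voxels,
                                 shared_frac, seed = 1) {
  n_items_L1 <- assert_count(n_items_L1, "n_items_L1")
  n_items_L2 <- assert_count(n_items_L2, "n_items_L2")
  n_voxels <- assert_count(n_voxels, "n_voxels", min = 2L)
  if (!is.numeric(shared_frac) || length(shared_frac) != 1L ||
      shared_frac < 0 || shared_frac >= 1) {
    stop("shared_frac must lie in [0, 1)", call. = FALSE)
  }
  with_rng_seed(seed, {
    common <- stats::rnorm(n_voxels)
    draw <- function(n_items) {
      noise <- matrix(stats::rnorm(n_items * n_voxels), n_items, n_voxels)
      sqrt(shared_frac) * matrix(common, n_items, n_voxels, byrow = TRUE) +
        sqrt(1 - shared_frac) * noise
    }
    structure(
      list(patterns_L1 = draw(n_items_L1), patterns_L2 = draw(n_items_L2),
           n_voxels = n_voxels, shared_frac = shared_frac, seed = seed),
      class = "latent_pattern_bank"
    )
  })
}

#' Simulate a BOLD run from a schedule and a pattern bank
#'
#' Forward model matching the first-level GLM: each voxel's signal is the sum
#' over items of the item's pattern amplitude times the HRF-convolved
#' stimulus boxcar, sampled at the TR. A linear drift (`drift_slope` signal
#' units per volume) and stationary AR(1) Gaussian noise (marginal standard
#' deviation `sd`, lag-1 coefficient `ar1_coef`) are added. `"CW"` events
#' take their amplitudes from `bank$patterns_L1`, `"ALW"` events from
#' `bank$patterns_L2`; fillers and other conditions evoke no signal.
#'
#' @param schedule an [event_schedule].
#' @param bank a [make_latent_patterns()] bank.
#' @param hrf an [double_gamma_hrf()] kernel.
#' @param tr_s repetition time in seconds (default 2, i.e. TR = 2000 ms).
#' @param noise_model list with `sd`, `ar1_coef`, `drift_slope`.
#' @param seed integer seed for the noise draws.
#'
#' @return An object of class `bold_run`: list with `data`
#'   (voxels x timepoints), `tr_s`, `schedule`, `noise_model`, `seed`.
#' @export
simulate_bold_run <- function(schedule, bank, hrf = double_gamma_hrf(),
                              tr_s = 2,
                              noise_model = list(sd = 1, ar1_coef = 0.3,
                                                 drift_slope = 0),
                              seed = 1) {
  stopifnot(inherits(schedule, "event_schedule"),
            inherits(bank, "latent_pattern_bank"))
  sd <- noise_model$sd %||% 0
  ar1 <- noise_model$ar1_coef %||% 0
  drift <- noise_model$drift_slope %||% 0
  if (abs(ar1) >= 1) stop("ar1_coef must lie in (-1, 1)", call. = FALSE)

  n_timepoints <- as.integer(ceiling(schedule$total_duration_s / tr_s))
  er <- event_regressors(schedule, tr_s, n_timepoints, hrf)
  n_voxels <- bank$n_voxels

  amp <- matrix(0, nrow(er$info), n_voxels)
  for (g in seq_len(nrow(er$info))) {
    cond <- er$info$condition[g]
    item <- er$info$item_id[g]
    src <- switch(cond, CW = bank$patterns_L1, ALW = bank$patterns_L2, NULL)
    if (!is.null(src)) {
      if (item > nrow(src)) {
        stop(sprintf("item %d (%s) has no pattern row in the bank", item, cond),
             call. = FALSE)
      }
      amp[g, ] <- src[item, ]
    }
  }
  signal <- t(er$regressors %*% amp)  # voxels x timepoints
  if (drift != 0) {
    signal <- signal + matrix(drift * (seq_len(n_timepoints) - 1),
                              n_voxels, n_timepoints, byrow = TRUE)
  }
  if (sd > 0) {
    noise <- with_rng_seed(seed, {
      innov <- matrix(stats::rnorm(n_timepoints * n_voxels, 0,
                                   sd * sqrt(1 - ar1^2)),
                      n_timepoints, n_voxels)
      if (ar1 != 0) {
        innov <- apply(innov, 2, function(x) {
          as.numeric(stats::filter(x, ar1, method = "recursive"))
        })
      }
      innov
    })
    signal <- signal + t(noise)
  }
  structure(
    list(data = signal, tr_s = tr_s, schedule = schedule,
         noise_model = list(sd = sd, ar1_coef = ar1, drift_slope = drift),
         seed = seed),
    class = "bold_run"
  )
}

#' Simulate a power-law learning series
#'
#' Per-session mean reaction times follow `y = a * x^(-b)` over sessions
#' `x = 1..n_sessions`, plus Gaussian noise, floored at `floor_ms`. An
#' accuracy column is generated as a saturating increasing sequence in
#' `[0, 1]` to mirror real behavioral tables; the learning-curve fit uses
#' only the RTs.
#'
#' @param a initial performance (ms), `a > 0`.
#' @param b learning rate (dimensionless), `b >= 0`.
#' @param n_sessions number of sessions (at least 3; 9 or 12 in practice).
#' @param noise_sd_ms RT noise standard deviation (ms).
#' @param floor_ms lower bound on simulated RTs (ms).
#' @param seed integer seed.
#' @param participant_id identifier recorded in the output.
#'
#' @return Data frame with columns `participant_id`, `session`, `rt_ms`,
#'   `accuracy`.
#' @export
simulate_learning_series <- function(a, b, n_sessions = 9, noise_sd_ms = 50,
                                     floor_ms = 100, seed = 1,
                                     participant_id = "s01") {
  assert_scalar_positive(a, "a")
  if (!is.numeric(b) || length(b) != 1L || b < 0) {
    stop("b must be a single non-negative number", call. = FALSE)
  }
  n_sessions <- assert_count(n_sessions, "n_sessions", min = 3L)
  x <- seq_len(n_sessions)
  with_rng_seed(seed, {
    eps <- if (noise_sd_ms > 0) stats::rnorm(n_sessions, 0, noise_sd_ms) else 0
    y <- pmax(floor_ms, a * x^(-b) + eps)
    acc <- 1 - (1 - 0.45) * exp(-0.35 * (x - 1)) +
      stats::rnorm(n_sessions, 0, 0.02)
    acc <- pmin(1, pmax(0, acc))
    data.frame(participant_id = participant_id, session = x,
               rt_ms = y, accuracy = acc)
  })
}

#' Default cohort design parameters
#'
#' Imaging and behavioral dimensions used by [simulate_cohort()]: the slow
#' event-related session (6 runs of 20 twelve-second trials, TR 2 s,
#' alternating native/novel-language runs), two regions of interest with
#' `n_voxels_roi` voxels each (the target region carries the
#' subject-specific shared-signal fraction; the control region a fixed null
#' level `rho_null`), AR(1)-plus-drift noise, and a 9-session behavioral
#' series. Pass overrides to scale the simulation down.
#'
#' @param ... named overrides of the defaults.
#' @return Named list of design parameters.
#' @export
cohort_design <- function(...) {
  design <- list(
    n_runs = 6L, n_items = 20L,
    fixation_s = 1, stimulus_s = 3, orientation_s = 8,
    tr_s = 2, hrf_dt_s = 0.1,
    n_voxels_roi = 200L,
    rois = c("left_fusiform", "right_fusiform"),
    rho_null = 0.1,
    noise = list(sd = 0.6, ar1_coef = 0.3, drift_slope = 0.05),
    n_sessions = 9L, rt_noise_sd_ms = 50, rt_floor_ms = 200,
    mu_a = 2000, sd_a = 150, mu_b = 0.3, sd_b = 0.08
  )
  overrides <- list(...)
  design[names(overrides)] <- overrides
  design
}

#' Simulate a cohort with a known brain-behavior link
#'
#' Draws a per-subject shared-signal fraction `rho_s`, couples the learning
#' rate to it as `b_s = mu_b + sd_b * (link * z(rho_s) + sqrt(1 - link^2) * eps)`
#' (so the expected correlation between `rho_s` and `b_s` equals
#' `link_strength`), then generates each subject's event schedules, BOLD runs
#' (target-region voxels carry `rho_s`; control-region voxels a fixed null
#' level), and behavioral learning series. All ground truth is recorded
#' before any estimation.
#'
#' @param n_subjects cohort size (at least 4).
#' @param rho_distribution length-2 numeric range for a uniform draw of
#'   `rho_s`, or a function `f(n)` returning `n` values in `[0, 1)`.
#' @param link_strength target correlation between `rho_s` and `b_s`,
#'   in `[-1, 1]`.
#' @param design design-parameter list from [cohort_design()].
#' @param seed integer master seed; per-subject seeds are derived from it.
#' @param imaging when `FALSE`, skip schedule and BOLD generation and return
#'   behavioral series and ground truth only (cheap for large calibration
#'   cohorts).
#'
#' @return An object of class `cohort`: list with `subjects` (each holding
#'   `participant_id`, `schedules`, `runs`, `behavior`, `roi_index`),
#'   `truth` (data frame: participant, true shared fraction, true a and b,
#'   per-subject seed), `link_strength`, `design`, `seed`.
#' @export
simulate_cohort <- function(n_subjects = 24,
                            rho_distribution = c(0.05, 0.65),
                            link_strength = 0.6,
                            design = cohort_design(),
                            seed = 1, imaging = TRUE) {
  n_subjects <- assert_count(n_subjects, "n_subjects", min = 4L)
  if (!is.numeric(link_strength) || length(link_strength) != 1L ||
      abs(link_strength) > 1) {
    stop("link_strength must lie in [-1, 1]", call. = FALSE)
  }
  if (abs(seed) + n_subjects + 1 >= 2^31) {
    stop("seed too large to derive per-subject seeds", call. = FALSE)
  }

  truth <- with_rng_seed(seed, {
    rho <- if (is.function(rho_distribution)) {
      rho_distribution(n_subjects)
    } else {
      stats::runif(n_subjects, rho_distribution[1], rho_distribution[2])
    }
    if (any(rho < 0 | rho >= 1)) stop("rho values must lie in [0, 1)", call. = FALSE)
    z <- as.numeric(scale(rho))
    eps <- stats::rnorm(n_subjects)
    b <- design$mu_b + design$sd_b *
      (link_strength * z + sqrt(1 - link_strength^2) * eps)
    b <- pmax(0.02, b)
    a <- pmax(500, stats::rnorm(n_subjects, design$mu_a, design$sd_a))
    data.frame(
      participant_id = sprintf("sub-%02d", seq_len(n_subjects)),
      true_shared_frac = rho, true_a = a, true_b = b,
      seed = seed + seq_len(n_subjects)
    )
  })

  hrf <- double_gamma_hrf(dt_s = design$hrf_dt_s)
  v <- design$n_voxels_roi
  roi_index <- stats::setNames(
    list(seq_len(v), v + seq_len(v)), design$rois)

  subjects <- lapply(seq_len(n_subjects), function(s) {
    seed_s <- truth$seed[s]
    behavior <- simulate_learning_series(
      a = truth$true_a[s], b = truth$true_b[s],
      n_sessions = design$n_sessions, noise_sd_ms = design$rt_noise_sd_ms,
      floor_ms = design$rt_floor_ms, seed = seed_s,
      participant_id = truth$participant_id[s]
    )
    if (!imaging) {
      return(list(participant_id = truth$participant_id[s],
                  behavior = behavior))
    }
    bank_target <- make_latent_patterns(design$n_items, design$n_items, v,
                                        truth$true_shared_frac[s],
                                        seed = seed_s)
    bank_control <- make_latent_patterns(design$n_items, design$n_items, v,
                                         design$rho_null, seed = seed_s + n_subjects)
    bank <- structure(
      list(patterns_L1 = cbind(bank_target$patterns_L1, bank_control$patterns_L1),
           patterns_L2 = cbind(bank_target$patterns_L2, bank_control$patterns_L2),
           n_voxels = 2L * v,
           shared_frac = truth$true_shared_frac[s],
           seed = seed_s),
      class = "latent_pattern_bank"
    )
    schedules <- generate_schedule_exp1(
      n_runs = design$n_runs, n_trials_per_run = design$n_items,
      fixation_s = design$fixation_s, stimulus_s = design$stimulus_s,
      orientation_s = design$orientation_s, seed = seed_s
    )
    runs <- lapply(seq_along(schedules), function(r) {
      simulate_bold_run(schedules[[r]], bank, hrf = hrf, tr_s = design$tr_s,
                        noise_model = design$noise,
                        seed = (seed_s %% 268435455) * 7 + r)
    })
    list(participant_id = truth$participant_id[s], schedules = schedules,
         runs = runs, behavior = behavior, roi_index = roi_index)
  })

  structure(
    list(subjects = subjects, truth = truth, link_strength = link_strength,
         design = design, seed = seed),
    class = "cohort"
  )
}
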