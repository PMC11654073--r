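#' Timed stimulus schedule for one fMRI run
#'
#' An `event_schedule` holds the labelled, timed stimulus events of a single
#' run: onset and duration in seconds from run start (0-based), a condition
#' label (`"CW"` native-language words, `"ALW"` artificial-language words,
#' `"EW"` known second-language words, `"filler"`), and an item identifier
#' that is unique within its condition.
#'
#' @param run_index integer run number (1-based).
#' @param events data frame with columns `onset`, `duration`, `condition`,
#'   `item_id`; onsets strictly increasing, events non-overlapping.
#' @param total_duration_s run length in seconds; must cover the last event.
#'
#' @return An object of class `event_schedule`.
#' @export
event_schedule <- function(run_index, events, total_duration_s) {
  run_index <- assert_count(run_index, "run_index")
  stopifnot(is.data.frame(events))
  required <- c("onset", "duration", "condition", "item_id")
  missing <- setdiff(required, names(events))
  if (length(missing)) {
    stop("events is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(events) == 0L) stop("events must contain at least one event", call. = FALSE)
  if (any(!is.finite(events$onset)) || any(!is.finite(events$duration))) {
    stop("onsets and durations must be finite", call. = FALSE)
  }
  if (any(events$duration <= 0)) stop("all durations must be > 0", call. = FALSE)
  if (any(events$onset < 0)) stop("onsets must be >= 0", call. = FALSE)
  if (is.unsorted(events$onset, strictly = TRUE)) {
    stop("onsets must be strictly increasing within a run", call. = FALSE)
  }
  n <- nrow(events)
  if (n > 1L) {
    ends <- events$onset + events$duration
    if (any(events$onset[-1L] < ends[-n] - 1e-9)) {
      stop("events must not overlap", call. = FALSE)
    }
  }
  last_end <- events$onset[n] + events$duration[n]
  if (total_duration_s < last_end - 1e-9) {
    stop("total_duration_s must cover the last event", call. = FALSE)
  }
  structure(
    list(run_index = run_index,
         events = events[, required],
         total_duration_s = as.numeric(total_duration_s)),
    class = "event_schedule"
  )
}

#' @export
print.event_schedule <- function(x, ...) {
  cat(sprintf("<event_schedule> run %d: %d events over %.1f s (%s)\n",
              x$run_index, nrow(x$events), x$total_duration_s,
              paste(unique(x$events$condition), collapse = ", ")))
  invisible(x)
}

#' Generate slow event-related run schedules
#'
#' Builds run schedules for a slow event-related implicit-reading design:
#' each trial is a fixed budget of fixation, stimulus presentation, and an
#' unmodelled self-paced orientation-judgment window. Only the stimulus
#' interval becomes an event; fixation and the orientation window are
#' implicit baseline. Runs alternate through `conditions`, and each run
#' presents every item of its condition exactly once in a seed-randomized
#' order. With the defaults (6 runs of 20 trials of 1 + 3 + 8 s) the session
#' totals 24 minutes.
#'
#' @param n_runs number of runs.
#' @param n_trials_per_run trials per run; equals the item count of one
#'   condition.
#' @param fixation_s,stimulus_s,orientation_s trial-segment durations in
#'   seconds.
#' @param seed integer seed controlling item order.
#' @param conditions condition labels cycled across runs.
#'
#' @return A list of [event_schedule] objects, one per run.
#' @export
generate_schedule_exp1 <- function(n_runs = 6, n_trials_per_run = 20,
                                   fixation_s = 1, stimulus_s = 3,
                                   orientation_s = 8, seed = 1,
                                   conditions = c("CW", "ALW")) {
  n_runs <- assert_count(n_runs, "n_runs")
  n_trials_per_run <- assert_count(n_trials_per_run, "n_trials_per_run")
  assert_scalar_positive(fixation_s, "fixation_s")
  assert_scalar_positive(stimulus_s, "stimulus_s")
  assert_scalar_positive(orientation_s, "orientation_s")
  trial_s <- fixation_s + stimulus_s + orientation_s
  with_rng_seed(seed, {
    lapply(seq_len(n_runs), function(r) {
      cond <- conditions[(r - 1L) %% length(conditions) + 1L]
      order_r <- sample.int(n_trials_per_run)
      onsets <- (seq_len(n_trials_per_run) - 1) * trial_s + fixation_s
      event_schedule(
        run_index = r,
        events = data.frame(
          onset = onsets,
          duration = stimulus_s,
          condition = cond,
          item_id = order_r
        ),
        total_duration_s = n_trials_per_run * trial_s
      )
    })
  })
}

# Probabilities of a truncated geometric-like distribution over `values`
# (p_k proportional to q^(k-1)) with q tuned so the mean equals target_mean.
truncated_geometric_probs <- function(values, target_mean) {
  k <- length(values)
  if (k == 1L) {
    if (abs(values - target_mean) > 1e-9) {
      stop("mean_isi_s must equal the single available ISI value", call. = FALSE)
    }
    return(1)
  }
  if (target_mean <= values[1] || target_mean >= values[k]) {
    stop("mean_isi_s must lie strictly inside isi_range_s", call. = FALSE)
  }
  gap <- function(logq) {
    w <- exp(logq * (seq_len(k) - 1))
    sum(values * w) / sum(w) - target_mean
  }
  root <- stats::uniroot(gap, c(-30, 30), tol = 1e-12)
  w <- exp(root$root * (seq_len(k) - 1))
  w / sum(w)
}

#' Generate a jittered event-related run schedule
#'
#' Builds the rapid event-related passive-viewing design: every item of every
#' condition is presented `n_repeats` times, plus `n_fillers` filler
#' presentations (underlined words requiring a key press), in a single
#' seed-randomized sequence. Inter-stimulus intervals are drawn from a
#' truncated geometric-like discrete distribution on the integer grid of
#' `isi_range_s`, tuned so the expected ISI equals `mean_isi_s`. With the
#' defaults (30 items x 3 conditions x 2 repeats + 9 fillers of 600 ms,
#' ISI 1-5 s with mean 2 s) the run has 189 presentations.
#'
#' @param items_per_condition items per condition.
#' @param n_conditions number of word conditions (labels from `conditions`).
#' @param n_repeats presentations per item.
#' @param n_fillers filler presentations (each filler item shown once).
#' @param stimulus_s stimulus duration in seconds.
#' @param isi_range_s length-2 numeric, inclusive ISI bounds in seconds.
#' @param mean_isi_s target mean ISI in seconds; must lie inside the range.
#' @param seed integer seed controlling stimulus order and ISI draws.
#' @param conditions condition labels, at least `n_conditions` of them.
#'
#' @return An [event_schedule].
#' @export
generate_schedule_exp2 <- function(items_per_condition = 30, n_conditions = 3,
                                   n_repeats = 2, n_fillers = 9,
                                   stimulus_s = 0.6, isi_range_s = c(1, 5),
                                   mean_isi_s = 2, seed = 1,
                                   conditions = c("CW", "ALW", "EW")) {
  items_per_condition <- assert_count(items_per_condition, "items_per_condition")
  n_conditions <- assert_count(n_conditions, "n_conditions")
  n_repeats <- assert_count(n_repeats, "n_repeats")
  n_fillers <- assert_count(n_fillers, "n_fillers", min = 0L)
  assert_scalar_positive(stimulus_s, "stimulus_s")
  if (length(isi_range_s) != 2L || any(isi_range_s <= 0) ||
      isi_range_s[1] > isi_range_s[2]) {
    stop("isi_range_s must be positive and ordered", call. = FALSE)
  }
  if (n_conditions > length(conditions)) {
    stop("not enough condition labels for n_conditions", call. = FALSE)
  }
  isi_values <- seq(isi_range_s[1], isi_range_s[2], by = 1)
  isi_probs <- truncated_geometric_probs(isi_values, mean_isi_s)

  stim <- expand.grid(item_id = seq_len(items_per_condition),
                      condition = conditions[seq_len(n_conditions)],
                      rep = seq_len(n_repeats),
                      stringsAsFactors = FALSE)
  if (n_fillers > 0L) {
    stim <- rbind(stim[, c("item_id", "condition")],
                  data.frame(item_id = seq_len(n_fillers), condition = "filler"))
  } else {
    stim <- stim[, c("item_id", "condition")]
  }
  n_events <- nrow(stim)

  with_rng_seed(seed, {
    stim <- stim[sample.int(n_events), ]
    isis <- sample(isi_values, n_events, replace = TRUE, prob = isi_probs)
    onsets <- c(0, cumsum(stimulus_s + isis))[seq_len(n_events)]
    event_schedule(
      run_index = 1L,
      events = data.frame(
        onset = onsets,
        duration = stimulus_s,
        condition = stim$condition,
        item_id = stim$item_id
      ),
      total_duration_s = onsets[n_events] + stimulus_s + isis[n_events]
    )
  })
}
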