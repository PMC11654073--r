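# HRF-convolved regressors and first-level design matrices.

# One regressor per (condition, item) group of non-filler events, plus a
# single shared group for fillers. Boxcars are laid on a fine grid of step
# hrf$dt_s, convolved with the kernel (scaled by dt so values approximate the
# continuous convolution integral), then sampled at volume times t = k * TR.
# Shared by the BOLD simulator and the design builder so that, noise aside,
# generating amplitudes are exactly the GLM's betas.
event_regressors <- function(schedule, tr_s, n_timepoints, hrf) {
  stopifnot(inherits(schedule, "event_schedule"), inherits(hrf, "hrf_kernel"))
  assert_scalar_positive(tr_s, "tr_s")
  n_timepoints <- assert_count(n_timepoints, "n_timepoints")
  dt <- hrf$dt_s
  steps_per_tr <- tr_s / dt
  if (abs(steps_per_tr - round(steps_per_tr)) > 1e-9) {
    stop("hrf dt_s must divide tr_s", call. = FALSE)
  }
  ev <- schedule$events
  scan_s <- n_timepoints * tr_s
  if (any(ev$onset + ev$duration > scan_s + 1e-9)) {
    stop("schedule contains events outside the scan window", call. = FALSE)
  }

  is_filler <- ev$condition == "filler"
  key <- ifelse(is_filler, "filler", paste(ev$condition, ev$item_id, sep = ":"))
  groups <- unique(key)
  info <- data.frame(
    label = groups,
    condition = ev$condition[match(groups, key)],
    item_id = ifelse(groups == "filler", NA_integer_,
                     ev$item_id[match(groups, key)]),
    stringsAsFactors = FALSE
  )

  n_fine <- as.integer(round(scan_s / dt))
  vol_idx <- as.integer(round((seq_len(n_timepoints) - 1) * steps_per_tr)) + 1L
  h <- hrf$values

  # one zero-padded FFT convolution for all groups at once
  n_pad <- stats::nextn(n_fine + length(h), 2)
  box <- matrix(0, n_pad, length(groups), dimnames = list(NULL, groups))
  for (i in seq_len(nrow(ev))) {
    g <- match(key[i], groups)
    i0 <- floor(ev$onset[i] / dt) + 1L
    i1 <- min(n_fine, ceiling((ev$onset[i] + ev$duration[i]) / dt))
    box[i0:i1, g] <- 1
  }
  h_fft <- stats::fft(c(h, numeric(n_pad - length(h))))
  conv <- Re(stats::mvfft(stats::mvfft(box) * h_fft, inverse = TRUE)) / n_pad
  reg <- conv[vol_idx, , drop = FALSE] * dt
  list(regressors = reg, info = info)
}

#' Build a first-level design matrix
#'
#' One regressor per item (HRF-convolved stimulus boxcar sampled at the TR),
#' so each item's beta is its single-trial activation estimate. Filler events
#' share one nuisance regressor; optional temporal derivatives
#' (finite differences of each task column) and user-supplied nuisance
#' columns (e.g. motion parameters) are flagged as not of interest. An
#' intercept is always included.
#'
#' @param schedule an [event_schedule].
#' @param tr_s repetition time in seconds.
#' @param n_timepoints number of volumes; the schedule must fit within
#'   `n_timepoints * tr_s`.
#' @param hrf an [double_gamma_hrf()] kernel; its `dt_s` must divide `tr_s`.
#' @param add_derivatives add a temporal-derivative column per task regressor.
#' @param nuisance optional numeric matrix of extra nuisance columns
#'   (`n_timepoints` rows).
#'
#' @return An object of class `design_matrix`: list with `matrix`
#'   (timepoints x regressors), `names`, logical `of_interest`, `items`
#'   (condition/item per of-interest column), and `tr_s`.
#' @export
build_design_matrix <- function(schedule, tr_s, n_timepoints,
                                hrf = double_gamma_hrf(),
                                add_derivatives = FALSE, nuisance = NULL) {
  er <- event_regressors(schedule, tr_s, n_timepoints, hrf)
  task <- er$regressors
  info <- er$info
  of_interest_task <- info$condition != "filler"

  cols <- list(task)
  names_all <- colnames(task)
  flags <- of_interest_task

  if (add_derivatives) {
    deriv <- apply(task, 2, function(col) c(0, diff(col)) / tr_s)
    colnames(deriv) <- paste0(colnames(task), "_deriv")
    cols <- c(cols, list(deriv))
    names_all <- c(names_all, colnames(deriv))
    flags <- c(flags, rep(FALSE, ncol(deriv)))
  }
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_timepoints) {
      stop("nuisance matrix must have n_timepoints rows", call. = FALSE)
    }
    if (is.null(colnames(nuisance))) {
      colnames(nuisance) <- paste0("nuisance", seq_len(ncol(nuisance)))
    }
    cols <- c(cols, list(nuisance))
    names_all <- c(names_all, colnames(nuisance))
    flags <- c(flags, rep(FALSE, ncol(nuisance)))
  }
  cols <- c(cols, list(matrix(1, n_timepoints, 1, dimnames = list(NULL, "intercept"))))
  names_all <- c(names_all, "intercept")
  flags <- c(flags, FALSE)

  X <- do.call(cbind, cols)
  colnames(X) <- names_all
  structure(
    list(matrix = X, names = names_all, of_interest = flags,
         items = info[of_interest_task, c("label", "condition", "item_id")],
         tr_s = tr_s),
    class = "design_matrix"
  )
}

# Drift basis: constant, linear trend, and DCT-II components with period
# longer than cutoff_s — the standard low-frequency confound set.
dct_drift_basis <- function(n_timepoints, tr_s, cutoff_s) {
  n_basis <- floor(2 * n_timepoints * tr_s / cutoff_s)
  t <- seq_len(n_timepoints) - 1
  B <- matrix(1, n_timepoints, 2 + n_basis)
  B[, 2] <- t - mean(t)
  for (k in seq_len(n_basis)) {
    B[, k + 2] <- cos(pi * (2 * t + 1) * k / (2 * n_timepoints))
  }
  B
}

#' High-pass filter a time series by drift-basis residualization
#'
#' Removes slow drifts (period above `cutoff_s`, plus the mean and a linear
#' trend) by projecting out a discrete-cosine drift basis. This is the
#' deterministic, spectrally matched
#' counterpart of FSL's 100-s nonlinear high-pass filter, and is applied
#' identically to data and design so that filtering commutes with GLM
#' estimation.
#'
#' @param ts numeric vector or matrix (timepoints x series).
#' @param tr_s sampling interval in seconds.
#' @param cutoff_s high-pass cutoff period in seconds; must exceed `2 * tr_s`.
#'
#' @return Filtered series with the same shape as `ts`.
#' @export
highpass_filter <- function(ts, tr_s, cutoff_s = 100) {
  assert_scalar_positive(tr_s, "tr_s")
  if (cutoff_s <= 2 * tr_s) stop("cutoff_s must exceed 2 * tr_s", call. = FALSE)
  vec <- is.null(dim(ts))
  ts_m <- as.matrix(ts)
  n <- nrow(ts_m)
  B <- dct_drift_basis(n, tr_s, cutoff_s)
  if (n <= ncol(B)) {
    stop("fewer timepoints than drift-basis size", call. = FALSE)
  }
  Q <- qr.Q(qr(B))
  out <- ts_m - Q %*% crossprod(Q, ts_m)
  if (vec) drop(out) else out
}
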