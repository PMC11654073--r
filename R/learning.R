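# Power-law learning-curve fitting and the goodness-of-fit inclusion rule.

#' Fit a power-law learning curve to per-session reaction times
#'
#' Nonlinear least squares of `y = a * x^(-b)` over sessions `x = 1..T`,
#' where `a` is the initial performance (ms) and `b` the learning rate.
#' Starting values come from the log-log closed form (regress `log y` on
#' `log x`); the optimizer then refines them on the raw-RT scale, with a few
#' deterministically perturbed restarts on failure. The coefficient of
#' determination `R^2 = 1 - SS_res / SS_tot` is computed on the raw (not
#' log) scale. A constant series is the degenerate exact fit `b = 0`,
#' `R^2 = 1`. If no start converges the fit is flagged with
#' `r_squared = -Inf`.
#'
#' @param series data frame with columns `session` and `rt_ms` (and
#'   optionally `participant_id`); at least 3 sessions, all RTs positive.
#' @param participant_id identifier for the output row; defaults to the
#'   series' own column.
#'
#' @return One-row data frame: `participant_id`, `a`, `b`, `r_squared`,
#'   `n_sessions`, `converged`.
#' @export
fit_power_law <- function(series, participant_id = NULL) {
  stopifnot(is.data.frame(series),
            all(c("session", "rt_ms") %in% names(series)))
  x <- as.numeric(series$session)
  y <- as.numeric(series$rt_ms)
  if (length(y) < 3L) stop("at least 3 sessions are required", call. = FALSE)
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("reaction times must be positive and finite", call. = FALSE)
  }
  pid <- participant_id %||%
    (if ("participant_id" %in% names(series)) series$participant_id[1] else NA_character_)

  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    # flat series: exact fit with no learning
    return(data.frame(participant_id = pid, a = y[1], b = 0, r_squared = 1,
                      n_sessions = length(y), converged = TRUE,
                      stringsAsFactors = FALSE))
  }

  loglog <- stats::lm(log(y) ~ log(x))
  a0 <- exp(stats::coef(loglog)[[1]])
  b0 <- -stats::coef(loglog)[[2]]

  starts <- list(
    c(a = a0, b = b0),
    c(a = a0 * 1.5, b = b0 + 0.1),
    c(a = a0 * 0.7, b = b0 - 0.1),
    c(a = mean(y), b = 0.3),
    c(a = max(y), b = 0.01)
  )
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a * x^(-b),
        start = as.list(st),
        lower = c(a = .Machine$double.eps, b = -10), upper = c(a = Inf, b = 10),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    return(data.frame(participant_id = pid, a = a0, b = b0,
                      r_squared = -Inf, n_sessions = length(y),
                      converged = FALSE, stringsAsFactors = FALSE))
  }
  est <- stats::coef(fit)
  r2 <- 1 - sum(stats::residuals(fit)^2) / ss_tot
  data.frame(participant_id = pid, a = est[["a"]], b = est[["b"]],
             r_squared = r2, n_sessions = length(y), converged = TRUE,
             stringsAsFactors = FALSE)
}

#' Apply the goodness-of-fit inclusion rule
#'
#' Participants whose learning-curve fit has `R^2` strictly below the
#' threshold are excluded from downstream brain-behavior analysis.
#'
#' @param fits data frame of [fit_power_law()] rows.
#' @param threshold inclusion threshold in `(0, 1]` (default 0.7); a fit is
#'   included iff `r_squared >= threshold`.
#'
#' @return List with `fits` (input plus logical `included` column) and
#'   `report`: excluded ids and their `R^2`, the surviving count, and the
#'   mean `R^2` of the survivors.
#' @export
select_by_fit <- function(fits, threshold = 0.7) {
  stopifnot(is.data.frame(fits), "r_squared" %in% names(fits))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  fits$included <- fits$r_squared >= threshold
  excluded <- fits[!fits$included, c("participant_id", "r_squared")]
  list(
    fits = fits,
    report = list(
      threshold = threshold,
      n_included = sum(fits$included),
      n_excluded = sum(!fits$included),
      excluded_ids = excluded$participant_id,
      excluded_r_squared = excluded$r_squared,
      mean_r_squared_included =
        if (any(fits$included)) mean(fits$r_squared[fits$included]) else NA_real_
    )
  )
}
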