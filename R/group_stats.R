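# Group-level statistics: training-effect repeated-measures ANOVA and the
# ROI-wise brain-behavior correlation.

#' One-way repeated-measures ANOVA
#'
#' Classical subjects x sessions decomposition: the session effect is tested
#' against the subject-by-session interaction, `F = MS_session / MS_error`
#' with degrees of freedom `(T - 1, (T - 1)(N - 1))`. The effect size is
#' partial eta squared, `SS_session / (SS_session + SS_error)`. No sphericity
#' correction is applied.
#'
#' @param data numeric matrix, subjects in rows and sessions in columns
#'   (complete cells, `N >= 2`, `T >= 2`).
#'
#' @return List of class `rm_anova`: `F`, `df_effect`, `df_error`, `p`,
#'   `eta_sq_partial`, and the sums of squares.
#' @export
rm_anova <- function(data) {
  data <- as.matrix(data)
  if (any(!is.finite(data))) stop("missing or non-finite cells are not allowed", call. = FALSE)
  n <- nrow(data)
  t <- ncol(data)
  if (n < 2L || t < 2L) stop("need at least 2 subjects and 2 sessions", call. = FALSE)

  grand <- mean(data)
  session_means <- colMeans(data)
  subject_means <- rowMeans(data)
  ss_session <- n * sum((session_means - grand)^2)
  ss_subject <- t * sum((subject_means - grand)^2)
  ss_total <- sum((data - grand)^2)
  ss_error <- ss_total - ss_session - ss_subject

  df_effect <- t - 1L
  df_error <- (t - 1L) * (n - 1L)
  ms_session <- ss_session / df_effect
  ms_error <- ss_error / df_error
  f <- if (ms_error > 0) ms_session / ms_error else if (ss_session == 0) 0 else Inf
  structure(
    list(F = f, df_effect = df_effect, df_error = df_error,
         p = stats::pf(f, df_effect, df_error, lower.tail = FALSE),
         eta_sq_partial = if (ss_session + ss_error > 0) {
           ss_session / (ss_session + ss_error)
         } else 0,
         ss = c(session = ss_session, subject = ss_subject, error = ss_error)),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("F(%d, %d) = %.3f, p = %.3g, partial eta^2 = %.3f\n",
              x$df_effect, x$df_error, x$F, x$p, x$eta_sq_partial))
  invisible(x)
}

#' Pearson correlation with a two-tailed t-test
#'
#' Sample Pearson correlation and the two-tailed p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, `n >= 4`, both non-constant.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("at least 4 complete pairs are required", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input has no defined correlation", call. = FALSE)
  }
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) {
    0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Correlate cross-language pattern similarity with the learning rate
#'
#' Per ROI, Pearson-correlates the included participants' similarity scores
#' (`ps_z`) with their fitted learning rates (`b`). Participants are matched
#' by id, and only fits flagged `included` (see [select_by_fit()]) enter the
#' analysis. ROIs with fewer than 4 matched participants are skipped with a
#' warning. Results are reported for every requested ROI, significant or not.
#'
#' @param ps_results data frame of similarity rows (`participant_id`,
#'   `roi_name`, `ps_z`).
#' @param fits data frame of learning fits with an `included` column.
#' @param rois ROI labels to analyse; defaults to all present in `ps_results`.
#'
#' @return Data frame with one row per analysed ROI: `roi_name`, `r`, `p`, `n`.
#' @export
correlate_ps_with_learning <- function(ps_results, fits, rois = NULL) {
  stopifnot(is.data.frame(ps_results), is.data.frame(fits))
  if (!"included" %in% names(fits)) {
    stop("fits must carry an `included` column; run select_by_fit() first",
         call. = FALSE)
  }
  rois <- rois %||% unique(ps_results$roi_name)
  fits <- fits[fits$included, c("participant_id", "b")]
  out <- lapply(rois, function(roi) {
    ps_roi <- ps_results[ps_results$roi_name == roi,
                         c("participant_id", "ps_z")]
    merged <- merge(ps_roi, fits, by = "participant_id")
    if (nrow(merged) < 4L) {
      warning(sprintf("ROI %s skipped: only %d matched participants",
                      roi, nrow(merged)), call. = FALSE)
      return(NULL)
    }
    res <- pearson_test(merged$ps_z, merged$b)
    data.frame(roi_name = roi, r = res$r, p = res$p, n = res$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))]) %||%
    data.frame(roi_name = character(), r = numeric(), p = numeric(),
               n = integer())
}
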