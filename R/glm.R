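# Single-item (beta-series) GLM estimation.

#' Fit the single-item GLM to one BOLD run
#'
#' Ordinary least squares per voxel after applying the same discrete-cosine
#' high-pass filter to both the data and the design (so drifts and the mean
#' are projected out of both sides; the intercept is absorbed by the filter
#' basis). For a single item versus baseline the contrast of parameter
#' estimates is the item's beta, so the returned of-interest betas are the
#' per-item activation estimates. Temporal-derivative and nuisance betas are
#' estimated but not returned.
#'
#' @param run a [simulate_bold_run()] result, or any list with `data`
#'   (voxels x timepoints) and `tr_s`.
#' @param design a [build_design_matrix()] result with rows matching the
#'   run's timepoints.
#' @param highpass_s high-pass cutoff period in seconds (default 100);
#'   `NULL` disables filtering (an intercept then stays in the model).
#'
#' @return An object of class `item_beta_set`: list with `betas`
#'   (items x voxels), `items` (condition/item per row), `run_index`,
#'   `condition` (the run's condition when unique).
#' @export
fit_glm <- function(run, design, highpass_s = 100) {
  stopifnot(inherits(design, "design_matrix"))
  Y <- t(run$data)  # timepoints x voxels
  X <- design$matrix
  if (nrow(X) != nrow(Y)) {
    stop("design rows must match run timepoints", call. = FALSE)
  }
  keep <- design$names != "intercept"
  if (!is.null(highpass_s)) {
    Xf <- highpass_filter(X[, keep, drop = FALSE], run$tr_s, highpass_s)
    Yf <- highpass_filter(Y, run$tr_s, highpass_s)
  } else {
    keep <- rep(TRUE, ncol(X))
    Xf <- X
    Yf <- Y
  }
  qrX <- qr(Xf)
  if (qrX$rank < ncol(Xf)) {
    bad <- colnames(Xf)[qrX$pivot[(qrX$rank + 1):ncol(Xf)]]
    stop("design is rank deficient after filtering; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coefs <- qr.coef(qrX, Yf)
  interest <- design$of_interest[keep]
  betas <- coefs[interest, , drop = FALSE]
  items <- design$items
  rownames(betas) <- items$label
  cond <- unique(items$condition)
  structure(
    list(betas = betas, items = items,
         run_index = run$schedule$run_index %||% NA_integer_,
         condition = if (length(cond) == 1L) cond else NA_character_),
    class = "item_beta_set"
  )
}

#' Average item betas across runs
#'
#' Element-wise mean of the per-item beta matrices across repeated runs of
#' the same condition, improving the signal-to-noise ratio of the
#' single-trial estimates. All runs must share the same items in the same
#' order.
#'
#' @param beta_sets list of [fit_glm()] results for the same condition.
#'
#' @return An object of class `item_pattern_set`: list with `patterns`
#'   (items x voxels), `items`, `condition`, `n_runs_averaged`.
#' @export
average_across_runs <- function(beta_sets) {
  stopifnot(length(beta_sets) >= 1L,
            all(vapply(beta_sets, inherits, logical(1), "item_beta_set")))
  ref <- beta_sets[[1L]]
  for (bs in beta_sets[-1L]) {
    if (!identical(bs$items$label, ref$items$label)) {
      stop("beta sets have mismatched items and cannot be averaged",
           call. = FALSE)
    }
    if (!identical(bs$condition, ref$condition)) {
      stop("beta sets have mismatched conditions", call. = FALSE)
    }
  }
  patterns <- Reduce(`+`, lapply(beta_sets, `[[`, "betas")) / length(beta_sets)
  structure(
    list(patterns = patterns, items = ref$items, condition = ref$condition,
         n_runs_averaged = length(beta_sets)),
    class = "item_pattern_set"
  )
}
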