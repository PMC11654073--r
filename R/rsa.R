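# ROI-based representational similarity analysis: cross-language pattern
# similarity (PS) as Fisher-z transformed Pearson correlations across voxels.

#' Region-of-interest mask
#'
#' @param name ROI label, e.g. `"left_fusiform"`.
#' @param voxel_indices integer matrix (n x 3) of 0-based voxel coordinates.
#' @param volume_dim optional length-3 volume dimensions used for bounds
#'   checking and for indexing flat pattern matrices.
#' @param source free-text provenance (e.g. an atlas and threshold).
#'
#' @return An object of class `roi_mask`. Voxels are canonicalized to
#'   lexicographic (x, y, z) order so downstream results do not depend on the
#'   ordering in a mask file.
#' @export
roi_mask <- function(name, voxel_indices, volume_dim = NULL, source = "") {
  voxel_indices <- as.matrix(voxel_indices)
  if (nrow(voxel_indices) == 0L || ncol(voxel_indices) != 3L) {
    stop("voxel_indices must be a non-empty n x 3 matrix", call. = FALSE)
  }
  if (any(voxel_indices < 0) || any(voxel_indices != round(voxel_indices))) {
    stop("voxel_indices must be non-negative integers (0-based)", call. = FALSE)
  }
  if (!is.null(volume_dim)) {
    stopifnot(length(volume_dim) == 3L)
    if (any(t(voxel_indices) >= volume_dim)) {
      stop("mask voxel outside volume bounds", call. = FALSE)
    }
  }
  ord <- order(voxel_indices[, 1], voxel_indices[, 2], voxel_indices[, 3])
  structure(
    list(name = name, voxel_indices = voxel_indices[ord, , drop = FALSE],
         volume_dim = volume_dim, source = source),
    class = "roi_mask"
  )
}

#' Extract ROI item patterns from a beta volume
#'
#' Pulls the masked voxels out of a 4-D beta image (x, y, z, item) or a flat
#' items x all-voxels matrix, in the mask's canonical lexicographic (x, y, z)
#' voxel order.
#'
#' @param betas 4-D numeric array with items on the fourth dimension, or an
#'   items x all-voxels matrix (requires `mask$volume_dim`).
#' @param mask an [roi_mask()] with at least 2 voxels inside the volume.
#' @param condition optional condition label carried into the result.
#'
#' @return An `item_pattern_set` whose `patterns` are items x mask-voxels.
#' @export
extract_roi_patterns <- function(betas, mask, condition = NA_character_) {
  stopifnot(inherits(mask, "roi_mask"))
  vi <- mask$voxel_indices
  if (nrow(vi) < 2L) stop("mask must contain at least 2 voxels", call. = FALSE)
  if (is.array(betas) && length(dim(betas)) == 4L) {
    d <- dim(betas)
    if (any(t(vi) >= d[1:3])) stop("mask voxel outside volume bounds", call. = FALSE)
    flat <- matrix(betas, prod(d[1:3]), d[4])
    lin <- vi[, 1] + d[1] * (vi[, 2] + d[2] * vi[, 3]) + 1
    patterns <- t(flat[lin, , drop = FALSE])
  } else if (is.matrix(betas)) {
    if (is.null(mask$volume_dim)) {
      stop("flat beta matrices require a mask with volume_dim", call. = FALSE)
    }
    d <- mask$volume_dim
    if (ncol(betas) != prod(d)) {
      stop("beta matrix columns do not match mask volume_dim", call. = FALSE)
    }
    lin <- vi[, 1] + d[1] * (vi[, 2] + d[2] * vi[, 3]) + 1
    patterns <- betas[, lin, drop = FALSE]
  } else {
    stop("betas must be a 4-D array or an items x voxels matrix", call. = FALSE)
  }
  structure(
    list(patterns = patterns, items = NULL, condition = condition,
         n_runs_averaged = NA_integer_, roi_name = mask$name),
    class = "item_pattern_set"
  )
}

#' Fisher z-transform of a correlation
#'
#' `z = arctanh(r) = 0.5 * log((1 + r) / (1 - r))`, mapping correlations to
#' an approximately normal scale before averaging.
#'
#' @param r correlation value(s) strictly inside (-1, 1).
#' @return Fisher-z value(s).
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop("fisher_z is undefined for |r| >= 1", call. = FALSE)
  }
  atanh(r)
}

as_pattern_matrix <- function(x, arg) {
  m <- if (inherits(x, "item_pattern_set")) x$patterns else x
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(sprintf("`%s` must be an item_pattern_set or items x voxels matrix", arg),
         call. = FALSE)
  }
  m
}

check_pattern_variance <- function(m, language) {
  v <- apply(m, 1, stats::var)
  bad <- which(v <= 0 | !is.finite(v))
  if (length(bad)) {
    stop(sprintf("zero-variance pattern for %s item(s): %s", language,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
}

ps_result <- function(participant_id, roi_name, ps_z, method, n_pairs, n_voxels) {
  data.frame(participant_id = participant_id, roi_name = roi_name,
             ps_z = ps_z, method = method, n_pairs = n_pairs,
             n_voxels = n_voxels, stringsAsFactors = FALSE)
}

guard_unit_correlation <- function(r, clip) {
  if (any(abs(r) >= 1)) {
    if (!clip) {
      stop("correlation of +/-1 encountered; Fisher z is undefined ",
           "(set clip = TRUE to clamp degenerate cases)", call. = FALSE)
    }
    r <- pmin(1 - 1e-12, pmax(-1 + 1e-12, r))
  }
  r
}

#' Pairwise cross-language pattern similarity
#'
#' Pearson-correlates every cross-language item pair across voxels
#' (`n1 x n2` pairs), Fisher-z transforms each correlation, and averages the
#' z values into one participant-level similarity scalar.
#'
#' @param patterns_L1,patterns_L2 `item_pattern_set`s or items x voxels
#'   matrices with identical voxel count and order (at least 3 voxels).
#' @param participant_id,roi_name labels carried into the result row.
#' @param clip clamp correlations of exactly +/-1 to `1 - 1e-12` instead of
#'   raising an error (off by default; only degenerate synthetic patterns
#'   reach +/-1).
#'
#' @return One-row data frame: `participant_id`, `roi_name`, `ps_z`,
#'   `method = "pairwise_mean"`, `n_pairs`, `n_voxels`.
#' @export
pairwise_cross_language_ps <- function(patterns_L1, patterns_L2,
                                       participant_id = NA_character_,
                                       roi_name = NA_character_,
                                       clip = FALSE) {
  m1 <- as_pattern_matrix(patterns_L1, "patterns_L1")
  m2 <- as_pattern_matrix(patterns_L2, "patterns_L2")
  if (ncol(m1) != ncol(m2)) stop("voxel counts differ between languages", call. = FALSE)
  if (ncol(m1) < 3L) stop("at least 3 voxels are required", call. = FALSE)
  check_pattern_variance(m1, "L1")
  check_pattern_variance(m2, "L2")
  r <- stats::cor(t(m1), t(m2))
  r <- guard_unit_correlation(r, clip)
  z <- atanh(r)
  ps_result(participant_id, roi_name, mean(z), "pairwise_mean",
            nrow(m1) * nrow(m2), ncol(m1))
}

#' Averaged-pattern cross-language similarity
#'
#' Averages each language's item patterns into a single mean pattern, then
#' takes one Pearson correlation across voxels between the two mean patterns
#' and Fisher-z transforms it.
#'
#' @inheritParams pairwise_cross_language_ps
#' @return One-row data frame with `method = "averaged_pattern"` and
#'   `n_pairs = 1`.
#' @export
averaged_pattern_ps <- function(patterns_L1, patterns_L2,
                                participant_id = NA_character_,
                                roi_name = NA_character_, clip = FALSE) {
  m1 <- as_pattern_matrix(patterns_L1, "patterns_L1")
  m2 <- as_pattern_matrix(patterns_L2, "patterns_L2")
  if (ncol(m1) != ncol(m2)) stop("voxel counts differ between languages", call. = FALSE)
  if (ncol(m1) < 3L) stop("at least 3 voxels are required", call. = FALSE)
  mean1 <- colMeans(m1)
  mean2 <- colMeans(m2)
  if (stats::var(mean1) <= 0 || stats::var(mean2) <= 0) {
    stop("zero-variance mean pattern", call. = FALSE)
  }
  r <- guard_unit_correlation(stats::cor(mean1, mean2), clip)
  ps_result(participant_id, roi_name, atanh(r), "averaged_pattern",
            1L, ncol(m1))
}
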