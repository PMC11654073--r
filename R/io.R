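# Standard-format I/O: BIDS-style events TSV, CSV tables, NIfTI images,
# JSON reports, YAML configuration.

#' Write / read a BIDS-style events table
#'
#' Tab-separated with columns `onset`, `duration`, `trial_type`, `item_id`
#' (seconds, period decimal).
#'
#' @param schedule an [event_schedule()].
#' @param path output file path (`.tsv`).
#' @return `write_events_tsv` returns `path` invisibly; `read_events_tsv`
#'   returns an [event_schedule()].
#' @export
write_events_tsv <- function(schedule, path) {
  stopifnot(inherits(schedule, "event_schedule"))
  ev <- schedule$events
  out <- data.frame(onset = ev$onset, duration = ev$duration,
                    trial_type = ev$condition, item_id = ev$item_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param path events file path.
#' @param run_index run number to record on the schedule.
#' @param total_duration_s run length; defaults to the last event's end.
#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path, run_index = 1L, total_duration_s = NULL) {
  tab <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("malformed events file %s: %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  required <- c("onset", "duration", "trial_type", "item_id")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop(sprintf("events file %s lacks column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  n <- nrow(tab)
  event_schedule(
    run_index = run_index,
    events = data.frame(onset = tab$onset, duration = tab$duration,
                        condition = tab$trial_type, item_id = tab$item_id),
    total_duration_s = total_duration_s %||% (tab$onset[n] + tab$duration[n])
  )
}

#' Write / read a ROI mask as 3-D NIfTI
#'
#' Masks are 0/1 volumes; on reading, voxels strictly above 0.5 are taken as
#' inside the mask.
#'
#' @param mask an [roi_mask()] with `volume_dim` set.
#' @param path output `.nii` path.
#' @export
write_roi_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  if (is.null(mask$volume_dim)) {
    stop("mask needs volume_dim to be written as NIfTI", call. = FALSE)
  }
  vol <- array(0, dim = mask$volume_dim)
  vol[mask$voxel_indices + 1] <- 1
  RNifti::writeNifti(vol, path)
  invisible(path)
}

#' @param path mask file path.
#' @param name ROI label for the returned mask.
#' @param source provenance note.
#' @rdname write_roi_mask
#' @export
read_roi_mask <- function(path, name = tools::file_path_sans_ext(basename(path)),
                          source = path) {
  vol <- as.array(RNifti::readNifti(path))
  # NIfTI readers drop trailing singleton dimensions; restore a 3-D shape
  d <- c(dim(vol), 1L, 1L)[1:3]
  dim(vol) <- d
  idx <- which(vol > 0.5, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop(sprintf("mask %s is empty", path), call. = FALSE)
  roi_mask(name, idx - 1L, volume_dim = d, source = source)
}

#' Write / read 4-D volumes as NIfTI
#'
#' Used both for simulated BOLD runs (x, y, z, time) and for per-item beta
#' volumes (x, y, z, item).
#'
#' @param vol 4-D numeric array.
#' @param path output `.nii` path.
#' @param pixdim4 step along the fourth dimension (TR in seconds for BOLD).
#' @export
write_nifti_4d <- function(vol, path, pixdim4 = 1) {
  stopifnot(length(dim(vol)) == 4L)
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(1, 1, 1, pixdim4)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_4d
#' @export
read_nifti_4d <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 4L) {
    stop(sprintf("%s is not a 4-D image", path), call. = FALSE)
  }
  arr
}

#' Write / read tabular pipeline artifacts as CSV
#'
#' UTF-8 CSV with headers; used for behavioral tables, similarity rows,
#' learning fits, and brain-behavior results.
#'
#' @param x data frame.
#' @param path output `.csv` path.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("malformed CSV %s: %s", path,
                                     conditionMessage(e)), call. = FALSE)
  )
}

#' Read a pipeline configuration
#'
#' YAML (or JSON) configuration with the simulation, GLM, similarity, and
#' learning-fit settings; see `inst/extdata/demo_config.yaml` for the layout.
#'
#' @param path YAML/JSON file path, or an already-parsed list (returned
#'   unchanged).
#' @return Named list.
#' @export
read_config <- function(path) {
  if (is.list(path)) return(path)
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
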