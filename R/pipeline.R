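# End-to-end orchestration: in-memory cohort analysis, file-based stages,
# and the reproducibility manifest.

# Reorder a beta set's rows into canonical item_id order so that runs with
# different presentation orders can be averaged.
order_beta_items <- function(beta_set) {
  ord <- order(beta_set$items$item_id)
  beta_set$betas <- beta_set$betas[ord, , drop = FALSE]
  beta_set$items <- beta_set$items[ord, , drop = FALSE]
  beta_set
}

#' Analyse a simulated cohort end to end
#'
#' Runs the full estimation chain on a [simulate_cohort()] object: per-run
#' single-item GLM, run-averaging per condition, cross-language pattern
#' similarity per ROI, power-law learning-curve fits with the
#' goodness-of-fit inclusion rule, the training-effect repeated-measures
#' ANOVA on the RT panel, and the ROI-wise brain-behavior correlation.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param ps_method `"pairwise_mean"` or `"averaged_pattern"`.
#' @param fit_threshold learning-fit inclusion threshold (default 0.7).
#' @param add_derivatives include temporal-derivative nuisance regressors.
#' @param highpass_s high-pass cutoff in seconds.
#'
#' @return List of class `cohort_analysis`: `ps` (similarity rows), `fits`
#'   (learning fits with inclusion flags), `exclusion_report`, `anova_rt`,
#'   and `brain_behavior` (per-ROI r, p, n).
#' @export
analyze_cohort <- function(cohort, ps_method = c("pairwise_mean", "averaged_pattern"),
                           fit_threshold = 0.7, add_derivatives = TRUE,
                           highpass_s = 100) {
  stopifnot(inherits(cohort, "cohort"))
  ps_method <- match.arg(ps_method)
  design_pars <- cohort$design
  hrf <- double_gamma_hrf(dt_s = design_pars$hrf_dt_s)
  ps_fun <- switch(ps_method,
                   pairwise_mean = pairwise_cross_language_ps,
                   averaged_pattern = averaged_pattern_ps)

  ps_rows <- list()
  fit_rows <- list()
  rt_matrix <- NULL
  for (subj in cohort$subjects) {
    beta_sets <- lapply(subj$runs, function(run) {
      n_tp <- ncol(run$data)
      X <- build_design_matrix(run$schedule, run$tr_s, n_tp, hrf = hrf,
                               add_derivatives = add_derivatives)
      order_beta_items(fit_glm(run, X, highpass_s = highpass_s))
    })
    conditions <- vapply(beta_sets, `[[`, character(1), "condition")
    patterns <- lapply(c(L1 = "CW", L2 = "ALW"), function(cond) {
      average_across_runs(beta_sets[conditions == cond])
    })
    for (roi in names(subj$roi_index)) {
      idx <- subj$roi_index[[roi]]
      ps_rows[[length(ps_rows) + 1L]] <- ps_fun(
        patterns$L1$patterns[, idx, drop = FALSE],
        patterns$L2$patterns[, idx, drop = FALSE],
        participant_id = subj$participant_id, roi_name = roi
      )
    }
    fit_rows[[length(fit_rows) + 1L]] <- fit_power_law(subj$behavior)
    rt_matrix <- rbind(rt_matrix, subj$behavior$rt_ms)
  }
  ps <- do.call(rbind, ps_rows)
  selection <- select_by_fit(do.call(rbind, fit_rows), threshold = fit_threshold)
  structure(
    list(ps = ps, fits = selection$fits,
         exclusion_report = selection$report,
         anova_rt = rm_anova(rt_matrix),
         brain_behavior = correlate_ps_with_learning(ps, selection$fits)),
    class = "cohort_analysis"
  )
}

cohort_volume_dim <- function(design) {
  c(length(design$rois), design$n_voxels_roi, 1L)
}

cohort_masks <- function(design) {
  v <- design$n_voxels_roi
  dim3 <- cohort_volume_dim(design)
  lapply(seq_along(design$rois), function(r) {
    roi_mask(design$rois[r],
             cbind(r - 1L, seq_len(v) - 1L, 0L),
             volume_dim = dim3, source = "synthetic ROI layout")
  })
}

flat_to_volume <- function(mat, roi_index, dim3) {
  # mat: (all ROI voxels) x k, rows ordered as unlist(roi_index)
  arr <- array(0, c(dim3, ncol(mat)))
  for (r in seq_along(roi_index)) {
    arr[r, , 1L, ] <- mat[roi_index[[r]], , drop = FALSE]
  }
  arr
}

config_design <- function(config) {
  do.call(cohort_design, config$simulate$design %||% list())
}

#' Pipeline stages
#'
#' Individually invokable, idempotent stages of the file-based pipeline; each
#' reads its inputs from `out_dir` (as written by the previous stage), writes
#' its outputs there, and returns the paths of the files it wrote.
#' `stage_simulate` generates the synthetic cohort (BOLD runs and events per
#' subject, ROI masks, the behavioral table, and the ground truth);
#' `stage_glm` fits the single-item GLMs and writes per-condition beta
#' volumes; `stage_ps` computes cross-language pattern similarity per ROI;
#' `stage_learning` fits the learning curves and applies the inclusion rule;
#' `stage_correlate` produces the ROI-wise brain-behavior table.
#'
#' @param config configuration list or YAML/JSON path (see [read_config()]).
#' @param out_dir output directory.
#' @return Character vector of written file paths, invisibly.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_simulate <- function(config, out_dir) {
  config <- read_config(config)
  sim <- config$simulate
  if (is.null(sim)) stop("config has no `simulate` block", call. = FALSE)
  design <- config_design(config)
  cohort <- simulate_cohort(
    n_subjects = sim$n_subjects %||% 24,
    rho_distribution = unlist(sim$rho_range %||% c(0.05, 0.65)),
    link_strength = sim$link_strength %||% 0.6,
    design = design,
    seed = config$seed %||% 1
  )
  data_dir <- file.path(out_dir, "data")
  mask_dir <- file.path(data_dir, "masks")
  dir.create(mask_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()

  for (mask in cohort_masks(design)) {
    p <- file.path(mask_dir, paste0(mask$name, "_mask.nii"))
    write_roi_mask(mask, p)
    written <- c(written, p)
  }
  dim3 <- cohort_volume_dim(design)
  for (subj in cohort$subjects) {
    sub_dir <- file.path(data_dir, subj$participant_id)
    dir.create(sub_dir, showWarnings = FALSE)
    for (r in seq_along(subj$runs)) {
      run <- subj$runs[[r]]
      bold_path <- file.path(sub_dir, sprintf("run-%02d_bold.nii", r))
      write_nifti_4d(flat_to_volume(run$data, subj$roi_index, dim3),
                     bold_path, pixdim4 = run$tr_s)
      ev_path <- file.path(sub_dir, sprintf("run-%02d_events.tsv", r))
      write_events_tsv(subj$schedules[[r]], ev_path)
      written <- c(written, bold_path, ev_path)
    }
  }
  behavior <- do.call(rbind, lapply(cohort$subjects, `[[`, "behavior"))
  beh_path <- file.path(data_dir, "behavior.csv")
  write_table_csv(behavior, beh_path)
  truth_path <- file.path(data_dir, "truth.json")
  jsonlite::write_json(
    list(seed = cohort$seed, link_strength = cohort$link_strength,
         truth = cohort$truth),
    truth_path, auto_unbox = TRUE, digits = NA
  )
  invisible(c(written, beh_path, truth_path))
}

pipeline_subjects <- function(out_dir) {
  dirs <- list.dirs(file.path(out_dir, "data"), recursive = FALSE)
  dirs <- dirs[grepl("sub-", basename(dirs))]
  if (!length(dirs)) stop("no subject data found under ", out_dir, call. = FALSE)
  dirs
}

#' @rdname pipeline_stages
#' @export
stage_glm <- function(config, out_dir) {
  config <- read_config(config)
  glm_cfg <- config$glm %||% list()
  tr_s <- glm_cfg$tr_s %||% 2
  hrf <- double_gamma_hrf(dt_s = glm_cfg$hrf_dt_s %||% 0.1)
  glm_dir <- file.path(out_dir, "glm")
  dir.create(glm_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()

  for (sub_dir in pipeline_subjects(out_dir)) {
    pid <- basename(sub_dir)
    ev_files <- sort(list.files(sub_dir, pattern = "events\\.tsv$",
                                full.names = TRUE))
    beta_sets <- lapply(seq_along(ev_files), function(r) {
      bold <- read_nifti_4d(sub("events\\.tsv$", "bold.nii", ev_files[r]))
      d <- dim(bold)
      n_tp <- d[4]
      run <- list(data = matrix(bold, prod(d[1:3]), n_tp),  # column-major voxels
                  tr_s = tr_s,
                  schedule = read_events_tsv(ev_files[r], run_index = r,
                                             total_duration_s = n_tp * tr_s))
      X <- build_design_matrix(run$schedule, tr_s, n_tp, hrf = hrf,
                               add_derivatives = glm_cfg$add_derivatives %||% TRUE)
      order_beta_items(fit_glm(run, X, highpass_s = glm_cfg$highpass_s %||% 100))
    })
    conditions <- vapply(beta_sets, `[[`, character(1), "condition")
    dim3 <- dim(read_nifti_4d(sub("events\\.tsv$", "bold.nii", ev_files[1])))[1:3]
    for (cond in unique(conditions)) {
      avg <- average_across_runs(beta_sets[conditions == cond])
      # flat voxel order of run$data is column-major over the volume
      vol <- array(t(avg$patterns), c(dim3, nrow(avg$patterns)))
      p <- file.path(glm_dir, sprintf("%s_desc-%s_betas.nii", pid, cond))
      write_nifti_4d(vol, p)
      written <- c(written, p)
    }
  }
  invisible(written)
}

#' @rdname pipeline_stages
#' @export
stage_ps <- function(config, out_dir) {
  config <- read_config(config)
  method <- config$ps_method %||% "pairwise_mean"
  ps_fun <- switch(method,
                   pairwise_mean = pairwise_cross_language_ps,
                   averaged_pattern = averaged_pattern_ps,
                   stop("unknown ps_method: ", method, call. = FALSE))
  mask_files <- list.files(file.path(out_dir, "data", "masks"),
                           pattern = "_mask\\.nii$", full.names = TRUE)
  if (!length(mask_files)) stop("no ROI masks found under ", out_dir, call. = FALSE)
  masks <- lapply(mask_files, function(p) {
    read_roi_mask(p, name = sub("_mask$", "", tools::file_path_sans_ext(basename(p))))
  })
  glm_dir <- file.path(out_dir, "glm")
  ps_rows <- list()
  for (sub_dir in pipeline_subjects(out_dir)) {
    pid <- basename(sub_dir)
    betas <- lapply(c(L1 = "CW", L2 = "ALW"), function(cond) {
      read_nifti_4d(file.path(glm_dir, sprintf("%s_desc-%s_betas.nii", pid, cond)))
    })
    for (mask in masks) {
      ps_rows[[length(ps_rows) + 1L]] <- ps_fun(
        extract_roi_patterns(betas$L1, mask),
        extract_roi_patterns(betas$L2, mask),
        participant_id = pid, roi_name = mask$name
      )
    }
  }
  ps_path <- file.path(out_dir, "ps.csv")
  write_table_csv(do.call(rbind, ps_rows), ps_path)
  invisible(ps_path)
}

#' @rdname pipeline_stages
#' @export
stage_learning <- function(config, out_dir) {
  config <- read_config(config)
  behavior <- read_table_csv(file.path(out_dir, "data", "behavior.csv"))
  fits <- do.call(rbind, lapply(split(behavior, behavior$participant_id),
                                fit_power_law))
  selection <- select_by_fit(fits, threshold = config$fit_threshold %||% 0.7)
  fits_path <- file.path(out_dir, "learning_fits.csv")
  write_table_csv(selection$fits, fits_path)
  report_path <- file.path(out_dir, "exclusion_report.json")
  jsonlite::write_json(selection$report, report_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(fits_path, report_path))
}

#' @rdname pipeline_stages
#' @export
stage_correlate <- function(config, out_dir) {
  config <- read_config(config)
  ps <- read_table_csv(file.path(out_dir, "ps.csv"))
  fits <- read_table_csv(file.path(out_dir, "learning_fits.csv"))
  result <- correlate_ps_with_learning(ps, fits)
  res_path <- file.path(out_dir, "brain_behavior.csv")
  write_table_csv(result, res_path)
  summary_path <- file.path(out_dir, "brain_behavior_summary.json")
  jsonlite::write_json(result, summary_path, auto_unbox = TRUE, digits = NA)
  invisible(c(res_path, summary_path))
}

#' Run the full pipeline
#'
#' Executes simulate (when the config has a `simulate` block) then GLM,
#' pattern similarity, learning-curve fitting, and the brain-behavior
#' correlation, and writes a manifest with content digests of every stage
#' output. Re-running with an identical config and seed reproduces identical
#' digests. Without a `simulate` block, the config must name an existing
#' `paths$data_dir` laid out like `stage_simulate`'s output; missing inputs
#' fail before any computation.
#'
#' @param config configuration list or YAML/JSON path.
#' @param out_dir output directory (defaults to `config$out_dir`).
#'
#' @return The manifest, invisibly: per-stage output digests, the config
#'   snapshot, package version, and timestamp.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- read_config(config)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("an output directory is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stages <- list()
  if (!is.null(config$simulate)) {
    stages$simulate <- function() stage_simulate(config, out_dir)
  } else {
    paths <- config$paths %||% list()
    data_dir <- paths$data_dir
    if (is.null(data_dir) || !dir.exists(data_dir)) {
      stop("config$paths$data_dir does not exist: ",
           data_dir %||% "<missing>", call. = FALSE)
    }
    required <- c(file.path(data_dir, "behavior.csv"),
                  file.path(data_dir, "masks"))
    missing <- required[!file.exists(required)]
    if (length(missing)) {
      stop("missing pipeline inputs: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    if (normalizePath(data_dir) != normalizePath(file.path(out_dir, "data"),
                                                 mustWork = FALSE)) {
      stop("paths$data_dir must be <out_dir>/data", call. = FALSE)
    }
  }
  stages$glm <- function() stage_glm(config, out_dir)
  stages$ps <- function() stage_ps(config, out_dir)
  stages$learning <- function() stage_learning(config, out_dir)
  stages$correlate <- function() stage_correlate(config, out_dir)

  manifest <- list(config = config,
                   package_version = as.character(utils::packageVersion("pslearn")),
                   created = format(Sys.time(), tz = "UTC"),
                   stages = list())
  for (stage_name in names(stages)) {
    outputs <- tryCatch(stages[[stage_name]](), error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", stage_name,
                   conditionMessage(e)), call. = FALSE)
    })
    rel <- sub(paste0("^", normalizePath(out_dir), "/?"), "",
               normalizePath(outputs))
    manifest$stages[[stage_name]] <-
      stats::setNames(as.list(unname(tools::md5sum(outputs))), rel)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
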