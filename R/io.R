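# File formats and the end-to-end pipeline. Images travel as NIfTI with the
# cardiac-phase axis in the 4th dimension (NIfTI has no native cardiac-phase
# semantics, so cycle duration lives in the config / JSON sidecar).

INTEGER_PHASE_SCALE <- 4096  # integer dialect: phi = stored * pi / 4096

series_to_nifti_array <- function(values) {
  d <- dim(values)
  array(values, dim = c(d[1], d[2], 1L, d[3]))
}

#' Write an image series as 4D NIfTI
#'
#' Layout is `x * y * 1 * n_phases`; voxel sizes from the acquisition
#' parameters are written into the header. Phase series are written in the
#' requested dialect: `"radians"` (float, values as-is) or `"integer"`
#' (values scaled by `4096 / pi`, the two's-complement scanner convention in
#' which -4096 maps to -pi).
#'
#' @param series A [phase_series] or [magnitude_series].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param dialect Phase storage dialect; ignored for magnitude series.
#' @return `path`, invisibly.
#' @export
write_image_series <- function(series, path,
                               dialect = c("radians", "integer")) {
  dialect <- match.arg(dialect)
  values <- series$values
  if (inherits(series, "phase_series") && dialect == "integer")
    values <- round(values * INTEGER_PHASE_SCALE / pi)
  p <- series$params
  img <- RNifti::asNifti(series_to_nifti_array(values))
  RNifti::pixdim(img) <- c(p$voxel_dx, p$voxel_dy, p$slice_dz,
                           phase_dt_ms(p) / 1000)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an image series from NIfTI
#'
#' Accepts 4D `x * y * 1 * n_phases` or 3D `x * y * n_phases` layouts. For
#' phase series, values are mapped into `[-pi, pi)` according to the storage
#' dialect: `"radians"` (stored as floating-point radians; wrapped if
#' marginally outside the interval) or `"integer"` (scanner integer units,
#' linear map `phi = stored * pi / 4096`). Voxel sizes in the header are
#' cross-checked against `params`; on mismatch a warning is raised and the
#' configured values win.
#'
#' @param path NIfTI file path.
#' @param params An [acq_params]; `n_phases` must match the file.
#' @param kind `"phase"` or `"magnitude"`.
#' @param dialect Phase storage dialect (see above).
#' @return A [phase_series] or [magnitude_series].
#' @export
read_image_series <- function(path, params, kind = c("phase", "magnitude"),
                              dialect = c("radians", "integer")) {
  kind <- match.arg(kind)
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4 && d[3] == 1) {
    arr <- array(as.numeric(img), dim = c(d[1], d[2], d[4]))
  } else if (length(d) == 3) {
    arr <- array(as.numeric(img), dim = d)
  } else {
    stop("expected a 4D (x, y, 1, phases) or 3D (x, y, phases) image, got dims ",
         paste(d, collapse = " x "))
  }
  np <- dim(arr)[3]
  if (np != params$n_phases)
    stop(sprintf("file has %d cardiac phases but config declares %d (%s)",
                 np, params$n_phases, path))
  pd <- RNifti::pixdim(img)
  if (!is.null(pd) && length(pd) >= 2 &&
      (abs(pd[1] - params$voxel_dx) > 1e-4 || abs(pd[2] - params$voxel_dy) > 1e-4))
    warning(sprintf("header voxel size (%g x %g mm) differs from config (%g x %g mm); config wins",
                    pd[1], pd[2], params$voxel_dx, params$voxel_dy))
  if (kind == "magnitude") return(magnitude_series(arr, params))
  if (dialect == "integer") arr <- arr * pi / INTEGER_PHASE_SCALE
  phase_series(wrap_phase(arr), params)
}

#' Write / read an ROI mask as NIfTI
#'
#' @param roi An [roi_mask] (written as 0/1).
#' @param path NIfTI path.
#' @return `path` / an [roi_mask].
#' @export
write_roi_mask <- function(roi, path) {
  stopifnot(inherits(roi, "roi_mask"))
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(roi$mask),
                                           dim = c(dim(roi$mask), 1L))), path)
  invisible(path)
}

#' @rdname write_roi_mask
#' @param params An [acq_params] (supplies the voxel area on read).
#' @export
read_roi_mask <- function(path, params) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  m <- if (length(d) == 3) array(as.numeric(img), d)[, , 1] else as.matrix(img)
  roi_mask(m > 0.5, params$voxel_dx * params$voxel_dy)
}

#' Write a phantom dataset to disk
#'
#' Writes the magnitude and phase series (NIfTI), the canal ROI mask (NIfTI)
#' and a JSON ground-truth sidecar (true waveform, metrics and an echo of
#' the generating spec) into a directory.
#'
#' @param phantom A `csf_phantom` from [generate_phantom()].
#' @param dir Output directory (created if needed).
#' @param dialect Phase storage dialect.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_phantom_dataset <- function(phantom, dir,
                                  dialect = c("radians", "integer")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(phantom, "csf_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(magnitude = file.path(dir, "magnitude.nii.gz"),
             phase = file.path(dir, "phase.nii.gz"),
             mask = file.path(dir, "mask.nii.gz"),
             truth = file.path(dir, "truth.json"))
  write_image_series(phantom$magnitude, paths["magnitude"])
  write_image_series(phantom$phase, paths["phase"], dialect = dialect)
  write_roi_mask(phantom$truth$mask, paths["mask"])
  truth <- list(
    waveform_true = phantom$truth$waveform_true$q,
    dt_ms = phantom$truth$waveform_true$dt_ms,
    metrics_true = unclass(phantom$truth$metrics_true),
    spec = unclass(phantom$spec),
    params = unclass(phantom$params))
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write / read a cohort table as CSV
#'
#' @param table A cohort data.frame.
#' @param path CSV path.
#' @return `path` / the table (class `csf_cohort`).
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(tab) <- c("csf_cohort", "data.frame")
  tab
}

#' Pipeline configuration
#'
#' All knobs of the end-to-end pipeline in one serializable list. Defaults
#' follow the reference spinal-canal protocol (VENC 10 cm/s, 40 cardiac
#' phases, 453 ms cycle, 0.47 x 0.47 x 3.1 mm voxels) and the analysis
#' conventions (temporal unwrapping anchored at the first cardiac phase,
#' first-order background surface, Spearman correlations, p < 0.05
#' uncorrected).
#'
#' @param venc,voxel_dx,voxel_dy,slice_dz,n_phases,cycle_ms See [acq_params()].
#' @param dialect Phase storage dialect, `"radians"` or `"integer"`.
#' @param unwrap Run temporal unwrapping.
#' @param unwrap_anchor Anchor cardiac phase (1-based).
#' @param bg_correct Run background correction.
#' @param bg_order Background surface order (0, 1 or 2).
#' @param method Correlation method for the association stage.
#' @param alpha Significance threshold.
#' @param seed Integer seed for simulation stages.
#' @param out_dir Output directory.
#' @return Object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(venc = 10, voxel_dx = 0.47, voxel_dy = 0.47,
                            slice_dz = 3.1, n_phases = 40, cycle_ms = 453,
                            dialect = "radians", unwrap = TRUE,
                            unwrap_anchor = 1L, bg_correct = TRUE,
                            bg_order = 1L, method = "spearman", alpha = 0.05,
                            seed = 1L, out_dir = tempfile("csfpulse_run_")) {
  cfg <- list(venc = venc, voxel_dx = voxel_dx, voxel_dy = voxel_dy,
              slice_dz = slice_dz, n_phases = as.integer(n_phases),
              cycle_ms = cycle_ms, dialect = dialect, unwrap = unwrap,
              unwrap_anchor = as.integer(unwrap_anchor),
              bg_correct = bg_correct, bg_order = as.integer(bg_order),
              method = method, alpha = alpha, seed = as.integer(seed),
              out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

config_params <- function(cfg) {
  acq_params(venc = cfg$venc, voxel_dx = cfg$voxel_dx, voxel_dy = cfg$voxel_dy,
             slice_dz = cfg$slice_dz, n_phases = cfg$n_phases,
             cycle_ms = cfg$cycle_ms)
}

#' Read / write a pipeline configuration as YAML
#'
#' Serialization round-trips losslessly: `read_config(write_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param cfg A [pipeline_config].
#' @param path YAML file path.
#' @return `path` / a [pipeline_config].
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, raw)
  cfg
}

run_stage <- function(name, input, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed on %s: %s", name, input,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the end-to-end pipeline
#'
#' Either processes existing files (phase/magnitude/mask NIfTI per subject)
#' or, with `simulate = TRUE`, sources everything from the phantom and
#' cohort modules: a cohort table is drawn, one phantom per subject is
#' generated with its waveform scaled by the subject's latent pulsatility,
#' each phantom is reconstructed (unwrap, velocity scaling, background
#' correction) and metered, the measured metrics replace the generated
#' metric columns, and the association report is produced. All intermediate
#' artifacts are written under `cfg$out_dir` with MD5 checksums recorded in
#' a JSON run manifest; reruns with the same config and seed are
#' byte-identical.
#'
#' @param cfg A [pipeline_config].
#' @param simulate Source inputs from the simulator (default `TRUE`).
#' @param n_subjects Cohort size in simulate mode.
#' @param inputs In non-simulate mode, a data.frame with columns
#'   `subject_id, phase, magnitude, mask` (file paths) plus a cohort CSV path
#'   in `cohort_csv` attribute or argument.
#' @param cohort_csv Path to a biomarker cohort CSV (non-simulate mode).
#' @return The run manifest (list, class `run_manifest`), invisibly; side
#'   effect: files under `cfg$out_dir`.
#' @export
run_pipeline <- function(cfg, simulate = TRUE, n_subjects = 16,
                         inputs = NULL, cohort_csv = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  params <- config_params(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  warnings_log <- character(0)

  if (simulate) {
    cspec <- cohort_spec(n_subjects = n_subjects, seed = cfg$seed)
    cohort <- run_stage("simulate-cohort", "cohort_spec",
                        generate_cohort(cspec))
    # latent pulsatility per subject, recovered from the noisy peak column
    latent <- cohort$peak_flow
    subject_files <- data.frame(subject_id = cohort$subject_id,
                                phase = NA, magnitude = NA, mask = NA,
                                stringsAsFactors = FALSE)
    for (i in seq_len(n_subjects)) {
      scale_i <- latent[i] / 25
      sp <- phantom_spec(
        waveform_harmonics = list(c(1.1 * scale_i, 1, -1.021),
                                  c(0.25 * scale_i, 2, 0.5)),
        velocity_mean = 0.3 * scale_i,
        background_offset = 0.05, background_ramp = c(2e-4, -1e-4),
        noise_sd_phase = 0.02, noise_sd_magnitude = 2,
        seed = cfg$seed * 1000L + i)
      ph <- run_stage("simulate-image", cohort$subject_id[i],
                      generate_phantom(sp, params))
      sdir <- file.path(cfg$out_dir, cohort$subject_id[i])
      paths <- write_phantom_dataset(ph, sdir, dialect = cfg$dialect)
      subject_files$phase[i] <- paths[["phase"]]
      subject_files$magnitude[i] <- paths[["magnitude"]]
      subject_files$mask[i] <- paths[["mask"]]
    }
    inputs <- subject_files
  } else {
    if (is.null(inputs)) stop("inputs are required when simulate = FALSE")
    if (is.null(cohort_csv)) stop("cohort_csv is required when simulate = FALSE")
    cohort <- run_stage("read-cohort", cohort_csv, read_cohort(cohort_csv))
  }
  timings["simulate"] <- proc.time()[["elapsed"]] - t0

  t1 <- proc.time()[["elapsed"]]
  metrics_rows <- vector("list", nrow(inputs))
  for (i in seq_len(nrow(inputs))) {
    for (col in c("phase", "magnitude", "mask"))
      if (!file.exists(inputs[[col]][i]))
        stop(sprintf("pipeline stage 'reconstruct' failed on %s: file not found: %s",
                     inputs$subject_id[i], inputs[[col]][i]), call. = FALSE)
    phs <- run_stage("reconstruct", inputs$phase[i],
                     read_image_series(inputs$phase[i], params,
                                       kind = "phase", dialect = cfg$dialect))
    mag <- run_stage("reconstruct", inputs$magnitude[i],
                     read_image_series(inputs$magnitude[i], params,
                                       kind = "magnitude"))
    roi <- run_stage("reconstruct", inputs$mask[i],
                     read_roi_mask(inputs$mask[i], params))
    vel <- run_stage("reconstruct", inputs$subject_id[i], {
      x <- phs
      if (cfg$unwrap) {
        x <- withCallingHandlers(
          unwrap_temporal(x, anchor = cfg$unwrap_anchor),
          warning = function(w) {
            warnings_log <<- c(warnings_log,
                               paste0(inputs$subject_id[i], ": ",
                                      conditionMessage(w)))
            invokeRestart("muffleWarning")
          })
      }
      v <- phase_to_velocity(x)
      if (cfg$bg_correct) {
        static <- auto_static_mask(v, mag) & !roi$mask
        v <- correct_background(v, static, order = cfg$bg_order)
      }
      v
    })
    w <- run_stage("metrics", inputs$subject_id[i], compute_waveform(vel, roi))
    metrics_rows[[i]] <- cbind(subject_id = inputs$subject_id[i],
                               as.data.frame(compute_metrics(w)))
  }
  measured <- do.call(rbind, metrics_rows)
  timings["reconstruct_metrics"] <- proc.time()[["elapsed"]] - t1

  t2 <- proc.time()[["elapsed"]]
  assembled <- merge(cohort[, setdiff(names(cohort), flow_metric_columns())],
                     measured, by = "subject_id", sort = TRUE)
  class(assembled) <- c("csf_cohort", "data.frame")
  metrics_csv <- file.path(cfg$out_dir, "cohort_metrics.csv")
  write_cohort(format_numeric_df(assembled), metrics_csv)
  report <- run_stage("associate", metrics_csv,
                      run_association_report(assembled, method = cfg$method,
                                             alpha = cfg$alpha))
  report_json <- file.path(cfg$out_dir, "association_report.json")
  jsonlite::write_json(list(
    rho = report$correlations$rho, p = report$correlations$p,
    variables = colnames(report$correlations$rho),
    age_adjusted = report$age_adjusted), report_json, digits = 12,
    auto_unbox = TRUE)
  timings["associate"] <- proc.time()[["elapsed"]] - t2

  manifest <- structure(list(
    config = unclass(cfg),
    software = paste0("csfpulse ",
                      as.character(utils::packageVersion("csfpulse"))),
    n_subjects = nrow(inputs),
    checksums = as.list(tools::md5sum(c(metrics_csv, report_json))),
    timings_s = as.list(round(timings, 3)),
    warnings = warnings_log), class = "run_manifest")
  jsonlite::write_json(unclass(manifest),
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$report <- report
  manifest$cohort <- assembled
  invisible(manifest)
}

# render numeric columns at fixed precision so CSV output is byte-stable
format_numeric_df <- function(df) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- formatC(df[[j]], digits = 12,
                                                format = "g")
  df
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("csfpulse run: %d subjects, out_dir %s\n", x$n_subjects,
              x$config$out_dir))
  cat(sprintf("  stages (s): %s\n",
              paste(names(x$timings_s), unlist(x$timings_s), sep = "=",
                    collapse = ", ")))
  if (length(x$warnings)) cat(sprintf("  %d warning(s)\n", length(x$warnings)))
  invisible(x)
}
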