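# Image-series containers: thin typed wrappers around a (nx, ny, n_phases)
# numeric array plus the acquisition parameters they were measured under.

new_series <- function(values, params, class, extra = list()) {
  values <- as.array(values)
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L)
    stop("series values must be a (nx, ny, n_phases) array")
  validate_acq_params(params)
  if (dim(values)[3] != params$n_phases)
    stop(sprintf("series has %d cardiac phases but params declare %d",
                 dim(values)[3], params$n_phases))
  structure(c(list(values = values, params = params), extra), class = class)
}

#' Phase image series
#'
#' A per-voxel, per-cardiac-phase phase image in radians. Raw (wrapped)
#' series lie in `[-pi, pi)`; series returned by [unwrap_temporal()] may
#' exceed that range and carry `unwrapped = TRUE`.
#'
#' @param values Numeric array, dimensions `(nx, ny, n_phases)`.
#' @param params An [acq_params] object.
#' @param unwrapped Logical; `TRUE` if the series has been temporally
#'   unwrapped (range check then not enforced).
#' @return An object of class `phase_series`.
#' @export
phase_series <- function(values, params, unwrapped = FALSE) {
  s <- new_series(values, params, "phase_series",
                  list(unwrapped = isTRUE(unwrapped)))
  if (!s$unwrapped) {
    rng <- range(s$values)
    if (rng[1] < -pi || rng[2] >= pi)
      stop("wrapped phase values must lie in [-pi, pi)")
  }
  s
}

#' Magnitude image series
#'
#' @param values Non-negative numeric array `(nx, ny, n_phases)`.
#' @param params An [acq_params] object.
#' @return An object of class `magnitude_series`.
#' @export
magnitude_series <- function(values, params) {
  s <- new_series(values, params, "magnitude_series")
  if (any(s$values < 0)) stop("magnitude values must be >= 0")
  s
}

#' Velocity image series
#'
#' Per-voxel velocity in cm/s. Positive is cranial, negative caudal.
#'
#' @param values Numeric array `(nx, ny, n_phases)`, cm/s.
#' @param params An [acq_params] object.
#' @param unwrapped,background_corrected Provenance flags.
#' @return An object of class `velocity_series`.
#' @export
velocity_series <- function(values, params, unwrapped = FALSE,
                            background_corrected = FALSE) {
  new_series(values, params, "velocity_series",
             list(unwrapped = isTRUE(unwrapped),
                  background_corrected = isTRUE(background_corrected)))
}

series_dims <- function(s) dim(s$values)

#' @export
print.phase_series <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("phase_series %d x %d voxels, %d cardiac phases%s\n",
              d[1], d[2], d[3], if (x$unwrapped) " (unwrapped)" else ""))
  invisible(x)
}

#' @export
print.velocity_series <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "velocity_series %d x %d voxels, %d phases; unwrapped=%s, background_corrected=%s\n",
    d[1], d[2], d[3], x$unwrapped, x$background_corrected))
  invisible(x)
}

#' Region-of-interest mask
#'
#' A set of in-plane voxels (typically the spinal-canal lumen) together with
#' the in-plane voxel area, so that the cross-sectional area of the region is
#' `sum(mask) * voxel_area`.
#'
#' @param mask Logical matrix `(nx, ny)`; `TRUE` marks voxels in the region.
#' @param voxel_area In-plane voxel area, mm^2 (`voxel_dx * voxel_dy`).
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, voxel_area) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!any(mask)) stop("ROI mask is empty")
  if (!is.finite(voxel_area) || voxel_area <= 0)
    stop("voxel_area must be > 0")
  structure(list(mask = mask, voxel_area = as.numeric(voxel_area)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask: %d voxels, area %.4g mm^2\n",
              sum(x$mask), sum(x$mask) * x$voxel_area))
  invisible(x)
}

#' Circular (disk) region of interest
#'
#' Convenience constructor for a disk-shaped ROI such as a spinal-canal
#' cross-section: voxels whose centre lies within `radius_mm` of `center`
#' (in voxel coordinates) are included.
#'
#' @param nx,ny Grid dimensions, voxels.
#' @param center Numeric length-2, disk centre in voxel coordinates
#'   (may be fractional; default grid centre).
#' @param radius_mm Disk radius, mm.
#' @param params An [acq_params] object (supplies the voxel size).
#' @return An [roi_mask].
#' @export
disk_roi <- function(nx, ny, radius_mm, params,
                     center = c((nx + 1) / 2, (ny + 1) / 2)) {
  d <- disk_distance_mm(nx, ny, center, params)
  m <- d <= radius_mm
  if (!any(m)) stop("disk ROI contains no voxels")
  roi_mask(m, params$voxel_dx * params$voxel_dy)
}

# distance of each voxel centre from `center`, in mm (anisotropic voxels ok)
disk_distance_mm <- function(nx, ny, center, params) {
  xs <- (seq_len(nx) - center[1]) * params$voxel_dx
  ys <- (seq_len(ny) - center[2]) * params$voxel_dy
  sqrt(outer(xs^2, ys^2, `+`))
}
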