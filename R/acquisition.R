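#' Acquisition parameters for cardiac-gated phase-contrast MRI
#'
#' Bundles the scan settings that govern velocity encoding and decoding:
#' the velocity-encoding limit (VENC), the voxel geometry, the number of
#' reconstructed cardiac phases and the nominal cardiac-cycle duration.
#' Velocities of magnitude `venc` map to a signal phase of +/- pi; anything
#' faster aliases (wraps). Defaults correspond to a single-slice spinal-canal
#' protocol with retrospective ECG gating.
#'
#' @param venc Velocity-encoding limit, cm/s. Must be positive.
#' @param voxel_dx,voxel_dy In-plane voxel size, mm.
#' @param slice_dz Slice thickness, mm.
#' @param n_phases Number of reconstructed cardiac phases per cycle.
#' @param cycle_ms Nominal cardiac-cycle (R-R interval) duration, ms.
#'
#' @return An object of class `acq_params`.
#' @examples
#' p <- acq_params()
#' p$venc
#' @export
acq_params <- function(venc = 10, voxel_dx = 0.47, voxel_dy = 0.47,
                       slice_dz = 3.1, n_phases = 40, cycle_ms = 453) {
  p <- list(venc = as.numeric(venc),
            voxel_dx = as.numeric(voxel_dx), voxel_dy = as.numeric(voxel_dy),
            slice_dz = as.numeric(slice_dz),
            n_phases = as.integer(n_phases), cycle_ms = as.numeric(cycle_ms))
  class(p) <- "acq_params"
  validate_acq_params(p)
  p
}

validate_acq_params <- function(p) {
  stopifnot(inherits(p, "acq_params"))
  if (!is.finite(p$venc) || p$venc <= 0) stop("venc must be > 0")
  if (p$n_phases < 2) stop("n_phases must be >= 2")
  if (p$voxel_dx <= 0 || p$voxel_dy <= 0 || p$slice_dz <= 0)
    stop("voxel dimensions must be > 0")
  if (p$cycle_ms <= 0) stop("cycle_ms must be > 0")
  invisible(p)
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf(
    "PC-MRI acquisition: VENC %g cm/s, %d cardiac phases, cycle %g ms, voxels %g x %g x %g mm\n",
    x$venc, x$n_phases, x$cycle_ms, x$voxel_dx, x$voxel_dy, x$slice_dz))
  invisible(x)
}

#' Per-phase sampling interval
#'
#' @param params An [acq_params] object.
#' @return Duration of one cardiac phase, ms (`cycle_ms / n_phases`).
#' @export
phase_dt_ms <- function(params) params$cycle_ms / params$n_phases
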