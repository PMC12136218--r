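# Reconstruction: wrapped phase -> velocity. Temporal unwrapping along the
# cardiac-phase axis, polynomial background-phase correction on velocity
# units, and the linear VENC scaling.

#' Convert a phase series to a velocity series
#'
#' Elementwise velocity scaling `v = phi * VENC / pi`. Provenance flags
#' (unwrapped / background-corrected) are carried through.
#'
#' @param phase A [phase_series].
#' @return A [velocity_series] in cm/s.
#' @examples
#' p <- acq_params(venc = 10, n_phases = 2)
#' ph <- phase_series(array(pi / 2, c(1, 1, 2)), p)
#' phase_to_velocity(ph)$values[1, 1, 1]   # 5 cm/s
#' @export
phase_to_velocity <- function(phase) {
  stopifnot(inherits(phase, "phase_series"))
  velocity_series(decode_velocity(phase$values, phase$params), phase$params,
                  unwrapped = phase$unwrapped)
}

#' Temporal phase unwrapping along the cardiac cycle
#'
#' For each voxel independently, removes 2*pi discontinuities from the
#' cardiac-phase time series: whenever adjacent phases jump by more than pi
#' in magnitude, an integer multiple of 2*pi is added to the remainder of the
#' series. The value at the `anchor` phase is taken as trusted (unaliased)
#' and left unchanged; velocities that exceed VENC at other phases are
#' thereby recovered provided the true phase changes by less than pi between
#' adjacent cardiac phases. Values are only ever changed by exact multiples
#' of 2*pi, and a series that is already smooth is returned unchanged.
#'
#' Voxels whose unwrapped range exceeds `max_range` are not altered further
#' but flagged as unreliable (attribute `unreliable`, a logical matrix) and a
#' warning is raised; such excursions usually indicate noise-driven runaway
#' unwrapping rather than genuine flow.
#'
#' @param phase A [phase_series] with at least 3 cardiac phases.
#' @param anchor Index (1-based) of the cardiac phase assumed unaliased;
#'   default the first. Choose a phase of slow flow for waveforms that start
#'   near peak systole.
#' @param max_range Range limit, rad, beyond which a voxel is flagged.
#' @return A [phase_series] with `unwrapped = TRUE` and attribute
#'   `unreliable` on the object (logical `(nx, ny)` matrix).
#' @export
unwrap_temporal <- function(phase, anchor = 1L, max_range = 4 * pi) {
  stopifnot(inherits(phase, "phase_series"))
  d <- dim(phase$values)
  np <- d[3]
  if (np < 3) stop("temporal unwrapping needs at least 3 cardiac phases")
  if (anchor < 1 || anchor > np) stop("anchor phase index out of range")

  m <- matrix(phase$values, ncol = np)         # voxels x phases
  dd <- m[, -1, drop = FALSE] - m[, -np, drop = FALSE]
  offs <- -2 * pi * round(dd / (2 * pi))       # |jump| > pi gets corrected
  if (np > 2)
    for (j in 2:(np - 1)) offs[, j] <- offs[, j - 1] + offs[, j]
  u <- m
  u[, -1] <- m[, -1, drop = FALSE] + offs
  # pin the anchor phase to its original (trusted) value per voxel
  u <- u - (u[, anchor] - m[, anchor])

  rng <- u[, 1]
  rmx <- u[, 1]
  for (j in 2:np) {
    rng <- pmin(rng, u[, j])
    rmx <- pmax(rmx, u[, j])
  }
  unreliable <- matrix(rmx - rng > max_range, d[1], d[2])
  if (any(unreliable))
    warning(sprintf("%d voxel(s) exceed the %.3g rad unwrapped-range limit; flagged as unreliable",
                    sum(unreliable), max_range))

  out <- phase_series(array(u, dim = d), phase$params, unwrapped = TRUE)
  attr(out, "unreliable") <- unreliable
  out
}

#' Background-phase (eddy-current) correction
#'
#' Fits a low-order polynomial surface in the in-plane coordinates to the
#' time-averaged velocity over a static-tissue mask and subtracts the fitted
#' surface from every cardiac phase. After correction the mean velocity over
#' the static mask is zero (to numerical precision). The static mask must be
#' disjoint from the flow region of interest.
#'
#' @param velocity A [velocity_series].
#' @param static_mask An [roi_mask] (or logical matrix) of static tissue;
#'   at least 10 voxels.
#' @param order Polynomial order of the fitted surface: 0 (constant),
#'   1 (plane, default) or 2 (quadratic).
#' @return A corrected [velocity_series] with `background_corrected = TRUE`
#'   and attribute `background_fit` (the fitted surface, cm/s).
#' @export
correct_background <- function(velocity, static_mask, order = 1L) {
  stopifnot(inherits(velocity, "velocity_series"))
  if (inherits(static_mask, "roi_mask")) static_mask <- static_mask$mask
  static_mask <- as.matrix(static_mask)
  d <- dim(velocity$values)
  if (!identical(dim(static_mask), d[1:2]))
    stop("static mask dimensions do not match the velocity series")
  if (!order %in% 0:2) stop("order must be 0, 1 or 2")
  n_static <- sum(static_mask)
  if (n_static < 10)
    stop(sprintf("static mask has %d voxels; at least 10 are required for a stable surface fit",
                 n_static))

  m <- matrix(velocity$values, ncol = d[3])
  tavg <- rowMeans(m)

  xs <- (rep(seq_len(d[1]), d[2]) - (d[1] + 1) / 2)
  ys <- (rep(seq_len(d[2]), each = d[1]) - (d[2] + 1) / 2)
  X <- switch(as.character(order),
    "0" = matrix(1, length(xs), 1),
    "1" = cbind(1, xs, ys),
    "2" = cbind(1, xs, ys, xs^2, xs * ys, ys^2))

  sel <- as.vector(static_mask)
  fit <- stats::lm.fit(X[sel, , drop = FALSE], tavg[sel])
  surface <- as.vector(X %*% fit$coefficients)

  out <- velocity_series(velocity$values - array(surface, dim = d),
                         velocity$params, unwrapped = velocity$unwrapped,
                         background_corrected = TRUE)
  attr(out, "background_fit") <- matrix(surface, d[1], d[2])
  out
}

#' Derive a static-tissue mask automatically
#'
#' Selects voxels whose velocity temporal standard deviation is below a
#' percentile threshold (quiet tissue) and, when a magnitude series is
#' supplied, whose mean magnitude exceeds a floor (excluding air). Emulates
#' the invisible on-scanner selection of stationary reference tissue.
#'
#' @param velocity A [velocity_series].
#' @param magnitude Optional [magnitude_series] on the same grid.
#' @param sd_quantile Quantile of the temporal-SD distribution below which a
#'   voxel counts as static (default 0.25).
#' @param mag_quantile Quantile of the mean-magnitude distribution a static
#'   voxel must exceed (default 0.5; ignored without `magnitude`).
#' @return Logical `(nx, ny)` matrix.
#' @export
auto_static_mask <- function(velocity, magnitude = NULL,
                             sd_quantile = 0.25, mag_quantile = 0.5) {
  stopifnot(inherits(velocity, "velocity_series"))
  d <- dim(velocity$values)
  m <- matrix(velocity$values, ncol = d[3])
  sds <- sqrt(pmax(rowMeans(m^2) - rowMeans(m)^2, 0))
  keep <- sds <= stats::quantile(sds, sd_quantile)
  if (!is.null(magnitude)) {
    stopifnot(inherits(magnitude, "magnitude_series"))
    mm <- rowMeans(matrix(magnitude$values, ncol = d[3]))
    keep <- keep & mm >= stats::quantile(mm, mag_quantile)
  }
  matrix(keep, d[1], d[2])
}
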