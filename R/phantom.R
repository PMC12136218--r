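# Digital phantom: forward model for cardiac-gated PC-MRI of a pulsatile
# fluid-filled canal, with analytic ground truth for every downstream stage.

# evaluate expr with a temporary RNG state seeded by `seed`; restores the
# caller's stream so phantom generation never perturbs outer simulations
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Wrap phase values into `[-pi, pi)`
#'
#' The half-open convention maps a phase of exactly `+pi` to `-pi`, matching
#' two's-complement phase storage on clinical scanners (so a velocity of
#' exactly `+VENC` encodes as `-pi`).
#'
#' @param phi Numeric vector/array of phase values, rad.
#' @return Values wrapped into `[-pi, pi)`, same shape as `phi`.
#' @export
wrap_phase <- function(phi) ((phi + pi) %% (2 * pi)) - pi

#' Encode velocity as wrapped signal phase
#'
#' Forward model of phase-contrast velocity encoding: `phi = pi * v / VENC`,
#' wrapped into `[-pi, pi)`. Velocities with `|v| < VENC` round-trip exactly
#' through [decode_velocity()]; faster flow aliases by multiples of
#' `2 * VENC`.
#'
#' @param v Velocity, cm/s (vector or array).
#' @param params An [acq_params] object (supplies VENC).
#' @return Wrapped phase, rad, same shape as `v`.
#' @examples
#' p <- acq_params(venc = 10)
#' encode_velocity(15, p) / pi   # aliases to -0.5 pi -> decodes as -5 cm/s
#' @export
encode_velocity <- function(v, params) {
  validate_acq_params(params)
  wrap_phase(pi * v / params$venc)
}

#' Decode signal phase to velocity
#'
#' The inverse velocity scaling: `v = phi * VENC / pi`. Applied to wrapped
#' phase it recovers velocities only up to aliasing; unwrap first (see
#' [unwrap_temporal()]) when `|v|` may exceed VENC.
#'
#' @param phi Phase, rad (vector or array).
#' @param params An [acq_params] object.
#' @return Velocity, cm/s.
#' @export
decode_velocity <- function(phi, params) {
  validate_acq_params(params)
  phi * params$venc / pi
}

#' Phantom specification
#'
#' Describes a synthetic single-slice PC-MRI acquisition of a circular canal
#' with pulsatile through-plane flow. The temporal waveform of the
#' canal-centre velocity is a truncated Fourier series
#' `v_c(k) = velocity_mean + sum_j A_j sin(2 pi f_j k / N + phi_j)` sampled at
#' the `N = n_phases` cardiac phases (`k = 0, ..., N-1`); the spatial profile
#' across the canal is either flat ("plug") or Poiseuille-like ("parabolic",
#' `1 - (r/R)^2`, peak at the centre). The default waveform starts caudal
#' (negative) at the R-wave, reverses to cranial flow between the 6th and 7th
#' cardiac phase, and carries a small positive mean so that cranial flow
#' volume exceeds caudal flow volume over the cycle.
#'
#' @param grid_nx,grid_ny Image dimensions, voxels.
#' @param canal_center Canal centre, voxel coordinates (length 2, may be
#'   fractional); default grid centre.
#' @param canal_radius Canal radius, mm.
#' @param waveform_harmonics List of length-3 numeric vectors
#'   `c(amplitude_cm_s, frequency_cycles_per_cardiac_cycle, phase_offset_rad)`.
#' @param velocity_mean Constant (zero-frequency) velocity component, cm/s.
#' @param velocity_profile `"parabolic"` (default) or `"plug"`.
#' @param background_offset Static phase bias, rad, added to every voxel.
#' @param background_ramp Length-2 in-plane linear phase ramp, rad/voxel
#'   (x and y coefficients, about the grid centre).
#' @param noise_sd_phase SD of additive Gaussian phase noise, rad.
#' @param noise_sd_magnitude SD of Gaussian noise on each complex channel of
#'   the magnitude image (yields Rician magnitude noise).
#' @param mag_inside,mag_outside Noise-free magnitude level inside/outside
#'   the canal (arbitrary units; fluid is bright).
#' @param seed Integer seed; phantom generation is bit-reproducible per seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_nx = 64, grid_ny = 64,
                         canal_center = c((grid_nx + 1) / 2, (grid_ny + 1) / 2),
                         canal_radius = 1.25,
                         waveform_harmonics = list(c(1.1, 1, -1.021),
                                                   c(0.25, 2, 0.5)),
                         velocity_mean = 0.3,
                         velocity_profile = c("parabolic", "plug"),
                         background_offset = 0,
                         background_ramp = c(0, 0),
                         noise_sd_phase = 0,
                         noise_sd_magnitude = 0,
                         mag_inside = 100, mag_outside = 20,
                         seed = 1L) {
  velocity_profile <- match.arg(velocity_profile)
  s <- list(grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
            canal_center = as.numeric(canal_center),
            canal_radius = as.numeric(canal_radius),
            waveform_harmonics = lapply(waveform_harmonics, as.numeric),
            velocity_mean = as.numeric(velocity_mean),
            velocity_profile = velocity_profile,
            background_offset = as.numeric(background_offset),
            background_ramp = as.numeric(background_ramp),
            noise_sd_phase = as.numeric(noise_sd_phase),
            noise_sd_magnitude = as.numeric(noise_sd_magnitude),
            mag_inside = as.numeric(mag_inside),
            mag_outside = as.numeric(mag_outside),
            seed = if (is.null(seed)) NULL else as.integer(seed))
  class(s) <- "phantom_spec"
  validate_phantom_spec(s)
  s
}

validate_phantom_spec <- function(s) {
  stopifnot(inherits(s, "phantom_spec"))
  if (s$grid_nx < 2 || s$grid_ny < 2) stop("grid must be at least 2 x 2")
  if (length(s$waveform_harmonics) < 1)
    stop("at least one waveform harmonic is required")
  for (h in s$waveform_harmonics)
    if (length(h) != 3) stop("each harmonic is c(amplitude, frequency, phase)")
  if (s$noise_sd_phase < 0 || s$noise_sd_magnitude < 0)
    stop("noise SDs must be >= 0")
  if (s$canal_radius <= 0) stop("canal_radius must be > 0")
  invisible(s)
}

# canal-centre velocity at cardiac phases k = 0..N-1, cm/s
phantom_center_waveform <- function(spec, params) {
  k <- seq_len(params$n_phases) - 1
  v <- rep(spec$velocity_mean, params$n_phases)
  for (h in spec$waveform_harmonics)
    v <- v + h[1] * sin(2 * pi * h[2] * k / params$n_phases + h[3])
  v
}

# spatial profile matrix (nx, ny): 1 (plug) or 1 - (r/R)^2 (parabolic)
# inside the canal, 0 outside
phantom_profile <- function(spec, params) {
  d <- disk_distance_mm(spec$grid_nx, spec$grid_ny, spec$canal_center, params)
  inside <- d <= spec$canal_radius
  prof <- matrix(0, spec$grid_nx, spec$grid_ny)
  if (spec$velocity_profile == "plug") {
    prof[inside] <- 1
  } else {
    prof[inside] <- 1 - (d[inside] / spec$canal_radius)^2
  }
  prof
}

#' Generate a synthetic cardiac-gated PC-MRI series with ground truth
#'
#' Builds the true velocity field (profile x waveform), encodes it as
#' wrapped phase, adds the configured static background phase (offset plus
#' in-plane linear ramp) and Gaussian phase noise, re-wraps, and produces a
#' Rician-noise magnitude series that is bright inside the canal. Ground
#' truth (true velocity, canal mask, noiseless flow waveform and its six
#' metrics) is carried alongside for validation.
#'
#' @param spec A [phantom_spec].
#' @param params An [acq_params].
#' @return A list of class `csf_phantom` with elements `magnitude`
#'   ([magnitude_series]), `phase` ([phase_series]), `truth` (list with
#'   `velocity_true`, `mask` ([roi_mask]), `waveform_true` ([flow_waveform]),
#'   `metrics_true` ([compute_metrics()] output)), plus `spec` and `params`.
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 42), acq_params())
#' ph$truth$metrics_true$peak
#' @export
generate_phantom <- function(spec, params) {
  validate_phantom_spec(spec)
  validate_acq_params(params)
  nx <- spec$grid_nx; ny <- spec$grid_ny; np <- params$n_phases

  # canal must lie fully inside the grid
  rx <- spec$canal_radius / params$voxel_dx
  ry <- spec$canal_radius / params$voxel_dy
  if (spec$canal_center[1] - rx < 1 || spec$canal_center[1] + rx > nx ||
      spec$canal_center[2] - ry < 1 || spec$canal_center[2] + ry > ny)
    stop("canal extends outside the image grid")

  prof <- phantom_profile(spec, params)
  wave <- phantom_center_waveform(spec, params)
  vel_true <- outer(prof, wave)               # (nx, ny, np), cm/s

  inside <- disk_distance_mm(nx, ny, spec$canal_center, params) <=
    spec$canal_radius
  mask <- roi_mask(inside, params$voxel_dx * params$voxel_dy)

  truth_vel <- velocity_series(vel_true, params,
                               unwrapped = TRUE, background_corrected = TRUE)
  waveform_true <- compute_waveform(truth_vel, mask)
  metrics_true <- compute_metrics(waveform_true)

  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  bg <- spec$background_offset +
    outer(spec$background_ramp[1] * (seq_len(nx) - cx),
          spec$background_ramp[2] * (seq_len(ny) - cy), `+`)

  with_seed(spec$seed, {
    phi <- pi * vel_true / params$venc + as.vector(bg)
    if (spec$noise_sd_phase > 0)
      phi <- phi + array(stats::rnorm(length(phi), 0, spec$noise_sd_phase),
                         dim = dim(phi))
    phi <- wrap_phase(phi)

    base <- ifelse(mask$mask, spec$mag_inside, spec$mag_outside)
    mag <- array(rep(base, np), dim = c(nx, ny, np))
    if (spec$noise_sd_magnitude > 0) {
      n1 <- array(stats::rnorm(length(mag), 0, spec$noise_sd_magnitude),
                  dim = dim(mag))
      n2 <- array(stats::rnorm(length(mag), 0, spec$noise_sd_magnitude),
                  dim = dim(mag))
      mag <- sqrt((mag + n1)^2 + n2^2)        # Rician
    }

    structure(list(
      magnitude = magnitude_series(mag, params),
      phase = phase_series(phi, params),
      truth = list(velocity_true = truth_vel, mask = mask,
                   waveform_true = waveform_true, metrics_true = metrics_true),
      spec = spec, params = params), class = "csf_phantom")
  })
}

#' @export
print.csf_phantom <- function(x, ...) {
  cat(sprintf("csf_phantom %d x %d, %d cardiac phases; canal %d voxels (r = %g mm)\n",
              x$spec$grid_nx, x$spec$grid_ny, x$params$n_phases,
              sum(x$truth$mask$mask), x$spec$canal_radius))
  cat(sprintf("  true peak flow %.3g mm^3/s, net stroke %.3g mm^3/s x phase\n",
              x$truth$metrics_true$peak, x$truth$metrics_true$net_stroke))
  invisible(x)
}
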