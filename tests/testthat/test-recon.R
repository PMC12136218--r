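test_that("phase-to-velocity scaling is exact and linear", {
  p <- acq_params(venc = 10, n_phases = 3)
  phs <- phase_series(array(c(pi / 2, 0, -pi / 2), c(1, 1, 3)), p)
  v <- phase_to_velocity(phs)
  expect_equal(as.vector(v$values), c(5, 0, -5))
  # linearity: scaling all phases by alpha scales all velocities by alpha
  phs2 <- phase_series(0.4 * phs$values, p)
  expect_equal(phase_to_velocity(phs2)$values, 0.4 * v$values)
})

test_that("temporal unwrapping resolves the hand-computed jump", {
  p <- acq_params(n_phases = 3)
  phs <- phase_series(array(c(0.9, -0.9, 0.9) * pi, c(1, 1, 3)), p)
  u <- unwrap_temporal(phs)
  expect_equal(as.vector(u$values), c(0.9, 1.1, 0.9) * pi)
  expect_true(u$unwrapped)
})

test_that("unwrapping is idempotent on smooth series and only adds 2*pi multiples", {
  p <- acq_params(n_phases = 12)
  set.seed(8)
  smooth <- array(cumsum(runif(12, -0.3, 0.3)), c(1, 1, 12))
  phs <- phase_series(wrap_phase(smooth), p)
  expect_equal(unwrap_temporal(phs)$values, phs$values)

  rnd <- random_phase_series(6, 6, p, seed = 21)
  u <- unwrap_temporal(rnd, max_range = Inf)
  k <- (u$values - rnd$values) / (2 * pi)
  expect_all_lt(abs(k - round(k)), 1e-9)
})

test_that("voxels with runaway unwrapped range are flagged, not altered", {
  p <- acq_params(n_phases = 8)
  # a sawtooth that keeps climbing: every step wraps, range ends up > 4 pi
  vals <- wrap_phase(array(seq(0, by = 2.5, length.out = 8), c(1, 1, 8)))
  phs <- phase_series(vals, p)
  expect_warning(u <- unwrap_temporal(phs), "unreliable")
  expect_true(attr(u, "unreliable")[1, 1])
})

test_that("aliased flow at 1.5x VENC is recovered exactly after unwrapping", {
  p <- acq_params()
  sp <- phantom_spec(waveform_harmonics = list(c(15, 1, 0)),
                     velocity_mean = 0, seed = 4)
  ph <- generate_phantom(sp, p)
  # without unwrapping the decoded peak is wrong (aliased)
  naive <- phase_to_velocity(ph$phase)
  expect_gt(max(abs(naive$values - ph$truth$velocity_true$values)), 5)
  vel <- phase_to_velocity(unwrap_temporal(ph$phase))
  expect_all_lt(abs(vel$values - ph$truth$velocity_true$values), 1e-9)
})

test_that("background correction recovers an injected constant offset", {
  p <- acq_params()
  b <- 0.23  # rad
  ph <- generate_phantom(phantom_spec(background_offset = b, seed = 9), p)
  vel <- phase_to_velocity(ph$phase)
  corr <- correct_background(vel, !ph$truth$mask$mask)
  expect_all_lt(abs(attr(corr, "background_fit") - b * p$venc / pi), 1e-9)
  expect_all_lt(abs(corr$values - ph$truth$velocity_true$values), 1e-9)
})

test_that("background correction is the identity on clean data and zeroes the static mean", {
  p <- acq_params()
  ph <- generate_phantom(phantom_spec(seed = 10), p)
  vel <- phase_to_velocity(ph$phase)
  static <- !ph$truth$mask$mask
  corr <- correct_background(vel, static)
  expect_all_lt(abs(corr$values - vel$values), 1e-12)
  tavg <- rowMeans(matrix(corr$values, ncol = p$n_phases))
  expect_lt(abs(mean(tavg[as.vector(static)])), 1e-10)
})

test_that("a linear phase ramp is removed below the noise floor", {
  p <- acq_params()
  sd_phase <- 0.05
  sp <- phantom_spec(background_ramp = c(4e-3, -2e-3),
                     noise_sd_phase = sd_phase, seed = 12)
  ph <- generate_phantom(sp, p)
  vel <- phase_to_velocity(ph$phase)
  static <- !ph$truth$mask$mask
  corr <- correct_background(vel, static)
  tavg <- rowMeans(matrix(corr$values, ncol = p$n_phases))
  resid_sd <- sd(tavg[as.vector(static)])
  noise_sd_v <- sd_phase * p$venc / pi   # per-voxel, per-phase velocity noise
  expect_lt(resid_sd, noise_sd_v)
})

test_that("background correction rejects undersized static masks", {
  p <- acq_params(n_phases = 4)
  vel <- velocity_series(array(0, c(8, 8, 4)), p)
  small <- matrix(FALSE, 8, 8); small[1:3, 1] <- TRUE
  expect_error(correct_background(vel, small), "at least 10")
})

test_that("auto static mask excludes the pulsatile canal", {
  p <- acq_params()
  ph <- generate_phantom(phantom_spec(noise_sd_phase = 0.01,
                                      noise_sd_magnitude = 1, seed = 13), p)
  vel <- phase_to_velocity(ph$phase)
  static <- auto_static_mask(vel, ph$magnitude)
  # strongly pulsing canal-core voxels must not be called static
  ctr <- round(ph$spec$canal_center)
  expect_false(static[ctr[1], ctr[2]])
  core <- abs(ph$truth$velocity_true$values[, , 11]) >
    0.5 * max(abs(ph$truth$velocity_true$values))
  expect_equal(sum(static & core), 0)
  # and a sensible share of the image is available as reference tissue
  expect_gt(mean(static), 0.1)
})
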