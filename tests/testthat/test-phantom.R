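test_that("velocity encoding wraps to [-pi, pi) with the scanner boundary convention", {
  p <- acq_params(venc = 10)
  expect_identical(encode_velocity(0, p), 0)
  # +VENC sits exactly on the boundary and aliases to -pi
  expect_equal(encode_velocity(10, p), -pi)
  # 15 cm/s at VENC 10: pi * 1.5 - 2 pi = -0.5 pi, naive decode -5 cm/s
  expect_equal(encode_velocity(15, p), -0.5 * pi)
  expect_equal(decode_velocity(encode_velocity(15, p), p), -5)
  v <- seq(-30, 30, by = 0.37)
  phi <- encode_velocity(v, p)
  expect_true(all(phi >= -pi & phi < pi))
})

test_that("encode/decode round-trips below VENC and is 2*VENC-periodic", {
  p <- acq_params(venc = 10)
  set.seed(42)
  v <- runif(2000, -9.999, 9.999)
  expect_all_lt(abs(decode_velocity(encode_velocity(v, p), p) - v), 1e-12)
  for (k in c(-2L, 1L, 3L))
    expect_all_lt(abs(encode_velocity(v + 2 * p$venc * k, p) -
                      encode_velocity(v, p)), 1e-9)
})

test_that("plug-flow waveform arithmetic matches the hand oracle", {
  # 100 voxels of 0.47 x 0.47 mm at a uniform 1 cm/s: q = 100 * 0.2209 * 10
  p <- acq_params(n_phases = 4)
  vel <- velocity_series(array(1, c(10, 10, 4)), p, unwrapped = TRUE)
  roi <- roi_mask(matrix(TRUE, 10, 10), 0.47^2)
  w <- compute_waveform(vel, roi)
  expect_equal(w$q, rep(220.9, 4), tolerance = 1e-12)

  # plug phantom: q equals n_voxels * area * 10 * waveform at every phase
  sp <- phantom_spec(waveform_harmonics = list(c(0.8, 1, 0.3)),
                     velocity_mean = 0.2, velocity_profile = "plug", seed = 7)
  ph <- generate_phantom(sp, acq_params())
  nvox <- sum(ph$truth$mask$mask)
  k <- 0:39
  wave <- 0.2 + 0.8 * sin(2 * pi * k / 40 + 0.3)
  expect_equal(ph$truth$waveform_true$q, nvox * 0.47^2 * 10 * wave,
               tolerance = 1e-12)
})

test_that("a pure harmonic integrates to zero net stroke over the cycle", {
  sp <- phantom_spec(waveform_harmonics = list(c(1.5, 1, 0.9)),
                     velocity_mean = 0, seed = 3)
  ph <- generate_phantom(sp, acq_params())
  scale <- ph$truth$metrics_true$absolute_stroke
  expect_lt(abs(ph$truth$metrics_true$net_stroke), 1e-10 * scale)
  expect_equal(ph$truth$metrics_true$cranial_volume,
               ph$truth$metrics_true$caudal_volume, tolerance = 1e-10)
})

test_that("phantom generation is bit-reproducible per seed and validates geometry", {
  p <- acq_params()
  sp <- phantom_spec(noise_sd_phase = 0.1, noise_sd_magnitude = 3, seed = 11)
  a <- generate_phantom(sp, p)
  b <- generate_phantom(sp, p)
  expect_identical(a$phase$values, b$phase$values)
  expect_identical(a$magnitude$values, b$magnitude$values)
  # canal must fit inside the grid
  expect_error(generate_phantom(phantom_spec(grid_nx = 16, grid_ny = 16,
                                             canal_radius = 6), p),
               "outside")
  # canal is bright in the magnitude image
  inside <- a$truth$mask$mask
  expect_gt(mean(a$magnitude$values[, , 1][inside]),
            2 * mean(a$magnitude$values[, , 1][!inside]))
})

test_that("noisy phase stays wrapped and noiseless phase decodes to truth", {
  p <- acq_params()
  ph <- generate_phantom(phantom_spec(noise_sd_phase = 0.5, seed = 2), p)
  expect_true(all(ph$phase$values >= -pi & ph$phase$values < pi))
  ph0 <- generate_phantom(phantom_spec(seed = 2), p)
  vel <- phase_to_velocity(ph0$phase)
  expect_all_lt(abs(vel$values - ph0$truth$velocity_true$values), 1e-12)
})

test_that("cohort generator enforces the degrees-of-freedom guard", {
  expect_error(cohort_spec(n_subjects = 3), "n_subjects")
  expect_error(cohort_spec(age_range = c(27, 10)), "age_range")
  expect_s3_class(cohort_spec(n_subjects = 4), "cohort_spec")
})

test_that("cohort tables are deterministic per seed with exact metric identities", {
  s <- cohort_spec(seed = 5)
  a <- generate_cohort(s)
  b <- generate_cohort(s)
  expect_identical(a, b)
  expect_equal(a$net_stroke, a$cranial_volume - a$caudal_volume)
  expect_equal(a$absolute_stroke, a$cranial_volume + a$caudal_volume)
  expect_true(all(a$age_years >= 10 & a$age_years <= 27))
  expect_equal(nrow(a), 16)
})

test_that("empirical cohort correlations converge to the configured population values", {
  tab <- generate_cohort(cohort_spec(n_subjects = 5000, seed = 123))
  sp_age_peak <- cor(rank(tab$age_years), rank(tab$peak_flow))
  expect_lt(abs(sp_age_peak - (-0.75)), 0.03)
  pc <- partial_correlation(tab, "peak_flow", "csf_ab42_40_ratio",
                            "age_years", method = "spearman")
  expect_lt(abs(pc$rho_partial - 0.70), 0.03)
  # caudal flow volume runs against the other metrics
  expect_gt(cor(rank(tab$age_years), rank(tab$caudal_volume)), 0.5)
})

test_that("a null flow-ratio effect yields a near-zero age-adjusted correlation", {
  tab <- generate_cohort(cohort_spec(n_subjects = 5000, beta_flow_ratio = 0,
                                     seed = 77))
  pc <- partial_correlation(tab, "peak_flow", "csf_ab42_40_ratio", "age_years")
  expect_lt(abs(pc$rho_partial), 0.05)
})
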