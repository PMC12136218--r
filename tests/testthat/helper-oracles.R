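# Shared fixtures and independent oracles for the test suite.

METRIC_KEYS <- c("cranial_volume", "caudal_volume", "net_stroke",
                 "absolute_stroke", "amplitude", "peak")

# Scale-floored relative error: |a - b| / max(|b|, floor). The floor (the
# waveform's absolute stroke volume by default) keeps the measure meaningful
# for metrics whose true value is ~0 (e.g. net stroke of a pure sine), where
# a raw relative error would divide by rounding noise.
metric_rel_errors <- function(measured, truth) {
  floor_scale <- abs(truth$absolute_stroke)
  vapply(METRIC_KEYS, function(k)
    abs(measured[[k]] - truth[[k]]) / max(abs(truth[[k]]), floor_scale * 1e-9,
                                          .Machine$double.xmin),
    numeric(1))
}

# Independent reference for first-order partial correlation: the inverse of
# the 3x3 correlation matrix, r_xy.z = -P_xy / sqrt(P_xx P_yy). Shares no
# code path with either route inside partial_correlation().
ref_partial_inverse <- function(x, y, z) {
  R <- stats::cor(cbind(x, y, z))
  P <- solve(R)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# random wrapped phase series fixture
random_phase_series <- function(nx, ny, params, seed) {
  set.seed(seed)
  phase_series(array(stats::runif(nx * ny * params$n_phases, -pi, pi * 0.999),
                     dim = c(nx, ny, params$n_phases)), params)
}

expect_all_lt <- function(x, bound) expect_lt(max(x), bound)
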