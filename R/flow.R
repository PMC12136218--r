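# Flow quantification: ROI velocity -> flow-rate waveform -> the six
# cardiac-cycle CSF flow metrics.

#' Flow-rate waveform over the cardiac cycle
#'
#' @param q Numeric vector of flow rates per cardiac phase, mm^3/s. Positive
#'   is cranial, negative caudal.
#' @param dt_ms Duration of one cardiac phase, ms.
#' @return An object of class `flow_waveform`.
#' @export
flow_waveform <- function(q, dt_ms) {
  q <- as.numeric(q)
  if (length(q) < 2) stop("waveform needs at least 2 cardiac phases")
  if (!is.finite(dt_ms) || dt_ms <= 0) stop("dt_ms must be > 0")
  structure(list(q = q, dt_ms = as.numeric(dt_ms)), class = "flow_waveform")
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf("flow_waveform: %d cardiac phases, dt %.3g ms, range [%.4g, %.4g] mm^3/s\n",
              length(x$q), x$dt_ms, min(x$q), max(x$q)))
  invisible(x)
}

#' @export
plot.flow_waveform <- function(x, ...) {
  graphics::plot((seq_along(x$q) - 1) * x$dt_ms, x$q, type = "b",
                 xlab = "time in cardiac cycle (ms)",
                 ylab = expression(paste("flow rate (", mm^3, "/s)")), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Integrate an ROI velocity series into a flow-rate waveform
#'
#' Per cardiac phase, the flow rate is the per-voxel sum of velocity times
#' voxel area: `q[k] = sum_vox v[vox, k] * 10 * voxel_area` (the factor 10
#' converts cm/s to mm/s so that q is in mm^3/s). Summing voxel-by-voxel
#' (rather than mean velocity times total area) is exact for uniform masks
#' and robust when the mask covers only part of the lumen.
#'
#' @param velocity A [velocity_series], cm/s.
#' @param roi An [roi_mask] within the image bounds.
#' @return A [flow_waveform].
#' @export
compute_waveform <- function(velocity, roi) {
  stopifnot(inherits(velocity, "velocity_series"), inherits(roi, "roi_mask"))
  d <- dim(velocity$values)
  if (!identical(dim(roi$mask), d[1:2]))
    stop("ROI dimensions do not match the velocity series")
  sel <- as.vector(roi$mask)
  m <- matrix(velocity$values, ncol = d[3])[sel, , drop = FALSE]
  q <- colSums(m) * 10 * roi$voxel_area
  flow_waveform(q, phase_dt_ms(velocity$params))
}

#' The six cardiac-cycle CSF flow metrics
#'
#' From a flow-rate waveform `q` (mm^3/s, one sample per cardiac phase):
#' cranial flow volume `sum(max(q, 0))`, caudal flow volume
#' `sum(max(-q, 0))`, net stroke volume `sum(q)`, absolute stroke volume
#' `sum(|q|)`, flow-rate amplitude `max(q) - min(q)` (peak-to-peak) and peak
#' flow rate `max(|q|)`. The four volume metrics are reported both as raw
#' phase-sums (mm^3/s x cardiac phase, the conventional reporting unit) and
#' time-integrated (multiplied by the phase duration in seconds, mm^3, as
#' `*_mm3` fields). Identities: `net = cranial - caudal`,
#' `absolute = cranial + caudal`, `peak <= amplitude <= 2 * peak`.
#'
#' @param w A [flow_waveform].
#' @return An object of class `flow_metrics`: list with `cranial_volume`,
#'   `caudal_volume`, `net_stroke`, `absolute_stroke` (phase-sum units),
#'   their `_mm3` counterparts, `amplitude` and `peak` (mm^3/s).
#' @examples
#' compute_metrics(flow_waveform(c(3, 1, -2, -2), dt_ms = 100))
#' @export
compute_metrics <- function(w) {
  stopifnot(inherits(w, "flow_waveform"))
  q <- w$q
  cranial <- sum(pmax(q, 0))
  caudal <- sum(pmax(-q, 0))
  dt_s <- w$dt_ms / 1000
  structure(list(
    cranial_volume = cranial, caudal_volume = caudal,
    net_stroke = sum(q), absolute_stroke = sum(abs(q)),
    cranial_volume_mm3 = cranial * dt_s, caudal_volume_mm3 = caudal * dt_s,
    net_stroke_mm3 = sum(q) * dt_s, absolute_stroke_mm3 = sum(abs(q)) * dt_s,
    amplitude = max(q) - min(q), peak = max(abs(q)),
    n_phases = length(q), dt_ms = w$dt_ms), class = "flow_metrics")
}

#' @export
print.flow_metrics <- function(x, ...) {
  cat("CSF flow metrics over one cardiac cycle\n")
  cat(sprintf("  cranial flow volume : %10.4g mm^3/s x phase  (%.4g mm^3)\n",
              x$cranial_volume, x$cranial_volume_mm3))
  cat(sprintf("  caudal flow volume  : %10.4g mm^3/s x phase  (%.4g mm^3)\n",
              x$caudal_volume, x$caudal_volume_mm3))
  cat(sprintf("  net stroke volume   : %10.4g mm^3/s x phase  (%.4g mm^3)\n",
              x$net_stroke, x$net_stroke_mm3))
  cat(sprintf("  absolute stroke vol.: %10.4g mm^3/s x phase  (%.4g mm^3)\n",
              x$absolute_stroke, x$absolute_stroke_mm3))
  cat(sprintf("  flow-rate amplitude : %10.4g mm^3/s (peak-to-peak)\n",
              x$amplitude))
  cat(sprintf("  peak flow rate      : %10.4g mm^3/s\n", x$peak))
  invisible(x)
}

#' @export
as.data.frame.flow_metrics <- function(x, ...) {
  data.frame(cranial_volume = x$cranial_volume, caudal_volume = x$caudal_volume,
             net_stroke = x$net_stroke, absolute_stroke = x$absolute_stroke,
             amplitude = x$amplitude, peak_flow = x$peak)
}

#' Locate flow-reversal (zero-crossing) intervals
#'
#' Finds, cyclically, each adjacent pair of cardiac phases between which the
#' flow rate changes sign, and linearly interpolates the fractional crossing
#' phase. A waveform of constant sign yields zero rows.
#'
#' @param w A [flow_waveform].
#' @return A data.frame with columns `from`, `to` (1-based phase indices,
#'   `to` cyclically follows `from`) and `phase` (fractional crossing
#'   position on the 0-based phase axis).
#' @export
find_flow_reversal <- function(w) {
  stopifnot(inherits(w, "flow_waveform"))
  q <- w$q
  n <- length(q)
  nxt <- c(2:n, 1)
  cross <- which(q * q[nxt] < 0)
  frac <- q[cross] / (q[cross] - q[nxt[cross]])
  data.frame(from = cross, to = nxt[cross],
             phase = (cross - 1) + frac)
}
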