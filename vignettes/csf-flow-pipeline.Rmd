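---
title: "Quantifying pulsatile CSF flow from cardiac-gated PC-MRI: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pulsatile CSF flow from cardiac-gated PC-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfpulse)
```

`csfpulse` measures pulsatile cerebrospinal fluid (CSF) flow in the spinal
canal from cardiac-gated phase-contrast MRI (PC-MRI) and relates the
resulting flow metrics, age-adjusted, to fluid biomarkers. This vignette is
the package's account of the underlying models, the numerical and design
choices, and what the test suite does and does not demonstrate.

## The measurement model

PC-MRI encodes through-plane velocity into the signal phase. With a
velocity-encoding limit VENC (cm/s), a voxel moving at velocity $v$ acquires
phase $\varphi = \pi v / \mathrm{VENC}$, observed wrapped into $[-\pi, \pi)$.
Decoding is the linear map $v = \varphi \cdot \mathrm{VENC} / \pi$. Two
artifacts intervene before decoding is valid:

* **Aliasing.** $|v| \ge \mathrm{VENC}$ wraps by multiples of
  $2\,\mathrm{VENC}$. We unwrap *temporally*: for each voxel, the
  cardiac-phase time series is scanned for adjacent jumps exceeding $\pi$ in
  magnitude, and the remainder of the series is shifted by the compensating
  multiple of $2\pi$. The first cardiac phase anchors the series (assumed
  unaliased; configurable for waveforms that start near peak systole).
  Temporal rather than spatial unwrapping is appropriate here because the
  flow region is a few voxels wide while the time series is smooth — the true
  phase changes by much less than $\pi$ between adjacent cardiac phases at
  physiological rates. Values are only ever changed by exact multiples of
  $2\pi$; a voxel whose unwrapped range exceeds 4$\pi$ (configurable) is
  flagged unreliable rather than silently corrected, since such excursions at
  spinal-canal velocities indicate noise-driven runaway rather than flow.
* **Background phase.** Eddy currents and field drift add a slowly varying
  static phase. We fit a polynomial surface (order 1 by default; 0 and 2
  available) in the in-plane coordinates to the *time-averaged* velocity over
  a static-tissue mask and subtract it from every cardiac phase. The static
  mask is user-supplied or auto-derived (temporal-SD below the 25th
  percentile, magnitude above its median — quiet, tissue-bright voxels).
  Correction is applied after unwrapping, on velocity units; for a truly
  linear background the order-1 fit removes it exactly, and the post-hoc
  static-region mean is zero to numerical precision.

The sign convention is anatomical: positive velocity and flow are cranial,
negative caudal. The wrap convention is half-open, $v = +\mathrm{VENC}
\mapsto -\pi$, matching two's-complement phase storage on scanners; the
integer file dialect maps stored values by $\varphi = s\,\pi/4096$.

## Flow waveform and the six metrics

Within an ROI of the canal, the flow rate at cardiac phase $k$ is the
voxelwise sum $Q_k = \sum_{\mathrm{vox}} v_{\mathrm{vox},k}\, A_{\mathrm{vox}}$
(mm³/s), not mean-velocity-times-area — identical for uniform masks but
robust to partial-lumen masks. The six cycle metrics are: cranial flow volume
$\sum_k \max(Q_k, 0)$, caudal flow volume $\sum_k \max(-Q_k, 0)$, net stroke
volume $\sum_k Q_k$, absolute stroke volume $\sum_k |Q_k|$, amplitude
$\max Q - \min Q$ (peak-to-peak; no harmonic model is fitted), and peak flow
$\max |Q_k|$. Volume metrics are emitted both as raw phase-sums (mm³/s ×
cardiac phase, the conventional reporting unit) and multiplied by the phase
duration in seconds (mm³), because published tables do not always state which
convention they use.

Identities: net = cranial − caudal and absolute = cranial + caudal hold for
every waveform. The inequality pair peak ≤ amplitude ≤ 2·peak holds exactly
for waveforms that change sign — the physiological case, since spinal-canal
CSF flow reverses every cycle — but *not* for constant-sign waveforms (a
constant waveform has amplitude 0 and peak > 0); the tests assert it on
zero-crossing waveforms and cover the degenerate case separately. Peak flow
is direction-agnostic by default (`max |Q|`); no temporal smoothing is
applied unless explicitly requested (moving average, window 3), and all
validation runs with smoothing off.

`find_flow_reversal()` locates sign changes cyclically and interpolates the
fractional crossing phase linearly; for a sampled sinusoid the interpolation
error is far below the 1/N phase spacing.

## The digital phantom

The phantom is a forward model of the acquisition, not an MR physics
simulation: no k-space, gradient-echo signal or eddy-current field model —
only the phenomena the reconstruction claims to handle (wrapping, a static
background offset plus in-plane linear ramp, noise). A circular canal of
radius 1.25 mm lies in a 64 × 64 grid of 0.47 × 0.47 mm voxels; its
centre-velocity waveform is a truncated Fourier series over the 40-phase,
453 ms cycle (defaults: fundamental 1.1 cm/s, second harmonic 0.25 cm/s,
mean 0.3 cm/s — caudal flow early in the cycle, reversal to cranial flow, and
a cranial-dominant volume ratio of about 2.3 over the cycle). The spatial
profile is parabolic (Poiseuille-like) by default, plug for analytic tests;
real canal profiles are not known to be either, so the profile is a
configuration choice, not a claim. Phase noise is Gaussian; magnitude noise
is Rician (Gaussian on the two complex channels), with the canal bright.
Ground truth (true velocity field, mask, noiseless waveform, metrics) is
computed through the same flow-quantification code on the noiseless field, so
"recovery" tests isolate the reconstruction stages.

VENC defaults to 10 cm/s: spinal-canal CSF velocities of a few cm/s then sit
well inside the dynamic range, and an amplitude of 15 cm/s (1.5 × VENC)
exercises aliasing.

## The synthetic cohort

The cohort generator emulates a small aging cohort (16 subjects, ages
uniform on 10–27 years). A latent pulsatility variable (scaled like peak
flow, mm³/s) is linear in age with slope −1 mm³/s·yr and Gaussian noise; the
six metric columns are fixed monotone linear transforms of it plus small
independent measurement noise (caudal volume decreasing in the latent, hence
*rising* with age; net and absolute stroke are derived as exact
cranial ± caudal combinations). The CSF Aβ42/40 ratio combines a direct
negative age effect with an effect of the *age-residual* of latent flow
(slope 0.0017 per mm³/s), so flow and the ratio stay associated after age
adjustment. CSF Aβ42, Aβ40, Aβ38, pTau181, NfL and GFAP carry age trends of
the expected signs but are conditionally independent of flow given age; six
plasma analogues are pure noise.

The two noise scales that set the correlation structure were calibrated once
by large-sample simulation (3 × 10⁶ draws) so that the *population* Spearman
correlations equal the configured targets: flow-noise SD = 0.905 × sd(age)
gives Spearman(age, flow) = −0.75, and ratio-noise SD = 0.00731 gives an
age-adjusted partial Spearman(flow, ratio) = +0.70. These targets are
configuration describing the simulated population, not empirical claims
about any real cohort. What passing tests show is that the *pipeline*
recovers the structure it is given; they cannot show that real scanner data
have this structure, that biomarker assays behave like Gaussian noise, or
that real metric columns are monotone in a single latent variable.

## The association stage

All correlation machinery is implemented from first principles and
cross-checked. Spearman correlations are Pearson correlations of mid-ranks
(ties averaged); p-values use the two-sided t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ — the conventional choice at cohort sizes
around 16, where exact permutation would also be feasible but is not the
field norm. Missing data are handled by pairwise (or triple-wise) complete
cases, with the n used always reported; cells with n < 4 are reported
missing, never zero. No multiple-testing correction is applied by default
(matching the p < 0.05 masking convention); Benjamini–Hochberg is available.

Partial correlation given age is computed by two routes on every call — the
closed form $(r_{xy} - r_{xz}r_{yz}) / \sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}$ and
the correlation of OLS residuals — and the call fails loudly if they differ
by more than 1e-10. Inference uses df = n − 3. Collinearity with the control
($|r| = 1$) is an error, not a number.

The residualization regression regresses the biomarker on the age-residual
of the flow metric. A genuine design fork: with stage 2 as a simple
regression (`biomarker ~ residual`, df = n − 2) its t statistic differs from
the partial-correlation t by the factor $\sqrt{(n-2)/(n-3)}$ and the two
p-values are close but not equal; with age retained as a stage-2 covariate
(`biomarker ~ age + residual`) the t statistic is *algebraically identical*
to the partial-correlation t (df = n − 3), which is why well-conducted
reports of both analyses print matching p-value columns. The package
defaults to the age-covariate form and exposes the simple form via
`age_covariate = FALSE`.

## Numerical choices and degenerate inputs

* Unwrapping jump threshold is strictly $> \pi$ (a jump of exactly $\pi$ is
  left alone, consistent with the half-open wrap convention); corrections are
  exact multiples of $2\pi$ by construction.
* Background fits use QR least squares on centred voxel coordinates; static
  masks under 10 voxels are rejected as under-determined.
* Relative-error comparisons against ground-truth metrics use a scale floor
  (the absolute stroke volume) so that metrics whose true value is ~0 — the
  net stroke of a pure harmonic — are compared on the waveform's scale rather
  than against rounding dust.
* Degenerate guards: empty ROIs, < 4 complete triples, zero-variance
  age-residuals, canal outside the grid, and phase-count mismatches between
  file and configuration are all errors that name the offending quantity.
* All simulators take integer seeds and are bit-reproducible; generation
  restores the caller's RNG state.

## Problem sizes used in validation

The suite validates at deliberately modest sizes chosen to make the checks
sharp: 10⁵ velocities for the encode/decode round trip (1e-12 tolerance);
64 × 64 × 40 phantoms for recovery (1e-9 relative clean; 1e-6 with aliasing
at 1.5 × VENC plus a background plane, after unwrapping and correction); 1000
random waveforms for the metric identities; n = 5000 cohorts for population-
target recovery (±0.03); 5000 Monte-Carlo replicates for the size of the
partial-correlation test at n = 16 (0.05 ± 0.01); 500 16-subject cohorts for
sign-pattern recovery (≥ 90%); and 100 noise seeds at waveform SNR 5 — SNR
defined as true peak flow over the waveform-level noise SD — for the noise-
bias characterisation, where rectification biases the absolute stroke volume
upward while the net stroke volume stays unbiased but with a standard
deviation of roughly √N × the per-phase noise, the quantitative form of the
usual caution that net stroke volume is the least reliable of the six
metrics at low SNR.

## Known limitations

* No spatial unwrapping, Maxwell-term or gradient-nonlinearity correction;
  equivalence with any scanner's proprietary pipeline is not claimed, only
  internal correctness against the phantom's forward model.
* No automatic canal segmentation beyond magnitude thresholding; the ROI is
  an input.
* Cardiac phases are treated as uniformly spaced samples of one cycle
  (retrospective gating); R-R variability and gating failures are not
  modelled.
* The cohort generator's biomarker scales are plausible magnitudes, not
  assay-calibrated values; only its correlation structure is engineered.
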