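# csfpulse

Quantification of pulsatile cerebrospinal fluid (CSF) flow in the spinal
canal from cardiac-gated phase-contrast MRI (PC-MRI), and age-adjusted
association of the resulting flow metrics with fluid biomarkers of amyloid
pathology.

CSF circulation is a transport medium for waste clearance from the brain's
interstitial space; diminished CSF pulsatility with age is a candidate
imaging marker of impaired amyloid clearance. `csfpulse` implements the full
computational chain needed to study this in small cohorts (human or
nonhuman-primate scale), together with a digital phantom and a synthetic
cohort generator so that every stage is testable against known ground truth
without access to scanner data.

## What it computes

**Velocity encoding.** PC-MRI stores through-plane velocity in the signal
phase: `v = phi * VENC / pi` (cm/s), where VENC is the velocity-encoding
limit. Velocities with `|v| >= VENC` alias by wrapping into `[-pi, pi)`;
`unwrap_temporal()` removes 2*pi jumps along the cardiac-phase axis per
voxel, and `correct_background()` fits and subtracts a low-order polynomial
background-phase surface estimated over static tissue.

**Flow waveform and metrics.** Within a region of interest (ROI) of the
spinal canal, the flow rate per cardiac phase k is
`Q[k] = sum_vox v[vox, k] * A_vox` (mm^3/s, positive = cranial). Six metrics
summarise the waveform over one cardiac cycle:

| metric | definition |
|---|---|
| cranial flow volume | `sum(max(Q, 0))` |
| caudal flow volume | `sum(max(-Q, 0))` |
| net stroke volume | `sum(Q)` |
| absolute stroke volume | `sum(abs(Q))` |
| flow-rate amplitude | `max(Q) - min(Q)` |
| peak flow rate | `max(abs(Q))` |

Volumes are reported both as phase-sums (mm^3/s x cardiac phase, the
conventional reporting unit) and time-integrated (mm^3).

**Association stage.** Spearman (or Pearson) correlation matrices with
significance masking at p < 0.05; age-controlled partial correlation
computed by two independent routes (closed form and residual correlation)
that are cross-checked to 1e-10 on every call, with `t = r sqrt(df/(1-r^2))`,
`df = n - 3`; and a residualization regression (biomarker on the age-residual
of a flow metric, age retained as covariate), whose t statistic is
algebraically identical to the partial-correlation t.

**Simulators.** `generate_phantom()` produces cardiac-gated magnitude/phase
series of a circular canal with plug or parabolic (Poiseuille-like) flow, a
truncated-Fourier waveform, background phase offset and ramp, Gaussian phase
noise and Rician magnitude noise — plus exact ground truth.
`generate_cohort()` draws subject tables (age, six metrics, CSF/plasma
biomarkers) whose population correlation structure is configurable; defaults
give Spearman rho(age, flow) = -0.75 and age-adjusted rho(flow, Ab42/40) =
+0.70, with plasma analogues null.

## Worked example

```r
library(csfpulse)

params <- acq_params()            # VENC 10 cm/s, 40 phases, 453 ms cycle
ph  <- generate_phantom(phantom_spec(seed = 42), params)
vel <- phase_to_velocity(ph$phase)
w   <- compute_waveform(vel, ph$truth$mask)
compute_metrics(w)
#> CSF flow metrics over one cardiac cycle
#>   cranial flow volume :      514.6 mm^3/s x phase  (5.827 mm^3)
#>   caudal flow volume  :      223.1 mm^3/s x phase  (2.527 mm^3)
#>   net stroke volume   :      291.4 mm^3/s x phase  (3.3 mm^3)
#>   absolute stroke vol.:      737.7 mm^3/s x phase  (8.354 mm^3)
#>   flow-rate amplitude :       57.1 mm^3/s (peak-to-peak)
#>   peak flow rate      :      33.09 mm^3/s
```

The canal flows caudally early in the cycle (systole) and reverses to
cranial flow between cardiac phases 3 and 4 (`find_flow_reversal(w)` gives
the interpolated crossing at phase 3.18); cranial volume exceeds caudal
volume roughly 2.3-fold, i.e. a net cranially-directed stroke per heartbeat.

```r
cohort <- generate_cohort(cohort_spec(n_subjects = 16, seed = 9))
rep <- run_association_report(cohort)
rep$age_adjusted
#>           metric partial_rho partial_p  estimate std_error t_value  resid_p  n
#>       net_stroke       0.738   0.00169  0.000113  2.59e-05    4.36 0.000776 16
#>   cranial_volume       0.722   0.00237  0.000155  3.65e-05    4.25 0.000953 16
#>    caudal_volume      -0.688   0.00458 -0.000405  8.91e-05   -4.54 0.000552 16
#>  absolute_stroke       0.674   0.00586  0.000243  6.18e-05    3.94 0.001701 16
#>        amplitude       0.699   0.00375  0.000854  2.05e-04    4.18 0.001085 16
#>        peak_flow       0.695   0.00400  0.001384  3.37e-04    4.11 0.001230 16
```

In this 16-subject draw, peak flow falls with age (Spearman rho = -0.747,
p = 0.00088), correlates positively with the CSF Ab42/40 ratio (rho = 0.779),
and remains associated after age adjustment (partial rho = 0.695, p = 0.004);
the partial-correlation and residualization p-value columns agree because the
two t statistics are identical by construction. Plasma analogues stay null
(e.g. plasma NfL vs peak flow, p = 0.47).

`run_pipeline(pipeline_config(seed = 1))` chains everything end to end
(simulate -> reconstruct -> metrics -> associate) and writes a JSON run
manifest with checksums. The same stages are exposed as shell subcommands:

```sh
Rscript inst/cli/csfpulse.R simulate    --seed 3 --out phdir
Rscript inst/cli/csfpulse.R reconstruct --phase phdir/phase.nii.gz --mag phdir/magnitude.nii.gz --out vel.nii.gz
Rscript inst/cli/csfpulse.R metrics     --velocity vel.nii.gz --roi phdir/mask.nii.gz --cycle-ms 453 --out metrics.json
Rscript inst/cli/csfpulse.R associate   --table cohort.csv --out report/
```

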