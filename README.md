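# repolab

Ventricular repolarization morphology from resting 12-lead ECG:
**TCRT**, **TMD/TMDpre/TMDpost**, and tangent-method **QT / QTc / Tp-e**
intervals, with a rank-3 dipole simulator providing analytic ground truth
and a case-control statistics layer.

## Who this is for

Researchers quantifying repolarization abnormalities from standard
resting ECGs — for example comparing a patient group (diabetes, impaired
fasting glucose, channelopathy carriers, ...) against controls — who need
the full chain from raw multi-lead signals to a clinical-style summary
table, and a way to validate every stage against known ground truth
without patient data.

## The method

Of the 12 standard leads only eight (I, II, V1–V6) are linearly
independent. Singular value decomposition of the baseline-corrected
8 × N beat matrix `X = U Σ Vᵀ` yields an optimized 3-D decomposition
space `S₃ = Σ₃V₃ᵀ` that retains ≈99 % of the signal energy, and an energy
envelope

```
E3d(t) = s₁(t)² + s₂(t)² + s₃(t)²
```

on which QRS and T-wave landmarks are located (R peak at the envelope
maximum; QRS onset/offset at maximum up/down-slope; T start/peak/end by
local maximum and 5 % energy crossings).

- **TCRT** — mean cosine of the angles between the QRS-loop vectors
  (samples between QRS onset and offset with ≥70 % of peak QRS energy)
  and the T-peak vector. Unitless, in [−1, 1]; negative values mean
  depolarization and repolarization loops point in very different
  directions.
- **TMD** — mean angle (degrees) between per-lead reconstruction vectors
  (each lead's loadings on the first two components of an SVD of the
  T-window segment), over all 28 lead pairs; TMDpre/TMDpost restrict the
  window to before/after the T peak.
- **Intervals** — on lead V5, the T end is the intersection of the
  isoelectric (PR-segment) level with the tangent at the steepest
  post-peak slope; QT, Bazett QTc = QT/√RR, Tp-e, Tp-e/QT, Tp-e/QTc.

Markers are computed from an **averaged** (template) beat and from a
**randomly selected** beat. The synthetic module generates 12-lead
recordings from a rank-3 Gaussian-wave dipole whose QRS-to-T spatial
angle θ is programmable — `cos θ` is the analytic TCRT ground truth —
projected through a fixed, column-orthogonal (angle-preserving)
Dower-derived lead field (`LEAD_PROJECTION`).

## Worked example

```r
library(repolab)

## one synthetic subject with a 60 degree QRS-T angle
cfg  <- synth_config(fs = 1000, duration = 10, heart_rate = 60,
                     theta = 60, noise_sd = 0.01, seed = 42)
rec  <- generate_ecg(cfg)
rec
#> <ecg_record> subject=synthetic  12 leads x 10000 samples  fs=1000 Hz  (10.00 s)

peaks <- detect_r_peaks(rec)
beats <- segment_beats(rec, peaks)
m     <- compute_markers(average_beat(beats))
m
#> <morphology_markers> mode=averaged  TCRT=0.493  TMD=24.8  TMDpre=19.2  TMDpost=23.5  E3frac=0.9996
```

TCRT comes out at 0.493 against the programmed `cos 60° = 0.5` (the
residual comes from the finite QRS loop width), and 99.96 % of the energy
sits in the three decomposition components.

```r
iv <- measure_intervals(average_beat(beats)$samples["V5", ], m$landmarks,
                        rr = mean(diff(peaks)) / rec$fs, fs = rec$fs)
iv
#> <interval_measures> QT=397.0 ms  QTc=397.0 ms  Tp-e=90.0 ms  Tp-e/QT=0.23  Tp-e/QTc=0.23  RR=1.000 s
```

A full case-control simulation — 74 controls vs 50 cases whose θ
distributions differ but whose T-wave geometry is identical:

```r
sim <- generate_cohort(cohort_sim_config(seed = 1))
res <- run_cohort(sim$records, sim$cohort, seed = 1)
res$summary[, c("variable", "control", "dm_ifg", "p_label")]
#>       variable       control        dm_ifg p_label
#>    tcrt_random   0.38 ± 0.04   0.04 ± 0.06   <0.01
#>     tmd_random  24.40 ± 0.21  24.69 ± 0.24      NS
#>  tcrt_averaged   0.38 ± 0.04   0.05 ± 0.06   <0.01
#>   tmd_averaged  24.24 ± 0.07  24.31 ± 0.07      NS
#>  ...
```

The TCRT rows separate the groups at p < 0.01 while every T-morphology
row stays non-significant — the signature of a group difference confined
to the depolarization-repolarization angle. The confounder model
(`res$model`) attributes the difference to group membership
(coefficient −0.35, p ≈ 7e-06) and to nothing else.

## File formats

- ECG: lead-per-column CSV plus a JSON sidecar (`{"fs": 500, "units":
  "mV", "subject_id": "S001"}`), or WFDB format-16 (`.hea`/`.dat`).
  Lead labels are normalized through a synonym table (`MLI → I`, ...).
- Cohort covariates: CSV with one row per subject; required column
  `group`, recognized clinical columns `age, sex, height, weight, bmi,
  sbp, dbp` and binary flags `dyslipidemia, hypertension, fhx_ihd,
  aspirin, acei_arb, ccb, beta_blocker, statin, thiazide,
  current_smoker, past_smoker` (plus screening flags `pregnant,
  history_mi, angiography, cabg, fhx_scd, surgery_or_malignancy,
  afib_pacemaker` used by the exclusion filters). Unknown columns are
  preserved. BMI is cross-checked against weight/height².

A command-line front end is included at `inst/cli/repolab.R`
(`simulate`, `analyze`, `compare` subcommands).

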