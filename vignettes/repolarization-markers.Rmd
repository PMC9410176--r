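---
title: "Quantifying ventricular repolarization: TCRT, TMD and tangent-method intervals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ventricular repolarization: TCRT, TMD and tangent-method intervals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repolab)
```

## The measurement problem

The spatial relation between ventricular depolarization and repolarization
carries prognostic information that scalar intervals (QT, QTc) miss. Two
descriptor families quantify it from an ordinary resting 12-lead ECG:

* **TCRT** (total cosine R-to-T) measures the angle between the QRS loop
  and the T-wave loop in a reconstructed 3-D vector space. Values near 1
  mean depolarization and repolarization wavefronts travel in nearly the
  same spatial direction; negative values mean the two loops point in
  substantially different directions.
* **TMD** (T-wave morphology dispersion) measures how much the *shape* of
  the T wave differs between leads, as a mean angle between per-lead
  reconstruction vectors; TMDpre and TMDpost restrict the comparison to
  the segments before and after the T peak.

Both are computed in a decomposition space obtained by singular value
decomposition (SVD) of the eight independent leads (I, II, V1--V6 -- the
other four are fixed linear combinations by the Einthoven/Goldberger
identities). Writing the baseline-corrected 8 x N beat matrix as
$X = U \Sigma V^\top$, the loop-space series is
$S_3 = \Sigma_3 V_3^\top$ (the first three principal temporal components,
scaled by their singular values) and the per-sample energy envelope is

$$E_{3d}(t) = s_1(t)^2 + s_2(t)^2 + s_3(t)^2 .$$

On clean recordings the three components retain about 99% of the total
signal energy, which is what justifies working in the reduced space.
`svd_decompose()` reports the retained fraction and warns below 0.95
rather than failing: the 99% figure is an empirical property of clean
recordings, not a precondition.

## Landmarks on the energy envelope

All fiducial points are located on $E_{3d}$, which is independent of loop
orientation and lead polarity (`detect_landmarks()`):

* R peak: envelope maximum within ±60 ms of the detector's hint;
* QRS onset / offset: maximum upslope / downslope of the envelope within
  100 ms on either side of the R peak (the maximum-slope convention for
  delimiting the high-energy QRS core);
* T peak: largest local envelope maximum 80--450 ms after QRS offset;
* T start / end: crossings of 5% of the T-peak energy, requiring the
  envelope to stay beyond the threshold for at least 20 ms so noise blips
  do not terminate the wave early.

The window constants (60, 100, 80--450 ms, 5%, 20 ms) are operational
choices, exposed as arguments with these defaults. They cover resting
heart rates of roughly 40--120 bpm; outside that range the T search
window would need adjustment. Note that this "QRS onset" sits on the R
upstroke (it is an energy-slope landmark), not at the conventional start
of the Q deflection; consumers that need a truly isoelectric reference
(the tangent method below) therefore back away from it.

## TCRT

`compute_tcrt()` averages the cosine of the angle between each QRS-loop
vector and the single T-peak vector:

$$\mathrm{TCRT} = \frac{1}{|Q|}\sum_{t \in Q}
  \cos \angle\bigl(S_3(t),\, S_3(t_{\mathrm{Tpeak}})\bigr),$$

where $Q$ is the set of samples between QRS onset and offset whose energy
reaches at least 70% of the QRS peak energy. The threshold keeps
low-energy QRS tail samples -- whose directions are noise-dominated -- out
of the average; setting `qrs_energy_frac = 0` reproduces the literal
all-samples definition, and on clean signals the two agree closely. A
single T-peak vector is used (rather than averaging several repolarization
vectors); the multi-vector variant can be emulated by widening the T
window, but the single-vector form is the one this package validates.

## TMD

`compute_tmd()` re-decomposes the T-window segment of the 8-lead beat by
SVD and builds, for each lead, a reconstruction vector from that lead's
loadings on the first two components scaled by the singular values. TMD
is the mean angle (degrees, in [0°, 180°]) over all 28 unordered lead
pairs. Two dimensions are the conventional choice for T-loop
reconstruction vectors (`ndim = 3` is available); leads whose vectors are
numerically zero are excluded from pairing, and more than four such leads
make the T loop degenerate.

A caution worth stating explicitly: unlike TCRT, energy and landmarks,
**TMD is not invariant under rotation of the underlying cardiac dipole.**
Its reconstruction vectors live in lead space, so the fixed electrode
geometry enters the value. Rotating the heart vector changes which leads
see similar T shapes, and TMD changes with it. This is a property of the
marker itself, not an implementation artifact, and it is why the
simulated cohorts below vary the QRS loop rather than the T loop.

## Beats: averaged and random

Markers are computed in two modes. The *averaged* mode aligns all beats
on their R peak (detected on the summed cross-lead energy, with a 200 ms
refractory period) and takes the sample-wise mean -- a template beat with
noise suppressed at the $1/\sqrt{n}$ rate. The *random* mode picks one
beat uniformly at random (excluding the first and last, whose windows abut
the recording edges), reproducibly from a seed. The beat window is 300 ms
before to 500 ms after the R peak, covering P onset through T end at
resting rates of about 45 bpm and up; if the window exceeds the shortest
RR interval it is truncated proportionally with a warning.

Recording quality is screened before analysis (`quality_check()`): a lead
is *displaced* when its RMS falls below 5% of the median lead RMS or when
its odd-beat average fails to correlate (r < 0.2) with its even-beat
average -- a morphology-agnostic consistency index, so legitimately
inverted or low-voltage leads are not penalized -- and *interference* is
flagged when more than 30% of a lead's spectral power sits above 40 Hz.
The thresholds are operational defaults, exposed as arguments.

## Intervals on V5: the tangent method

`tangent_t_end()` implements the classical construction: the T end is the
intersection of the isoelectric line with the tangent at the steepest
post-peak slope. The tangent is a 10 ms least-squares line slid along the
descending limb; the isoelectric level is a 40 ms mean on the PR segment,
ending 60 ms before the (energy-slope) QRS onset so that no Q/R deflection
contaminates it. For a Gaussian T wave of width $\sigma$ the construction
has a closed form -- the tangent at the steepest-descent point
$\mu + \sigma$ meets the baseline at exactly $\mu + 2\sigma$ -- which the
test suite uses as an analytic oracle, including the mirrored case of an
inverted T wave. QT runs from QRS onset to the tangent T end, Tp-e from
the T peak, QTc is Bazett's $QT/\sqrt{RR}$ with the recording-mean RR, and
the Tp-e/QT and Tp-e/QTc ratios follow. Intervals are kept at full
precision internally; clinical-style tables round ratios to two decimals.

## The synthetic cohort: what it emulates and what it does not

`generate_dipole()` builds a rank-3 cardiac dipole from Gaussian waves
(P, Q, R, S, T) attached to spatial directions -- a deliberately
minimal, ECGSYN-style kinematic model chosen for controllable geometry,
not biophysical realism. The R wave lies exactly on the QRS axis, Q and S
sit `qrs_loop_spread` degrees (default 15°) to either side so the QRS
loop has nontrivial width, and the T wave lies on the T axis with a
minor-axis component (`t_loop_ratio`, default 0.2) along the loop-plane
normal, so the trajectory genuinely spans three dimensions. The angle
theta between the QRS and T axes is the programmable ground truth:
noiseless, zero-spread beats must yield TCRT = cos(theta), and the
acceptance suite verifies this within 0.02 across the whole 0--180°
range. The P wave rides on the T axis: the atrial axis is not a property
of the ventricular loop, and fixing it keeps the pre-QRS baseline
independent of theta.

`project_to_leads()` maps the dipole through a fixed 8 x 3 lead-field
matrix, a column-orthogonalized (Löwdin) version of the classical Dower
matrix rescaled to physiological gains. Column orthogonality with equal
norms is essential: it makes the projection angle-preserving, so the
programmed spatial angle survives into lead space and back through the
SVD. The matrix ships as the versioned constant `LEAD_PROJECTION` so all
tests are bit-stable. White noise is added per independent lead; the
derived leads (III, aVR, aVL, aVF) inherit the corresponding noise
combinations, exactly as they would from a real limb-lead recording.

`generate_cohort()` draws each subject's theta from a group-specific
normal distribution, truncated (not resampled) to [0°, 180°]. The
group difference is implemented by rotating the *QRS* axis away from a
fixed T axis: because TMD is orientation-sensitive in lead space (see
above), rotating the T loop with theta would leak the group difference
into the TMD rows, whereas the QRS rotation confines it to TCRT --
mirroring a cohort whose groups differ in depolarization-repolarization
angle but share T-wave morphology. Defaults are 74 controls
(theta ~ N(61°, 25°)) versus 50 cases (theta ~ N(85°, 30°)), chosen by a
delta-method calibration so the group means of cos(theta) land near 0.44
and 0.08 -- the magnitudes reported for such cohorts -- with dispersion of
the same order as observed between patients. The synthetic spread is
deliberately somewhat tighter than real-cohort standard errors: the
simulator varies only the angle, while real between-patient variability
also contains shape and measurement noise that the model does not emulate.
Clinical covariates (age, sex, anthropometrics, risk factors, medications)
are drawn from distributions typical of a middle-aged screening
population, with a higher statin rate among cases.

What passing these simulations shows -- and what it does not: the pipeline
recovers a known spatial angle through projection, decomposition,
landmarking and averaging, and the statistics layer detects a
TCRT-confined group difference at realistic sample sizes while leaving
T-shape markers non-significant. It does not show that real diabetic
cohorts have any particular TCRT value: real ECGs add respiration drift,
electrode placement variation, beat-to-beat T-wave lability and
pathology-specific morphology that the rank-3 Gaussian model deliberately
omits.

## The statistics layer

Groups are summarized as mean ± SEM (SD with the n−1 convention over
$\sqrt{n}$); "abnormal" means strictly more than 2 reference SDs from the
reference mean. Continuous markers are compared with the Kruskal–Wallis
rank test and binary covariates with Fisher's exact test (two-sided by the
probability-mass rule). For two-group samples of total size at most 12 the
Kruskal–Wallis p-value is computed by exhaustive enumeration of all group
assignments -- at such sizes the chi-square approximation misstates p by
up to ~0.1, and the enumeration is instant -- while larger samples use the
standard tie-corrected chi-square reference. Confounding is assessed with
an OLS model of the averaged-beat TCRT on group, age, sex, height, weight
and the binary risk factors; BMI is dropped from the default covariate set
because it is structurally (near-)collinear with height and weight, and an
exactly rank-deficient design raises an error naming the aliased columns
rather than silently dropping them. No multiple-testing correction is
applied, matching the descriptive single-table reporting style the output
mirrors; summary tables render p ≥ 0.05 as "NS" and p < 0.01 as "<0.01".

## Numerical choices and degenerate inputs

* SVD component signs are arbitrary; each component is flipped so its
  value at the R peak is non-negative (max-abs-sample tie-break). Cosines
  are unaffected; the convention exists so intermediates are reproducible.
* The decomposition is fit per analyzed beat, not once per recording:
  markers are beat-level quantities, and per-beat fitting is the
  conservative reading when the two differ.
* $E_{3d}$ is the *squared* norm of the loop vector. Landmarks (argmax,
  slope extrema, relative thresholds) and cosine markers are unchanged
  under the unsquared convention.
* Zero-energy beats, flat T waves, degenerate QRS/T loops, zero-margin
  2 x 2 tables and single-value groups all raise typed errors or warnings
  rather than returning silent numbers; `run_subject()` converts them to
  per-subject failure rows so one bad recording never aborts a cohort.
* Every random choice (noise, cohort draws, random-beat selection) flows
  through an explicit seed; a cohort run is byte-reproducible from
  `(inputs, seed)`.

## Problem sizes used in validation

The test and acceptance suites run entirely on synthetic data generated at
run time: single recordings of 2--10 s at 500--1000 Hz, and simulated
cohorts of 74 + 50 subjects at 500 Hz / 10 s, analyzed end-to-end over 20
seeds for the significance-pattern check. Property sweeps use dozens of
random configurations per invariant. These sizes keep the full validation
run in the minutes range on a single core while still exercising every
stage at the cohort scale the statistics are designed for.

## Known limitations

* The dipole model has no respiratory modulation, no heart-rate-dependent
  interval adaptation (T timing is fixed relative to R), no ectopy and no
  atrial realism beyond a single Gaussian P.
* WFDB support covers the common format-16 single-file layout only.
* TMD's lead-space orientation sensitivity means simulated TMD values
  should be compared only within a fixed lead-field convention.
* The tangent method assumes a monophasic T wave; biphasic T waves yield
  a T end on whichever limb is steepest after the detected peak.
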