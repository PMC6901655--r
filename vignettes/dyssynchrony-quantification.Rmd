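---
title: "Quantifying regional metabolism, perfusion and myocardial work in mechanical dyssynchrony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying regional metabolism, perfusion and myocardial work in mechanical dyssynchrony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In non-ischemic heart failure patients referred for cardiac
resynchronization therapy (CRT), mechanical dyssynchrony — discoordinate
left-ventricular contraction recognized on echocardiography as septal
flash and/or apical rocking — redistributes regional workload: the
early-activated septum contracts against low load (and may even be
stretched while the rest of the ventricle is in systole, performing
*negative*, wasted work), while the late-activated lateral wall is
pre-stretched and overloaded. Regional glucose metabolism (¹⁸F-FDG
uptake) and resting myocardial blood flow (MBF, from dynamic ¹³N-NH₃
PET) follow this workload imbalance. A compact summary of the imbalance
is the septal-to-lateral ratio (SLR): the mean septal value of a
quantity divided by its mean lateral value. A low FDG SLR is associated
with the presence of mechanical dyssynchrony and with volumetric
reverse remodeling (relative reduction of LV end-systolic volume,
ΔLV ESV) a year after CRT.

`dyssyncPET` implements the full quantification chain behind these
observations, plus a calibrated synthetic-cohort generator so that the
chain can be exercised, tested and benchmarked end to end without
patient data (none are publicly deposited for this problem).

## The kinetic model for ¹³N-NH₃

Regional MBF comes from the irreversible two-tissue compartment model.
With arterial input \(C_a(t)\) (metabolite-corrected whole blood),
free-tissue compartment \(C_1\) and trapped compartment \(C_2\):

\[
\frac{dC_1}{dt} = K_1 C_a - (k_2 + k_3) C_1, \qquad
\frac{dC_2}{dt} = k_3 C_1, \qquad C_T = C_1 + C_2 .
\]

The impulse response is
\(h(t) = K_1\,[k_3 + k_2 e^{-(k_2+k_3)t}]/(k_2+k_3)\), and the measured
regional signal mixes tissue with blood-pool spillover:

\[
C_m(t) = (1 - f_{sp})\, (C_a * h)(t) + f_{sp}\, C_{wb}(t),
\]

frame-averaged over the 22-frame schedule (12×10 s, 4×30 s, 3×120 s,
180 s, 420 s, 600 s). Only frames ending within the first 10 min (19 of
22) enter the fit, because ¹³N metabolites progressively contaminate
the blood signal later on; the metabolite fraction is taken as zero for
the first 2 min, then rising linearly to a plateau (default 0.5 at
600 s) — the literature correction this stands in for is not published
as a closed form, so the package declares its own and exposes it in the
configuration.

Design choices worth knowing:

* **MBF = K₁.** At rest the first-pass extraction of ammonia is near
  unity; `fitRegion()` reports MBF = K₁ by default and accepts an
  `extractionCorrection` hook for users who prefer an explicit
  flow-extraction inversion.
* **Weights.** "Weighted least squares" is under-determined without a
  weight law; the package defaults to frame-duration weights (longer
  frames have lower variance), with an activity-based alternative
  behind the `weighting` argument.
* **Spillover / partial volume.** A single blood-spill fraction per
  region is absorbed into the fit as a fourth parameter, with the
  \((1-f_{sp})\) factor approximating partial-volume loss of tissue
  signal. No geometric recovery coefficients are published for this
  chain, so none are hard-coded.
* **Optimizer.** Bounded Levenberg–Marquardt (`minpack.lm::nls.lm`)
  from five fixed start points (bounds \(K_1 \in [0,5]\),
  \(k_2, k_3 \in [0,2]\), \(f_{sp} \in [0,0.8]\)); ties are broken by
  lowest weighted SSE, then lowest K₁. The convolution runs on a fixed
  0.5 s trapezoidal grid with the exact one-step recursion for the
  exponential kernel, so results are bit-reproducible for identical
  inputs.

## FDG regionalization

Static FDG uptake arrives as a standard AHA 17-segment polar map of
SUVmean values. Walls are unweighted means of their segments with the
apical cap (segment 17) excluded; the default mapping assigns
anteroseptal + inferoseptal segments {2, 3, 8, 9, 14} to the septum and
inferolateral + anterolateral segments {5, 6, 11, 12, 16} to the
lateral wall, {1, 7, 13} anterior and {4, 10, 15} inferior. The exact
4-wall split used upstream of the published group statistics is not
enumerated anywhere, so the mapping is an explicit, overridable
argument. The FDG SLR is the septal wall mean divided by the lateral
wall mean.

## Myocardial work

Segmental myocardial work per unit volume is the signed area of the
stress–strain loop over one cycle:

* **LV pressure** is estimated noninvasively by time-warping a fixed
  normalized reference waveform to the measured valve events (mitral
  closure, aortic opening, aortic closure, mitral opening) and scaling
  it so its maximum equals the cuff systolic pressure. The published
  empirical waveform is not printed, so the package ships an explicit
  piecewise half-cosine template (plateau → isovolumic rise to 0.6 of
  the range at aortic opening → dome peaking at 1 midway through
  ejection → 0.7 at aortic closure → fall to the plateau); the landmark
  values are arguments.
* **Wall stress** follows the spherical Laplace relation
  \(\sigma = P/(2\,c\,h)\) with dynamic mid-wall curvature \(c\) (1/mm)
  and wall thickness \(h\) (mm); a cylindrical variant is available.
* **Loop area** is the signed shoelace area of the closed
  (strain, stress) polygon, oriented so that shortening under high
  stress is positive and systolic stretching yields negative (wasted)
  work; it is invariant under cyclic shifts of the starting sample, and
  traces must close to within 10⁻⁶ of their amplitude.
* **Regional work** averages the basal/mid/apical loop areas of a wall
  (18-segment model, 6 walls × 3 levels). How 18 segments map onto
  "septum" and "lateral wall" is not published; the default averages
  the two septal (respectively lateral) walls, and a single
  `SEPT`/`LAT` wall layout is accepted as well. The 17- vs 18-segment
  mismatch between the PET and work chains is inherited from the
  method; the package keeps both models and does not attempt to
  reconcile them.

## The synthetic cohort and its calibration

`generateCohort()` draws per-patient ground truth from the published
group distributions (23 dyssynchrony / 7 without) and forward-simulates
every raw input the pipeline consumes. Three calibration problems
deserve explanation:

* **Jointly matching wall means and SLR means.** Drawing septal and
  lateral uptake independently would fix the wall means but not the
  mean per-patient ratio. The generator instead draws the lateral
  uptake and the SLR (both truncated normal) and sets septal = SLR ×
  lateral. Because the factors are independent, the septal mean is the
  product of the means (0.5 × 11.19 ≈ 5.6, matching the published
  5.58); the implied septal SD (≈2.4) is slightly below the published
  2.65 — the three published moments are not jointly reachable under
  any construction that also fixes the SLR distribution, and the wall
  and SLR means take priority. Anterior and inferior walls, for which
  no values are published, are set to the septal–lateral midpoint plus
  jitter.
* **The negative-work fraction.** A normal with mean 370 and SD 816
  mmHg·% puts about 33% of its mass below zero, but negative septal
  work is reported in 40% of dyssynchrony patients.
  `calibrateWorkMixture()` therefore solves (deterministically, by
  Nelder–Mead on two parameters) for a mixture of a negative
  half-normal (weight 0.40, scale 400 mmHg·%) and a zero-truncated
  normal such that the mixture mean and SD hit 370/816 — so the mean,
  SD and sign fraction hold simultaneously. The non-dyssynchrony group
  draws from a zero-truncated normal, making negative septal work
  impossible there, as observed.
* **Coupling ΔESV to the FDG SLR.** ΔESV is generated as group mean +
  slope × (SLR − group SLR mean) + noise.
  `calibrateOutcomeCoupling()` solves for the common slope in closed
  form so the pooled Pearson correlation equals the target (−0.62) in
  expectation while per-group means and SDs stay at 47 ± 14 and
  −3 ± 20. A point worth noting: with these group parameters and the
  23/7 weights, the between-group separation alone already implies a
  pooled correlation of about −0.64, so the calibrated within-group
  slope is small and slightly *positive*. The residual SDs absorb the
  rest; an unreachable target raises an explicit calibration error.

Truncated draws use inverse-CDF sampling (equivalent to redrawing
out-of-range values, but with deterministic RNG consumption), and the
seed fully determines the cohort down to the bytes of its files.

The forward simulation itself is the package's own model chain run in
reverse: TACs are the two-tissue forward model (K₁ = true MBF, default
k₂ = 0.25/min, k₃ = 0.12/min, spill 0.35 septal / 0.25 elsewhere —
physiologic resting values, all configurable) driven by a gamma-variate
bolus (A(t−t₀)^α e^{−(t−t₀)/β}, peak ≈ 100 kBq/ml at 34 s) with
zero-mean frame noise of SD `noiseScale · sqrt(activity/duration)`
(default scale 1, i.e. roughly 5–10% on early frames and ~1% on late
frames); strain/curvature traces are closed ellipses in (strain,
stress) space of exactly the prescribed loop area, with thickness held
constant and curvature obtained by inverting the Laplace relation
against the patient's estimated pressure curve. Valve events default to
mvc/avo/avc/mvo = 0.034/0.103/0.387/0.447 s of a 0.86 s cycle
(isovolumic contraction ≈ 70 ms, ejection ≈ 280 ms — typical for a
heart-failure cohort at ~70 bpm). Three patients lack an FDG study
(21/23 dyssynchrony complete), one lacks the ammonia study and two lack
the follow-up echo, mirroring the availability pattern of the source
cohort; the missing patients are chosen at random per seed because the
overlap is not published.

**What the generator does not emulate.** No image domain exists: no
voxels, reconstruction, attenuation or motion artifacts, and no
speckle-tracking — the simulation starts at regional curves, maps and
traces. Inter-wall and inter-modality correlations beyond those stated
above are not modeled (nothing is published about them); frame noise is
Gaussian and independent, whereas real framed PET noise is correlated
through reconstruction; every patient shares one input-function shape;
and the stress–strain loops are geometric constructions, not
physiologic trace shapes (curvature is whatever makes the Laplace
relation consistent, which at the diastolic pressure plateau is far
from anatomic). Passing tests therefore demonstrate correctness and
calibration of the quantification chain, not clinical performance on
real images.

## Statistics

The statistical surface mirrors the source analysis: Shapiro–Wilk
driven mean ± SD vs median/IQR summaries, paired (septal vs lateral)
and unpaired (between-group) two-tailed t tests with Bonferroni
correction, Pearson/Spearman correlations, and Cohen's kappa with the
Fleiss–Cohen–Everitt asymptotic CI for reader agreement. Two
conventions are under-determined by the source and declared here:
unpaired tests are pooled-variance Student by default (Welch behind a
flag), and the Bonferroni family is m = 2 (the septal-vs-lateral
comparison per modality and group); both are arguments, not constants.
Delegation: t tests, correlations and Shapiro–Wilk call the standard
`stats` routines; kappa and its CI are implemented here (no installed
package provides the CI) and the point estimate is cross-checked
against an independent implementation in the test suite.

## Problem sizes and runtime choices

The replicate protocol used by the tests and the acceptance script is
20 cohorts of the default 23 + 7 patients (seeds base … base + 19),
with full four-parameter fits of the septal and lateral TACs of every
patient — 1 200 bounded fits, about a minute in total. Calibration
properties of the generator are checked at n = 5 000 per group with the
raw-data simulation switched off (`simulateRaw = FALSE`); estimator
bias is checked over 200 noisy single-region fits; the type-I error of
the unpaired t test over 10 000 null simulations at the cohort's 23 vs
7 imbalance. The brute-force fit oracle exploits that the model is
linear in ((1−spill)·K₁, spill) to grid only (k₂, k₃), making an
81²-point grid with one refinement exact enough to confirm the
nonlinear optimizer.

## Known limitations

* MBF = K₁ ignores extraction nonlinearity at high flow; fine at rest,
  wrong under stress.
* The metabolite model and pressure template are declared stand-ins
  for unpublished empirical curves; both are configuration, not truth.
* The SLR of MBF in the dyssynchrony group is reproduced only
  qualitatively (≈0.62–0.66 vs the published 0.7 ± 0.2): a mean of
  per-patient ratios is not identified by the published wall moments
  alone.
* Group SDs of fitted quantities inherit both biological spread and
  fit noise; only the published means are calibration targets.
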