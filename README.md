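# dyssyncPET

Quantification of regional myocardial metabolism, perfusion and work in
non-ischemic CRT candidates with mechanical dyssynchrony.

In mechanical dyssynchrony (septal flash / apical rocking on
echocardiography), the early-activated septum is unloaded — sometimes
performing negative, *wasted* work — while the late-activated lateral
wall is overloaded. Regional ¹⁸F-FDG uptake and resting myocardial
blood flow (MBF) follow this workload imbalance, and the
septal-to-lateral ratio (SLR) of FDG uptake tracks both the presence of
dyssynchrony and volumetric reverse remodeling (ΔLV ESV) after CRT.
`dyssyncPET` implements the whole measurement chain for researchers
working on CRT patient selection:

* **¹³N-NH₃ kinetics** — irreversible two-tissue compartment model
  `dC₁/dt = K₁Cₐ − (k₂+k₃)C₁`, `dC₂/dt = k₃C₁`, fitted to framed
  regional time-activity curves by bounded weighted least squares with
  metabolite correction of the arterial input and a blood-spill
  fraction in the model; MBF = K₁ (`fitRegion`, `mbfSLR`).
* **FDG regionalization** — wall SUVmean from AHA 17-segment polar maps
  (apex excluded) and the FDG SLR (`wallMeans`, `fdgSLR`).
* **Myocardial work** — noninvasive LV pressure from a landmark-warped
  reference waveform, spherical Laplace wall stress σ = P/(2ch), signed
  stress–strain loop areas (mmHg·%), 18-segment regional aggregation
  and wasted-work flagging (`estimateLVPressure`, `laplaceStress`,
  `loopArea`, `regionalWork`, `computeWork`).
* **Cohort statistics** — Shapiro–Wilk-driven summaries, paired /
  unpaired t tests with Bonferroni correction, Pearson / Spearman
  correlations, Cohen's kappa with asymptotic CI, ΔLV ESV
  (`tTestBonferroni`, `pearsonCorr`, `cohenKappa`, `deltaESV`).
* **Synthetic cohorts** — a seeded generator (`generateCohort`)
  calibrated to the published group distributions (23 patients with /
  7 without dyssynchrony; FDG 5.58 ± 2.65 vs 11.19 ± 4.10; MBF
  0.57 ± 0.11 vs 0.92 ± 0.23 ml/g/min; work 370 ± 816 vs 3174 ± 1033
  mmHg·% with 40% negative septal work; ΔESV 47 ± 14%; pooled
  r(FDG SLR, ΔESV) = −0.62), so the full chain runs end to end without
  any patient data.

## Worked example

```r
library(dyssyncPET)

coh <- generateCohort(cohortConfig(seed = 42))
coh
#> DyssyncCohort: 30 patients (23 with, 7 without mechanical dyssynchrony), seed 42
#>   modality availability: FDG 27, NH3 29, post-CRT echo 28

m <- analyzeCohort(coh, kinetics = "fit")   # full compartment fits
cohortReport(m)
#> Cohort report: 23 with / 7 without mechanical dyssynchrony
#>   suv_septal    dys 5.33 ± 1.96 (n=21) | non-dys 6.90 ± 2.06 (n=6)
#>   suv_lateral   dys 11.19 ± 3.88 (n=21) | non-dys 8.42 ± 2.44 (n=6)
#>   mbf_septal    dys 0.62 ± 0.12 (n=22) | non-dys 0.63 ± 0.20 (n=7)
#>   mbf_lateral   dys 0.96 ± 0.32 (n=22) | non-dys 0.77 ± 0.24 (n=7)
#>   work_septal   dys 337.44 ± 843.86 (n=23) | non-dys 1715.82 ± 595.89 (n=7)
#>   work_lateral  dys 3064.81 ± 1026.11 (n=23) | non-dys 2196.87 ± 559.57 (n=7)
#>   fdg_slr       dys 0.48 ± 0.10 (n=21) | non-dys 0.84 ± 0.24 (n=6)
#>   mbf_slr       dys 0.76 ± 0.43 (n=22) | non-dys 0.85 ± 0.30 (n=7)
#>   delta_esv     dys 49.14 ± 14.55 (n=22) | non-dys -15.30 ± 11.42 (n=6)
#>   r(FDG SLR, dESV) = -0.559 (p = 0.003687, n = 25)
#>   wasted septal work: 43% dys, 0% non-dys
#>   reader kappa = 0.814 (95% CI 0.566-1.000)
```

Read the report as one simulated study: in the dyssynchrony group the
septum takes up less than half the FDG of the lateral wall
(SLR ≈ 0.5), is hypoperfused relative to the lateral wall, and performs
an order of magnitude less work — negative in 43% of patients — while
the non-dyssynchrony group is nearly homogeneous; the FDG SLR
correlates inversely with reverse remodeling. Per-group numbers at
n = 23/7 scatter around the generating means from seed to seed;
`replicateRuns()` averages the headline metrics over replicate cohorts.

The same stages can be run against their file interfaces
(CSV TACs / polar maps / traces, JSON manifest and sidecars):

```r
runPipeline(cohortConfig(seed = 1), "out/")   # simulate ... stats
```

or from a shell via the thin wrapper `inst/scripts/dyssync.R`
(`simulate | fit-nh3 | fdg-regional | work | stats | run | replicate`).

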