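# cestpd

Quantification and group-comparison pipeline for CEST/APT and diffusion
tensor MRI of the substantia nigra and striatum, built for studies that ask
whether amide proton transfer (APT) contrast separates Parkinson's disease
(PD) patients from controls — and early-stage from advanced-stage patients —
better than diffusion metrics do.

Patient images in this setting are rarely shareable, so the package pairs
the analysis chain with a physics-based synthetic cohort generator: a
multi-pool Bloch-McConnell simulator produces two-slice saturation
acquisitions (and matching diffusion-weighted volumes) for seeded cohorts
with region- and stage-specific effects, and every downstream stage is
tested against that generator.

## What it computes

**CEST quantification.** The Z-spectrum is the normalized saturated signal
`Z(Δω) = S_sat(Δω) / S_0` as a function of the saturation offset Δω (ppm
relative to water). After averaging repeated acquisitions, normalizing, and
correcting each voxel for B0 inhomogeneity (water-center referencing), the
pipeline evaluates the magnetization-transfer-ratio asymmetry

    MTR_asym(Δω) = MTR(+Δω) − MTR(−Δω) = [S_sat(−Δω) − S_sat(+Δω)] / S_0

and reports two metrics per voxel, in percent:

* **APT-weighted signal** — `MTR_asym(3.5 ppm)`, the asymmetry at the amide
  proton resonance;
* **total CEST signal** — the trapezoidal integral of the `MTR_asym` curve
  over 0–4 ppm (% · ppm).

**Diffusion metrics.** A log-linear ordinary-least-squares tensor fit per
voxel, then mean diffusivity `MD = (λ1+λ2+λ3)/3` (in 10⁻³ mm²/s) and
fractional anisotropy
`FA = √(3/2) · √Σ(λi − MD)² / √Σλi²`.

**Group statistics.** ROI samples (each hemisphere a separate sample, or
averaged per subject) feed the standard chain for this literature:
mean ± 95 % CI summaries, independent-samples t-tests (control vs PD),
one-way ANOVA across control / early PD / advanced PD, and a Levene
homogeneity gate that selects Tukey HSD (Levene p ≥ 0.05) or Games-Howell
(p < 0.05) pairwise post hoc tests. A summary-statistics bridge
(`ttest_from_summary()`) reconstructs p-values directly from printed
"mean ± CI" table rows.

**Synthetic data.** `simulate_zspectrum()` propagates the coupled
Bloch-McConnell equations for water + amide (+3.5 ppm) + aliphatic NOE
(−3.5 ppm) + a semisolid MT pool through the pulsed saturation train
(200 ms × 4 at 2 µT, 10 ms gaps, 3 T) by piecewise-constant
matrix-exponential propagation; `generate_phantom()` / `generate_dwi()`
build two-slice labeled head phantoms with a smooth B0 field and seeded
Gaussian channel noise; `generate_cohort()` and `sample_roi_cohort()`
produce 23 control / 12 early / 11 advanced cohorts with lognormal
between-subject variability.

## Worked example

```r
library(cestpd)

## one Z-spectrum at the healthy substantia nigra calibration
pools <- default_pools(amide_fraction = 0.0033)
z     <- simulate_zspectrum(pools, sat_params(), default_schedule())
curve <- mtr_asym_curve(z)
apt_weighted(curve)   # 1.25   (% ; APT-weighted signal)
total_cest(curve)     # 2.37   (% * ppm ; 0-4 ppm integral)

## a small end-to-end cohort (4 controls, 3 early PD, 3 advanced PD)
cfg <- run_config(
  cohort  = cohort_config(n_control = 4, n_early_pd = 3, n_advanced_pd = 3),
  phantom = phantom_spec(shape = c(32, 32, 2)),
  seed    = 7)
res <- run_all(cfg, "demo_run")
subset(res$analysis$summaries,
       region == "substantia_nigra" & metric == "apt_weighted")
```

The last call prints the substantia nigra APT-weighted summaries of this
10-subject demo:

```
           region       metric          level  n     mean      ci95
 substantia_nigra apt_weighted        control  8 1.145424 0.1919921
 substantia_nigra apt_weighted             pd 12 1.098506 0.1299778
 substantia_nigra apt_weighted  stage:control  8 1.145424 0.1919921
 substantia_nigra apt_weighted    stage:early  6 1.193054 0.1703405
 substantia_nigra apt_weighted stage:advanced  6 1.003958 0.2207982
```

`n` counts bilateral ROI samples (2 per subject); the advanced-stage mean
sits below control, the direction of interest, though a cohort this small
does not reach significance for APTw (the FA contrast does, at p ≈ 0.002 in
`res$analysis$two_group`). `run_all()` also writes per-subject NIfTI
volumes, the ROI sample CSV, the statistics CSVs, a text report, a log and
the resolved YAML config under `demo_run/`.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/pd-cest.R", package="cestpd"))')" \
  run-all --out demo_run --seed 7 --subjects 4,3,3 --shape 32,32,2
```

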