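---
title: "Models and methods behind cestpd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cestpd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

cestpd implements the analysis chain of regional CEST/APT + DTI group
studies of Parkinson's disease — Z-spectrum quantification, B0 correction,
MTR-asymmetry metrics, tensor metrics, and Levene-gated post hoc statistics
— together with the Bloch-McConnell synthetic cohorts used to test it. This
vignette records the models, the tunable parameters, and the design choices
that were genuinely open, so that a reader can judge what a passing test
suite does and does not establish.

## The saturation model

`simulate_zspectrum()` integrates the coupled Bloch-McConnell equations for
a configurable pool set. The default tissue model has four pools:

* **water** (fraction 1, chemical shift 0; defaults T1 = 1.3 s,
  T2 = 70 ms, typical of deep gray matter at 3 T);
* **amide** at +3.5 ppm (slow exchange, k = 30 s⁻¹, T2 = 2 ms) — the pool
  whose fraction carries all disease contrast by default;
* **aliphatic NOE** at −3.5 ppm (k = 15 s⁻¹), the main upfield confound of
  asymmetry analysis;
* **semisolid MT**, centered on water, treated as a longitudinal-only pool
  saturated through a Lorentzian absorption lineshape (T2 = 10 µs). A
  super-Lorentzian lineshape is deliberately out of scope; the Lorentzian
  keeps the pool symmetric about water, which is the property that matters
  for asymmetry metrics.

Saturation is the pseudo-continuous-wave train of the emulated protocol:
four 200 ms rectangular pulses at 2 µT separated by 10 ms delays, at 3 T.
Because the irradiation is piecewise constant, the system is propagated
exactly by matrix exponentials of the per-segment generators (one for the
pulse, one for the delay), applied from thermal equilibrium; no step-size
tuning is involved. The matrix exponential itself is a compact
scaling-and-squaring Padé routine, unit-tested against `Matrix::expm` to
1e-9 and against a fixed-step RK4 integration of the same ODEs to a
relative 1e-4.

Shifted solute pools exchange with water in all three magnetization
components; the MT pool exchanges longitudinally. Readout is the water
longitudinal magnetization after the last block, normalized by its
equilibrium value — i.e. the model covers saturation, not the imaging
readout (no TR/TE, readout flip or recovery effects).

### Pool calibration

The emulated study reports no tissue parameters, so the amide fractions are
implementation constants, not claims about the source data. They live in
`inst/extdata/cohort_defaults.yaml`, not in code, and were fixed once by
simulating the default protocol and solving for the fraction that puts each
region's noiseless APT-weighted value at its healthy-control target
(substantia nigra 1.25 %, globus pallidus 0.68 %, putamen 0.83 %, caudate
0.84 %): fractions 0.0033 / 0.0026 / 0.0027 / 0.0028 relative to water.
With the amide fraction at zero the NOE/MT floor of the asymmetry is
−1.33 %; the asymmetry is linear in the amide fraction over the working
range (slope ≈ 783 % per unit fraction). One consequence worth knowing: the
simulated 0–4 ppm integral at these calibrations (≈ 2.4 % · ppm for the
substantia nigra) is smaller relative to the 3.5 ppm value than in vivo
totals, because a single 2 ms-T2 amide line is narrower than the in vivo
mixture of exchangeable resonances. Total-CEST contrasts in the synthetic
cohort are therefore meaningful in sign and ordering, not in absolute
magnitude.

## The offset schedule

`parse_schedule()` understands the compact printed convention
(`"0, ±0.25, …, ±3.5 (8), …"`): `±x` expands to both signs, `(k)` gives the
acquisition count, 1 if unspecified. The default schedule has 31 unique
offsets between ±6 ppm and 61 saturated acquisitions, with eight averages
at ±3.5 ppm and 0.25 ppm sampling within ±1 ppm of water — the near-water
density is what makes per-voxel B0 estimation possible at all.

## B0 correction

The emulated study says only that spectra were "corrected for field
inhomogeneity effects on a pixel-by-pixel basis". Two estimators are
implemented in `b0_correct()`:

* `spline_min` — the argmin of a cubic-spline interpolation of the
  Z-spectrum on a dense grid (default 0.01 ppm) inside a ±1 ppm window;
* `symmetry` (default) — the maximum-symmetry center: the grid point
  minimizing Σ_δ [Ẑ(s+δ) − Ẑ(s−δ)]² with a shape-preserving
  monotone-Hermite interpolant Ẑ and mirror offsets δ up to 0.5 ppm.

The default changed from the obvious spline minimum after measurement: at
2 µT the direct-saturation dip bottom is nearly flat (Z ≈ 0.01–0.03 across
±0.5 ppm), so its raw argmin is ill-conditioned and snaps to interpolation
wiggles, while the symmetry center remains sharply determined. The
estimator returns the grid argmin (no sub-grid refinement: a parabolic
vertex refinement was tried and removed because the amide/NOE asymmetry of
the spectrum skews the vertex a few 10⁻³ ppm off center even at zero true
shift, breaking the exactness of on-resonance quantification). Centers on
the window boundary are never trusted: the voxel is flagged invalid rather
than clamped.

`quantify_volume()` applies, by default, a 3×3 in-plane median filter to
the fitted shift map before resampling. The underlying field is spatially
smooth while the per-voxel estimate is noise-limited (the near-water
offsets are acquired once each), so this is standard regularization, and it
is disabled automatically when a precomputed field map is supplied
(`b0_map`, the testing mode).

**Accuracy, honestly stated.** With near-water samples every 0.25 ppm, all
center estimators we evaluated (spline argmin in identity and log domains,
symmetry costs with several interpolants and mirror ranges,
reflected-sample costs, fixed-point iteration, even-polynomial profile
fits, level-set midpoint inversion) share an interpolation-limited
worst-case error of ≈ 0.015–0.02 ppm over injected shifts within ±0.5 ppm,
present even for perfectly symmetric spectra. The corrected spectrum is
resampled linearly at (nominal offset + shift), which on these steep
spectra leaves a worst-case whole-spectrum deviation of order 5·10⁻², and
residual shift error propagates into the APT-weighted value at roughly
38 %/ppm. Region-mean APTw values in the phantom therefore carry a
field-dependent bias of up to a few tenths of a percent; the bias is common
to all groups (same field, same spectral family), so group *contrasts* are
unaffected — which is why the acceptance summary also reports stage
differences, which are bias-free. The tests assert these achieved figures;
tighter figures would require finer near-water sampling than the protocol
provides.

## CEST metrics

`mtr_asym_curve()` evaluates
MTR_asym(Δω) = [Z(−Δω) − Z(+Δω)] at every non-negative nominal offset whose
mirror is covered, by linear interpolation, and reports **percent**; its two
algebraically equivalent formulations (via MTR = 1 − Z, or directly from Z)
are tested to agree to 1e-14. The value at 0 ppm is identically 0, and
one-sided offsets are omitted rather than extrapolated. The emulated tables
print APTw values of ≈ 0.7–1.3 without units; that magnitude is consistent
with percent, which is the convention adopted throughout.

`apt_weighted()` reads the curve at 3.5 ppm (linear interpolation if 3.5
was not sampled). `total_cest()` integrates the percent-valued curve over
0–4 ppm by the trapezoid rule after resampling onto a uniform 0.125 ppm
grid — the source software's rule is unknown; a uniform-grid trapezoid is
insensitive to the (non-uniform) acquisition grid and is documented as the
package's choice. Averaging order is: average repeats, then divide by the
unsaturated reference; with a single reference this equals the reverse
order and has the better noise behavior.

Degenerate inputs are flagged, never zeroed: voxels with non-positive
unsaturated signal or an untrusted B0 fit carry NA in all metric maps, and
an all-invalid volume raises an explicit warning.

## Diffusion metrics

`fit_tensor()` is a per-voxel ordinary-least-squares fit of log S against
the 6-element b-matrix design (plus intercept) — exact on noiseless
single-tensor data, which the tests exploit (recovery to 1e-10). Weighted
least squares was considered and left out: at the SNR regimes simulated
here OLS tracks the reference implementations closely, and the exactness
property is what the acceptance fixtures rely on. Rank-deficient direction
sets abort; voxels with non-positive signal are invalidated; negative
eigenvalues are clamped to zero with the voxel flagged before
FA = √(3/2)·√Σ(λi−MD)²/√Σλi² and MD = Σλi/3 are computed (FA of the zero
tensor is defined as 0). MD is reported in 10⁻³ mm²/s so healthy gray
matter sits near 0.7, matching the magnitude convention of the emulated
tables. Eddy-current and motion correction and skull stripping are not
re-implemented: the synthetic inputs have neither distortion nor skull.

## The synthetic cohort

`phantom_spec()` defines a two-slice head: bilateral elliptical regions
(substantia nigra on slice 1; globus pallidus, putamen, caudate on slice 2)
in fractional coordinates so the same geometry scales from 24×24 test grids
to 64×64 defaults; a smooth in-plane B0 field with |B0| ≤ 0.1 ppm by
default (well inside the ±1 ppm search window, as after second-order
shimming); Gaussian channel noise of sd 0.005 · S0 per acquisition
(SNR 200; Gaussian, not Rician — at these saturation levels the signal
stays far from zero, and the simplification is deliberate and documented);
and per-region diffusion ground truth built as axially symmetric tensors
from (MD, FA) targets.

`cohort_config()` holds the study design: 23 controls, 12 early-stage and
11 advanced-stage PD subjects; per-region, per-stage effect multipliers on
the amide pool fraction (and on the diffusion eigenvalues, FA acting
through its anisotropy component); and lognormal between-subject and
between-hemisphere variability. Disease acts on the amide *fraction*, not
the exchange rate, reflecting the protein/peptide-content interpretation of
APT contrast; an exchange-rate mode would be a one-line change in the
generator but is off by default.

Stage multipliers are derived from per-stage metric targets (the printed
group means) through the calibrated linear map, so the generated cohort's
expected group means reproduce the table pattern: substantia nigra APTw
control > early > advanced; putamen and caudate APTw early > control;
caudate early > advanced.

**Variability calibration.** The printed CIs imply a between-sample CV of
30–45 %, but at that spread the smallest configured contrast (substantia
nigra early vs advanced, 0.96 vs 0.81 %) would reorder in well over 5 % of
cohorts, contradicting the required reproducibility of the staging pattern.
The defaults — between-subject CV 0.06, between-hemisphere CV 0.05 on the
amide component — were set by a power calculation on the configured
contrasts (z ≥ 2.3 for the binding one, accounting for the fact that both
hemispheres share the subject-level deviate, so the effective n is the
subject count). The synthetic cohort is thus a cleaner instrument than the
clinical data it emulates; passing the sign-pattern checks demonstrates the
pipeline's correctness, not clinical effect sizes.

`sample_roi_cohort()` draws the ROI sample table directly from the same
statistical model without simulating images; large-replicate properties
(type-I error over 500 cohorts, sign-pattern reproducibility over 100) are
checked at that level, with one full imaging cohort exercising the
image-domain path end to end.

## Group statistics

The chain mirrors SPSS-style practice: Student's pooled t-test by default
(Welch available); one-way ANOVA via the classic between/within
decomposition; Levene's homogeneity test in its mean-centered form (ANOVA
on |x − group mean|, verified against `car::leveneTest` to 1e-10); and the
gate: Tukey HSD when Levene's p ≥ 0.05, Games-Howell otherwise. Both post
hoc families are built on R's studentized-range distribution (`ptukey` /
`qtukey`, numerical integration validated against the published
q(0.95; 3, 10) = 3.88): Tukey with pooled variance and df = N − k,
Games-Howell with per-pair SE √(sᵢ²/nᵢ + sⱼ²/nⱼ), Welch-Satterthwaite df
and q = √2·|diff|/SE. Degenerate cells (zero variance everywhere) return
p = 1 with a flag rather than an error. No multiple-testing correction is
applied across region × metric cells, matching the emulated analysis; the
0.05 threshold is fixed.

`ttest_from_summary()` bridges printed "mean ± 95 % CI" rows to p-values
(SE = ci95 / t(0.975, n−1), Welch df); no pooled sd is recoverable from two
CIs, hence Welch. The reconstruction is insensitive to whether the printed
n counts subjects (23) or bilateral samples (46) — both conventions round
to the printed p-values — which matters because the source convention is
ambiguous (`analyze_roi_table()` ships both as `sample_unit`).

**A caution on bilateral samples.** Treating left and right ROIs as
separate samples doubles n but the two sides share the subject-level
effect; under the default variability model the intraclass correlation is
≈ 0.6 and the independent-samples t-test is measurably liberal (empirical
size ≈ 0.12 at nominal 0.05 in the null-cohort simulation). The type-I
property is therefore asserted at the subject unit, and the
hemisphere-unit inflation is itself asserted as a documented property. For
real analyses the subject unit (or a mixed model, out of scope here) is the
defensible choice.

## Problem sizes and determinism

Module tests run phantoms at 24×24×2, the acceptance suite at 32×32×2 with
the full 23/12/11 cohort, and the default generator at 64×64×2 — the
smallest grid at which ROI statistics are stable, per the phantom design.
Every generator takes an explicit seed, restores the caller's RNG state,
and is bit-reproducible: the same config and seed yield a byte-identical
ROI CSV (checksum-tested). Derived seeds stay below 2³¹.

## Known limitations

* Saturation-only signal model: no readout, TR-recovery, or slice-profile
  effects; Gaussian (not Rician) noise.
* Lorentzian MT lineshape; no super-Lorentzian option.
* B0 center estimation is interpolation-limited to ≈ 0.02 ppm at the
  protocol's near-water sampling, with the metric-level consequences
  quantified above.
* Simple bilateral-ellipse anatomy; no partial-volume or CSF compartments;
  no motion or eddy-current artifacts (and hence no preprocessing for
  them).
* The statistics chain intentionally reproduces the emulated study's
  choices, including the absence of multiple-testing correction and the
  bilateral-sample convention, with the caveats noted.
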