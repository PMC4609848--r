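# Default cohort / phantom configuration.
#
# Group sizes and the per-region, per-stage metric targets follow the study
# design this pipeline emulates (two-slice CEST of substantia nigra and
# striatum; controls vs early / advanced Parkinson subjects). Pool
# calibration constants (amide fractions, asymmetry floor) are
# implementation choices fixed by simulating the default saturation protocol
# so that the healthy phantom lands in the ~1% APT-weighted regime; they are
# configuration, not code.

groups:
  n_control: 23
  n_early_pd: 12
  n_advanced_pd: 11

variability:
  between_subject_cv: 0.06
  hemisphere_cv: 0.05
  fa_between_subject_cv: 0.08
  fa_hemisphere_cv: 0.04
  md_between_subject_cv: 0.03
  md_hemisphere_cv: 0.02

calibration:
  # MTR_asym(3.5 ppm), percent, of the tissue model with the amide fraction
  # set to zero (NOE/MT floor), and the simulated slope per unit fraction.
  apt_floor: -1.3317
  amide_slope: 782.5
  # corresponding 0-4 ppm integral floor (percent * ppm)
  tc_floor: -2.5101

background:
  amide_fraction: 0.002838
  fa: 0.10
  md: 0.80

regions:
  substantia_nigra:
    slice: 1
    center: [0.62, 0.45]
    semiaxes: [0.08, 0.05]
    amide_fraction: 0.003299
    apt_targets: {control: 1.25, early: 0.96, advanced: 0.81}
    total_cest_targets: {control: 3.45, early: 2.68, advanced: 2.21}
    fa_targets: {control: 0.36, early: 0.34, advanced: 0.31}
    md_targets: {control: 0.68, early: 0.69, advanced: 0.70}
  globus_pallidus:
    slice: 2
    center: [0.60, 0.50]
    semiaxes: [0.05, 0.045]
    amide_fraction: 0.002551
    apt_targets: {control: 0.68, early: 0.89, advanced: 0.78}
    total_cest_targets: {control: 2.20, early: 2.60, advanced: 2.34}
    fa_targets: {control: 0.25, early: 0.23, advanced: 0.24}
    md_targets: {control: 0.70, early: 0.71, advanced: 0.73}
  putamen:
    slice: 2
    center: [0.74, 0.50]
    semiaxes: [0.06, 0.09]
    amide_fraction: 0.002746
    apt_targets: {control: 0.83, early: 1.12, advanced: 0.99}
    total_cest_targets: {control: 2.68, early: 3.10, advanced: 2.92}
    fa_targets: {control: 0.14, early: 0.14, advanced: 0.14}
    md_targets: {control: 0.72, early: 0.72, advanced: 0.74}
  caudate:
    slice: 2
    center: [0.60, 0.68]
    semiaxes: [0.05, 0.07]
    amide_fraction: 0.002760
    apt_targets: {control: 0.84, early: 1.35, advanced: 0.91}
    total_cest_targets: {control: 2.79, early: 3.06, advanced: 2.73}
    fa_targets: {control: 0.16, early: 0.16, advanced: 0.15}
    md_targets: {control: 0.74, early: 0.75, advanced: 0.74}
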