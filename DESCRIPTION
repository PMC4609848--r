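Package: cestpd
Title: CEST/APT and Diffusion MRI Quantification for Basal Ganglia Group Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantification and group-comparison pipeline for chemical exchange
    saturation transfer (CEST/APT) and diffusion tensor MRI of the substantia
    nigra and striatum. Provides a multi-pool Bloch-McConnell saturation
    simulator and synthetic two-slice brain phantom cohorts; Z-spectrum
    normalization, spline-minimum B0 inhomogeneity correction, MTR asymmetry
    at 3.5 ppm (APT-weighted) and 0-4 ppm integral CEST maps; log-linear
    diffusion tensor fitting with FA and MD maps; and the group statistics
    chain used in regional CEST studies of Parkinson disease: mean +/- 95% CI
    summaries, independent t-tests, one-way ANOVA with a Levene homogeneity
    gate selecting Tukey HSD or Games-Howell post hoc comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    Matrix,
    withr
Config/testthat/edition: 3
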