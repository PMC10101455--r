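Package: nmvolumetry
Title: Neuromelanin-Sensitive MRI Volumetry of Substantia Nigra and Locus Coeruleus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated volumetry of the substantia nigra pars compacta (SNc)
    and locus coeruleus (LC) from neuromelanin-sensitive MRI: motion
    correction and averaging of repeated measurements, atlas-localized
    reference-ROI intensity-threshold segmentation, and cohort statistics
    (Welch t-tests, ANCOVA, age-adjusted partial correlations, ROC/AUC with
    Hanley-McNeil standard errors). Ships a parametric NM-MRI phantom
    generator with known ground truth so the full pipeline can be exercised
    and validated end-to-end without scanner data.
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
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
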