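Package: dcaMS
Title: Derivative Component Analysis for Mass Spectral Proteomic Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Multiresolution denoising and implicit feature selection for
    mass spectral serum proteomic profiles. Spectra are decomposed channel-wise
    with a periodized orthogonal discrete wavelet transform; fine-level detail
    coefficient matrices are replaced by their leading principal-component
    reconstructions while coarse levels pass through unchanged, and the inverse
    transform yields a same-dimensional denoised "meta-data" panel. The package
    couples this transform with a linear support vector machine classifier
    (binary and one-against-one multiclass with max-wins voting), t/F-statistic
    biomarker ranking with a linear-separability check, a repeated stratified
    cross-validation harness with confusion-derived diagnostic metrics, and a
    seeded generator of synthetic serum-like spectra for controlled evaluation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'wavelet-filters.R'
    'AllClasses.R'
    'AllGenerics.R'
    'spectra-io.R'
    'wavelet.R'
    'dca.R'
    'svm.R'
    'biomarker.R'
    'evaluation.R'
    'simulate.R'
    'cli.R'
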