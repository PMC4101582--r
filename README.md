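# dcaMS

Derivative component analysis for mass spectral serum proteomic profiles.

## The problem

Serum proteomic profiles from MALDI-TOF / SELDI-TOF platforms are panels of
10^3–10^4 m/z intensity channels measured on on the order of 10^2 subjects.
Disease classes often share their *global* structure — the same major peaks
at almost the same heights — and differ only in *subtle*, rapidly varying
low-amplitude structure that is buried well below the per-channel noise
level. Conventional feature selection (univariate filters, PCA subspaces)
works at the raw data level and tends to miss this fine structure, while the
noise it leaves behind degrades downstream classifiers.

`dcaMS` implements derivative component analysis (DCA), a multiresolution
denoising transform that acts as an implicit feature selector, together with
the classification, biomarker-ranking and evaluation machinery built on it.

## The method

For a panel X (samples × channels), each spectrum is decomposed with a
J-level orthogonal discrete wavelet transform (Daubechies `db8` by default,
periodized boundary) into detail coefficient matrices cD1..cDJ and an
approximation cAJ. Fine levels (j ≤ τ, default τ = 2) carry the subtle
structure — and most of the noise. DCA replaces each fine-level matrix by a
rank-m principal-component reconstruction,

    cDj  ←  mean term  +  Σ_{i≤m} u_i s_iᵀ ,          (default m = 1)

keeps the coarse levels j > τ and cAJ untouched, and inverts the transform.
The result, the *meta-data* X\*, has the same dimensions as the input but
with the fine bands collapsed onto their dominant component: the subtle
class signature survives, the isotropic noise in those bands does not. The
number of components can alternatively be chosen per level as the smallest
m whose variability explanation ratio ρ_m = Σ_{i≤m}σ_i / Σσ_i reaches a
threshold (conventionally 60%).

On the meta-data the package provides:

* **DCA-SVM** — soft-margin linear SVM (binary, and one-against-one
  multiclass with max-wins voting) for disease diagnosis;
* **DCA-MARK** — per-channel t-statistic (binary, Welch or pooled) or
  F-statistic (multiclass) biomarker ranking, with a linear-separability
  check on the top-ranked channels;
* an evaluation harness — repeated stratified k-fold cross-validation with
  accuracy, sensitivity TP/(TP+FN), specificity TN/(TN+FP) and positive
  prediction ratio TP/(TP+FP), comparing DCA-SVM against a plain linear SVM
  and a p < 0.05 univariate-filter SVM;
* a seeded generator of synthetic serum-like spectra (Gaussian peaks,
  exponential baseline, class-dependent fine-band ripple, white noise) with
  ground truth, used as the controlled test bed.

## Worked example

```r
library(dcaMS)

## a 100 x 1024 panel whose two classes share every peak and differ only in
## the amplitude of a fine-band ripple an order of magnitude below the noise
sim <- simulateSpectra(simulationPreset("binary_subtle", seed = 1))
sim$spectra
#> SpectraMatrix: 100 samples x 1024 channels
#>   m/z range: [ 500 , 10000 ]
#>   labels: case=50, control=50

model <- dca(sim$spectra, verbose = TRUE)   # db8, J = 7, tau = 2, m = 1
#> level 1: 100 x 512, m = 1, rho_m = 0.576
#> level 2: 100 x 256, m = 1, rho_m = 0.649

report <- crossValidate(sim$spectra, methods = c("dca_svm", "svm"),
                        k = 5, repeats = 10, seed = 1)
report
#> EvalReport: 10 x 5 -fold CV | seed 1
#>   dca_svm  accuracy 0.8500 (sd 0.0789)
#>   svm      accuracy 0.7770 (sd 0.0648)
```

The first principal component explains 58% / 65% of the variance of the two
fine detail levels, and classifying the denoised meta-data raises the mean
cross-validated accuracy by about 7 percentage points over the same SVM on
the raw panel — the subtle class signature is only usable after the fine
bands are collapsed onto their dominant component.

Biomarker ranking on a panel with genuine differential peaks pinpoints the
discriminative channels and confirms linear separability:

```r
simG <- simulateSpectra(simulationPreset("binary_global", seed = 1))
rankBiomarkers(metaData(dca(simG$spectra)))
#>  rank channel       mz statistic       p_value kind
#>     1     214 2478.006  158.5604 1.068558e-116    t
#>     2     213 2468.719  129.6874 2.468053e-109    t
#>     3     215 2487.292  129.5157 5.079875e-111    t
```

All three sit on the first differential peak (2500 Da). A command-line
front end wrapping the same functions is installed at
`inst/scripts/dca` (subcommands `simulate`, `transform`, `classify`,
`biomarkers`, `evaluate`).

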