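---
title: "Derivative component analysis: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Derivative component analysis: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcaMS)
```

## The model

A serum proteomic panel is a matrix $X \in \mathbb{R}^{n \times p}$ of $n$
samples by $p$ m/z channels, $p \gg n$. We model each spectrum as a smooth
global component (baseline and peaks), a low-amplitude rapidly oscillating
"subtle" component, and additive noise. The central assumption of
derivative component analysis (DCA) is a *scale separation*: the global
component lives in the coarse bands of a multiresolution decomposition, the
subtle component and most of the noise live in the fine bands, and within
the fine bands the biologically meaningful structure is low-rank across
samples while the noise is isotropic.

The transform proceeds in three steps:

1. **Decompose.** Each sample's spectrum is passed through a $J$-level
   orthogonal discrete wavelet transform along the m/z axis, giving detail
   coefficient matrices $cD_1 \dots cD_J$ (fine to coarse) and the
   approximation $cA_J$. Under the default periodized boundary the
   transform is orthonormal, so coefficient energies add up exactly to the
   panel's energy and the inverse is exact.
2. **Rank-reduce the fine bands.** For every level $j \le \tau$ the detail
   matrix is replaced by a mean term plus its rank-$m$ truncated singular
   value decomposition; levels above $\tau$ and $cA_J$ pass through
   untouched.
3. **Invert.** The inverse transform of the modified coefficients yields
   the *meta-data* $X^*$, a same-dimensional denoised panel.

Because the reconstruction keeps whole channels rather than selecting a
subset, DCA acts as an *implicit* feature selector: nothing is removed from
the channel axis, but the effective dimensionality of the fine bands drops
from thousands of noisy coefficients to $m$ directions per level.

## The centering choice

Step 2 admits two readings that differ in what is treated as an
observation, and the difference matters.

* `center = "sample"` (the default). Each sample's detail row is centered
  by its own mean coefficient, and the principal components are computed
  over *coefficient positions*: the covariance is $n \times n$ across
  samples, estimated from $p_j$ coefficient positions. Since fine levels
  are much wider than the sample count ($p_j \gg n$), this eigenproblem is
  well conditioned, and the leading component reliably recovers a shared
  oscillatory template together with each sample's amplitude on it. This is
  the reconstruction rule the transform is built around, and the one that
  makes the denoised fine bands informative at realistic noise levels: in
  our simulations it is the only variant whose meta-data classify better
  than the raw panel (see below).
* `center = "coefficient"`. Classic PCA of samples: the per-coefficient
  mean across samples is removed and components live in coefficient space
  estimated from $n$ samples. With $p_j / n \approx 5$ the leading sample
  eigenvector is dominated by estimation noise unless the fine-band
  structure is very strong, and the meta-data then tend to classify *worse*
  than the raw panel. The variant is retained because it is the natural
  reading for users coming from standard PCA denoising, and because it is
  the form against which the truncated-SVD oracle in the test suite is
  easiest to state; every contract (Eckart–Young equivalence, identity
  limit, monotone fidelity, self-consistent model application) is tested
  for both centerings.

Both variants store orthonormal coefficient-space loadings; they differ
only in which mean is removed and added back. `applyModel()` uses the
stored loadings with the matching centering (a new sample's own row mean
under `"sample"`, the stored training mean under `"coefficient"`), so
fitting on training folds and applying to held-out folds is leakage-free.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `wavelet` | `db8` | Orthogonal, compactly supported; 8 vanishing moments keep smooth peak shapes out of the fine bands. `haar`/`db1`–`db10` available. |
| `level` (J) | 7 | Deep enough that the coarse bands isolate baseline and peak structure on $10^3$–$10^4$-channel panels; advisory range $4 \le J \le \lceil \log_2 p \rceil$ (a warning, not an error). |
| `tau` | 2 | Levels 1..tau are treated as "fine" and rank-reduced; advisory range $1 < \tau \le J/2$. `tau = 0` switches the transform off (identity). |
| `m` | 1 | Components kept per fine level. The first component typically explains well over half of a fine level's variance, and more components mostly re-admit noise. |
| `rho` | unset | When supplied, per-level $m$ is the smallest with $\rho_m \ge$ `rho` (conventional threshold 0.60) instead of the fixed `m`. |
| `boundary` | `periodization` | Coefficient counts halve exactly and the transform is orthonormal; `symmetric` avoids wrap-around at the spectrum ends at the cost of a few extra boundary coefficients per level. |
| `fitMode` | `transductive` | The transform is fitted once on the full panel before cross-validation; `inductive` refits per training split. |
| `C` (SVM) | 1 | Conventional soft-margin cost; the separability check uses a large cost (1e6) to approximate a hard margin. |

## Numerical choices

* **Odd widths.** Under periodization an odd-length level is extended by
  repeating its last sample before filtering; the extension is removed
  again on inversion, so reconstruction stays exact for arbitrary channel
  counts ($p_j = \lceil p_{j-1}/2 \rceil$). A `padToDyadic` option instead
  right-pads the panel to the next power of two with its edge value.
* **Sign convention.** Each loading is oriented so its largest-magnitude
  entry is positive. Reconstruction is sign-invariant; the convention only
  makes stored models reproducible.
* **Degenerate inputs.** An all-zero fine level yields explained ratio 1
  with a warning; constant channels score $t = 0$, $p = 1$ in the
  biomarker ranking (and are counted in a message); confusion metrics with
  a zero denominator return NaN with a warning instead of failing.
* **Ties.** Biomarker ranking breaks statistic ties by the lower channel
  index. Max-wins voting breaks vote ties by the largest sum of absolute
  decision values over the comparisons each tied class won, then by the
  lexicographically smallest class code. Decision value 0 resolves to the
  +1 class. All three rules make results order- and run-independent.
* **Solver tolerances.** The SVM dual is solved by the SMO implementation
  in `e1071` at tolerance 1e-6 (1e-4 inside cross-validation); the trained
  models are checked against their optimality conditions —
  $0 \le \alpha_i \le C$, $\sum \alpha_i c_i = 0$,
  $w = \sum \alpha_i c_i y_i$ — at 1e-6, and strong duality holds to 1e-4
  on separable problems.
* **Statistics.** The two-sample statistic is the absolute-value form
  $|\bar x - \bar y| / \sqrt{s_x^2/n_1 + s_y^2/n_2}$ (Welch, the literal
  formula) with the pooled-variance form behind a flag; $p$-values are
  two-sided and unadjusted by default (Benjamini–Hochberg available behind
  a flag), matching the univariate-filter baseline's raw $p < 0.05$ rule.
  For two pooled-variance classes $F = t^2$ holds to 1e-10, which the
  suite verifies, with `stats::t.test`/`stats::oneway.test` as independent
  oracles.

## The synthetic generator

`simulateSpectra()` emulates the *shape* of benchmark serum panels
($10^2$-order samples, $10^3$-order channels, 2–4 classes) and the
global-versus-subtle dichotomy, not mass-spectrometric physics. A sample of
class $g$ is

$$ x_s = scale_s \,\big[\, b(x) + \textstyle\sum_p h_{g,p}\,
   G(x;\,loc_p, w_p) + a_s\, r(x) \,\big] + \varepsilon, $$

with an exponentially decaying baseline $b$, Gaussian peaks $G$, a fixed
zero-mean unit-RMS ripple template $r$ (a standardized sum of 16 cosines
with wavelengths of 2.5–7 channels, so its energy is concentrated in the
two finest dyadic bands — exactly the levels reconstructed at
$\tau = 2$), per-sample amplitude $a_s$ (class value plus optional
jitter), lognormal scale jitter and white noise
$\varepsilon \sim N(0, \sigma^2)$. The noise-free part is returned as
ground truth.

Three presets define the study conditions used by the test suite:

* `binary_global` — 50 + 50 samples, three of six peaks 30% higher in the
  case class, noise sd 0.3, no ripple. At these settings the differential
  peak apexes separate the classes by ~15 noise standard deviations, so
  the top-3 biomarker channels are linearly separable by construction.
* `binary_subtle` — 50 + 50 samples, identical peaks, both classes carry
  the ripple (base amplitude 1.0) with the case class at 1.125, noise sd
  1. The per-channel class gap (0.125) is an order of magnitude below the
  noise, so single-channel statistics are nearly useless — the signature
  is recoverable only by aggregating a fine band, which is precisely the
  property the denoise-then-classify comparison exploits. The shared base
  amplitude reflects the intended regime: both phenotypes exhibit the
  subtle oscillation, the disease changes its strength.
* `three_class` — 30 + 30 + 30 samples with the middle class's
  differential peak heights halfway between the outer two, mimicking an
  intermediate pathological stage.

What the generator does **not** emulate: isotope envelopes, peak-shape
asymmetry (EMG tails), detector saturation, calibration drift,
heteroscedastic or correlated noise, and batch effects. Passing the
simulation-based tests therefore demonstrates the transform's mechanism
under its own assumptions, not clinical performance on real spectra.

## Evaluation harness

Cross-validation is stratified (per-class fold counts differ by at most
one) and repeated; repeat $r$ draws its folds from seed $+\,r-1$, so a run
is fully reproducible from one integer. Ten repeats of 5-fold CV is the
default — enough replication for meaningful standard deviations at
desk-scale panel sizes. The default *transductive* mode fits the transform
(and the univariate filter of the `fs_svm` baseline) once on the full
panel; this is the conventional protocol for transductive denoisers but
lets test-fold samples influence the fitted directions, so the *inductive*
mode — refit per training split, apply to the held-out fold — is provided
and tested as the statistically safe alternative. Multiclass accuracy is
top-1; sensitivity, specificity and positive prediction ratio always
derive from an explicit, recorded binarization of the class set.

The test suite and the acceptance script run everything at desk scale —
panels of 100 samples by 1024 channels, 8–20-sample coefficient matrices
for the oracle checks — which keeps the full suite under half a minute
while exercising every contract at realistic $p/n$ ratios.

## Known limitations

* The fine-band structure must genuinely be low-rank across samples for
  the rank-1 default to help; panels whose subtle variation spans several
  independent templates need `m > 1` or the `rho` rule.
* With `center = "coefficient"` and weak signals the leading component can
  be a noise direction, making the meta-data worse than the raw panel —
  this is inherent to sample-space PCA at $p_j \gg n$, not a bug.
* The transductive default is not leakage-free; use `fitMode =
  "inductive"` for honest generalization estimates.
* No multiple-testing correction is applied by default in the biomarker
  table; the ranking is unaffected, but the raw $p$-values should not be
  read as genome-wide significance claims.
* Optimal selection of $J$ and $\tau$ (e.g. by entropy criteria) is out of
  scope; the defaults are fixed, documented conventions.
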