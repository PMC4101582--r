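#' @import methods
NULL

#' SpectraMatrix: a sample-by-channel intensity panel
#'
#' Holds a panel of mass spectra stored sample-major: one row per sample, one
#' column per m/z channel. The m/z axis must be strictly increasing and all
#' intensities finite. Class labels are optional; when present there must be
#' at least two samples and at least two distinct classes.
#'
#' @slot intensities numeric matrix, n_samples x n_channels.
#' @slot mz numeric vector of channel m/z values (Daltons), strictly
#'   increasing, length n_channels.
#' @slot sampleIds character vector of unique sample identifiers.
#' @slot labels character vector of class codes, either empty (no labels) or
#'   of length n_samples.
#' @aliases SpectraMatrix
#' @exportClass SpectraMatrix
setClass("SpectraMatrix",
  representation(
    intensities = "matrix",
    mz = "numeric",
    sampleIds = "character",
    labels = "character"
  )
)

setValidity("SpectraMatrix", function(object) {
  x <- object@intensities
  msg <- character(0)
  if (!is.numeric(x)) msg <- c(msg, "intensities must be a numeric matrix")
  if (anyNA(x) || any(!is.finite(x)))
    msg <- c(msg, "intensities contain missing or non-finite values")
  if (length(object@mz) != ncol(x))
    msg <- c(msg, "length(mz) must equal the number of channels")
  if (length(object@mz) > 1 && any(diff(object@mz) <= 0))
    msg <- c(msg, "mz values must be strictly increasing")
  if (length(object@sampleIds) != nrow(x))
    msg <- c(msg, "length(sampleIds) must equal the number of samples")
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "sampleIds must be unique")
  if (length(object@labels) > 0) {
    if (length(object@labels) != nrow(x))
      msg <- c(msg, "labels must have one entry per sample")
    if (nrow(x) < 2)
      msg <- c(msg, "at least 2 samples are required when labels are present")
    if (length(unique(object@labels)) < 2)
      msg <- c(msg, "labels must contain at least 2 distinct classes")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpectraMatrix
#'
#' @param intensities numeric matrix, samples in rows, channels in columns.
#' @param mz strictly increasing numeric vector of channel m/z values;
#'   defaults to 1..n_channels.
#' @param sampleIds character sample identifiers; defaults to "S1", "S2", ...
#' @param labels optional character vector of class codes (one per sample).
#' @return A validated \linkS4class{SpectraMatrix}.
#' @examples
#' sm <- SpectraMatrix(matrix(rnorm(32), 4, 8))
#' dim(sm)
#' @export
SpectraMatrix <- function(intensities, mz = NULL, sampleIds = NULL,
                          labels = character(0)) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (is.null(mz)) mz <- seq_len(ncol(intensities))
  if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(nrow(intensities)))
  if (is.null(labels)) labels <- character(0)
  new("SpectraMatrix", intensities = intensities, mz = as.numeric(mz),
      sampleIds = as.character(sampleIds), labels = as.character(labels))
}

#' @describeIn SpectraMatrix dimensions (samples, channels)
#' @param x a SpectraMatrix.
#' @export
setMethod("dim", "SpectraMatrix", function(x) dim(x@intensities))

setMethod("show", "SpectraMatrix", function(object) {
  d <- dim(object)
  cat("SpectraMatrix:", d[1], "samples x", d[2], "channels\n")
  cat("  m/z range: [", format(min(object@mz)), ",",
      format(max(object@mz)), "]\n")
  if (length(object@labels)) {
    tb <- table(object@labels)
    cat("  labels:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  } else {
    cat("  labels: none\n")
  }
})

#' WaveletConfig: settings of the channel-axis discrete wavelet transform
#'
#' @slot wavelet name of an orthogonal compact-support wavelet
#'   (\code{"haar"}, \code{"db1"} ... \code{"db10"}).
#' @slot level integer transform depth J.
#' @slot boundary boundary handling, \code{"periodization"} (coefficient
#'   counts halve exactly) or \code{"symmetric"} (a few extra boundary
#'   coefficients per level).
#' @aliases WaveletConfig
#' @exportClass WaveletConfig
setClass("WaveletConfig",
  representation(wavelet = "character", level = "integer",
                 boundary = "character")
)

setValidity("WaveletConfig", function(object) {
  msg <- character(0)
  if (length(object@level) != 1 || object@level < 1)
    msg <- c(msg, "level must be a single integer >= 1")
  if (!object@boundary %in% c("periodization", "symmetric"))
    msg <- c(msg, "boundary must be 'periodization' or 'symmetric'")
  ok <- tryCatch({ waveletFilters(object@wavelet); TRUE },
                 error = function(e) FALSE)
  if (!ok) msg <- c(msg, paste0("unknown wavelet '", object@wavelet, "'"))
  if (length(msg)) msg else TRUE
})

#' Construct a WaveletConfig
#'
#' @param wavelet wavelet name (default \code{"db8"}).
#' @param level transform depth J.
#' @param boundary \code{"periodization"} (default) or \code{"symmetric"}.
#' @return A validated \linkS4class{WaveletConfig}.
#' @examples
#' waveletConfig("db8", level = 5)
#' @export
waveletConfig <- function(wavelet = "db8", level = 7L,
                          boundary = c("periodization", "symmetric")) {
  boundary <- match.arg(boundary)
  new("WaveletConfig", wavelet = wavelet, level = as.integer(level),
      boundary = boundary)
}

setMethod("show", "WaveletConfig", function(object) {
  cat("WaveletConfig:", object@wavelet, "| J =", object@level,
      "|", object@boundary, "\n")
})

#' WaveletDecomposition: J-level multiresolution coefficients of a panel
#'
#' Per-level detail coefficient matrices cD1..cDJ (fine to coarse) and the
#' level-J approximation matrix cAJ, each with one row per sample.
#'
#' @slot details list of J numeric matrices, element j holding level-j detail
#'   coefficients.
#' @slot approx numeric matrix of level-J approximation coefficients.
#' @slot config the \linkS4class{WaveletConfig} used.
#' @slot nChannels original channel count of the decomposed panel.
#' @slot inputLengths integer vector, signal length entering each level
#'   (needed to undo odd-length padding on inversion).
#' @aliases WaveletDecomposition
#' @exportClass WaveletDecomposition
setClass("WaveletDecomposition",
  representation(
    details = "list",
    approx = "matrix",
    config = "WaveletConfig",
    nChannels = "integer",
    inputLengths = "integer"
  )
)

setValidity("WaveletDecomposition", function(object) {
  msg <- character(0)
  J <- object@config@level
  if (length(object@details) != J)
    msg <- c(msg, "details must hold one matrix per level")
  ns <- vapply(object@details, nrow, integer(1))
  if (length(ns) && (any(ns != nrow(object@approx))))
    msg <- c(msg, "all coefficient matrices must share the sample count")
  if (length(object@inputLengths) != J)
    msg <- c(msg, "inputLengths must have one entry per level")
  if (length(msg)) msg else TRUE
})

setMethod("show", "WaveletDecomposition", function(object) {
  J <- object@config@level
  cols <- vapply(object@details, ncol, integer(1))
  cat("WaveletDecomposition:", nrow(object@approx), "samples,",
      object@nChannels, "channels,", object@config@wavelet,
      paste0("(", object@config@boundary, ")"), "\n")
  cat("  detail columns cD1..cD", J, ": ", paste(cols, collapse = ", "),
      "; approx: ", ncol(object@approx), "\n", sep = "")
})

#' DCAConfig: parameters of the derivative-component transform
#'
#' @slot wavelet a \linkS4class{WaveletConfig}.
#' @slot tau integer cutoff: detail levels 1..tau are rank-reduced ("fine"),
#'   levels above tau and the approximation pass through unchanged.
#' @slot m number of principal components kept per fine level; ignored when
#'   \code{rho} is finite.
#' @slot rho variability-explanation threshold in (0, 1]; when finite, the
#'   smallest m with cumulative explained ratio >= rho is used per level.
#' @slot center \code{"sample"}: remove each sample's own mean coefficient
#'   and run the PCA over coefficient positions (the transform's native
#'   reconstruction rule); \code{"coefficient"}: classic PCA removing the
#'   per-coefficient mean across samples.
#' @slot fitMode \code{"transductive"} (fit on the full panel) or
#'   \code{"inductive"} (fit on training data only, apply to new samples).
#' @aliases DCAConfig
#' @exportClass DCAConfig
setClass("DCAConfig",
  representation(wavelet = "WaveletConfig", tau = "integer", m = "integer",
                 rho = "numeric", center = "character", fitMode = "character")
)

setValidity("DCAConfig", function(object) {
  msg <- character(0)
  if (object@tau < 0 || object@tau > object@wavelet@level)
    msg <- c(msg, "tau must satisfy 0 <= tau <= wavelet level (0 = identity)")
  if (!is.na(object@rho) && (object@rho <= 0 || object@rho > 1))
    msg <- c(msg, "rho must lie in (0, 1]")
  if (is.na(object@rho) && object@m < 1)
    msg <- c(msg, "m must be >= 1")
  if (!object@center %in% c("sample", "coefficient"))
    msg <- c(msg, "center must be 'sample' or 'coefficient'")
  if (!object@fitMode %in% c("transductive", "inductive"))
    msg <- c(msg, "fitMode must be 'transductive' or 'inductive'")
  if (length(msg)) msg else TRUE
})

#' Construct a DCAConfig
#'
#' Defaults follow the transform's standard tuning: db8 wavelet, J = 7,
#' cutoff tau = 2, first principal component only (m = 1). The recommended
#' ranges 4 <= J and 1 < tau <= J/2 are advisory: values outside them raise a
#' warning, not an error.
#'
#' @param wavelet a \linkS4class{WaveletConfig} (default db8, J = 7,
#'   periodization).
#' @param tau fine/coarse cutoff level (default 2).
#' @param m components kept per fine level (default 1).
#' @param rho optional variability-explanation threshold; when supplied the
#'   per-level m is the smallest one whose cumulative explained ratio reaches
#'   it (conventional choice 0.60).
#' @param center \code{"sample"} (default) or \code{"coefficient"}, see
#'   \linkS4class{DCAConfig}.
#' @param fitMode \code{"transductive"} (default) or \code{"inductive"}.
#' @return A validated \linkS4class{DCAConfig}.
#' @examples
#' dcaConfig(tau = 2, m = 1)
#' @export
dcaConfig <- function(wavelet = waveletConfig("db8", 7L), tau = 2L, m = 1L,
                      rho = NULL, center = c("sample", "coefficient"),
                      fitMode = c("transductive", "inductive")) {
  center <- match.arg(center)
  fitMode <- match.arg(fitMode)
  cfg <- new("DCAConfig", wavelet = wavelet, tau = as.integer(tau),
             m = as.integer(m), rho = if (is.null(rho)) NA_real_ else rho,
             center = center, fitMode = fitMode)
  J <- wavelet@level
  if (J < 4)
    warning("transform level J = ", J, " below the recommended range J >= 4")
  if (!(cfg@tau > 1 && cfg@tau <= J / 2))
    warning("cutoff tau = ", cfg@tau,
            " outside the recommended range 1 < tau <= J/2")
  cfg
}

setMethod("show", "DCAConfig", function(object) {
  cat("DCAConfig:", object@wavelet@wavelet, "J =", object@wavelet@level,
      "| tau =", object@tau,
      if (is.na(object@rho)) paste("| m =", object@m)
      else paste("| rho >=", object@rho),
      "| center =", object@center, "|", object@fitMode, "\n")
})

#' DCAModel: a fitted derivative-component transform
#'
#' Stores, for each fine level, the orthonormal coefficient-space loadings of
#' the retained principal components, the per-coefficient training mean, and
#' the eigenvalue spectrum, together with the denoised panel ("meta-data")
#' computed at fit time.
#'
#' @slot config the \linkS4class{DCAConfig} used.
#' @slot loadings list over fine levels of n_j x m orthonormal matrices.
#' @slot means list over fine levels of per-coefficient training means.
#' @slot explained list over fine levels of non-increasing eigenvalues of the
#'   level's covariance.
#' @slot mUsed integer vector: components kept at each fine level.
#' @slot rhoM numeric vector: variability-explanation ratio achieved by the
#'   kept components at each fine level.
#' @slot meta the denoised \linkS4class{SpectraMatrix} for the fitted panel.
#' @slot nChannels channel count the model was fitted on.
#' @aliases DCAModel
#' @exportClass DCAModel
setClass("DCAModel",
  representation(config = "DCAConfig", loadings = "list", means = "list",
                 explained = "list", mUsed = "integer", rhoM = "numeric",
                 meta = "SpectraMatrix", nChannels = "integer")
)

setMethod("show", "DCAModel", function(object) {
  cat("DCAModel:", object@nChannels, "channels |", sep = " ")
  show(object@config)
  for (j in seq_along(object@loadings)) {
    cat(sprintf("  level %d: m = %d, rho_m = %.3f\n", j, object@mUsed[j],
                object@rhoM[j]))
  }
})

#' SvmModel: a trained soft-margin linear support vector machine
#'
#' @slot alphas non-negative Lagrange multipliers of the support vectors.
#' @slot supportVectors matrix of support vectors (rows).
#' @slot supportLabels numeric +1/-1 labels of the support vectors.
#' @slot bias intercept b of the decision function w.x + b.
#' @slot cost the regularization constant C.
#' @slot w normal vector of the maximum-margin hyperplane.
#' @slot classMap character of length 2: original class codes mapped to +1
#'   and -1 respectively.
#' @aliases SvmModel
#' @exportClass SvmModel
setClass("SvmModel",
  representation(alphas = "numeric", supportVectors = "matrix",
                 supportLabels = "numeric", bias = "numeric",
                 cost = "numeric", w = "numeric", classMap = "character")
)

setValidity("SvmModel", function(object) {
  msg <- character(0)
  tol <- 1e-6
  if (any(object@alphas < -tol) || any(object@alphas > object@cost + tol))
    msg <- c(msg, "alphas must satisfy 0 <= alpha <= C")
  if (abs(sum(object@alphas * object@supportLabels)) > 1e-6)
    msg <- c(msg, "dual constraint sum(alpha * c) = 0 violated")
  wref <- drop(crossprod(object@supportVectors,
                         object@alphas * object@supportLabels))
  if (sqrt(sum((object@w - wref)^2)) > 1e-6 * (1 + sqrt(sum(object@w^2))))
    msg <- c(msg, "w must equal sum(alpha * c * y)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SvmModel", function(object) {
  cat("SvmModel: linear kernel, C =", object@cost, "|",
      length(object@alphas), "support vectors |",
      "classes:", paste0(object@classMap[1], " -> +1, ",
                         object@classMap[2], " -> -1"), "\n")
})

#' MulticlassModel: one-against-one linear SVMs with max-wins voting
#'
#' @slot classSet sorted class codes.
#' @slot models list of k(k-1)/2 pairwise \linkS4class{SvmModel}s named
#'   "i|j" with i < j lexicographically.
#' @slot cost the shared regularization constant C.
#' @aliases MulticlassModel
#' @exportClass MulticlassModel
setClass("MulticlassModel",
  representation(classSet = "character", models = "list", cost = "numeric")
)

setValidity("MulticlassModel", function(object) {
  k <- length(object@classSet)
  if (length(object@models) != k * (k - 1) / 2)
    "there must be exactly k(k-1)/2 pairwise models" else TRUE
})

setMethod("show", "MulticlassModel", function(object) {
  cat("MulticlassModel:", length(object@classSet), "classes (",
      paste(object@classSet, collapse = ", "), ") |",
      length(object@models), "pairwise models | C =", object@cost, "\n")
})

#' EvalReport: repeated cross-validation results
#'
#' @slot folds data.frame with one row per repeat x fold x method holding
#'   accuracy, sensitivity, specificity, ppv and the confusion counts.
#' @slot summary data.frame of per-method mean and standard deviation for
#'   each metric.
#' @slot metadata list of run settings (seed, k, repeats, methods, C,
#'   transform configuration, fit mode, binarization map, schema version).
#' @aliases EvalReport
#' @exportClass EvalReport
setClass("EvalReport",
  representation(folds = "data.frame", summary = "data.frame",
                 metadata = "list")
)

setMethod("show", "EvalReport", function(object) {
  md <- object@metadata
  cat("EvalReport:", md$repeats, "x", md$k, "-fold CV | seed", md$seed, "\n")
  s <- object@summary
  acc <- s[s$metric == "accuracy", ]
  for (i in seq_len(nrow(acc))) {
    cat(sprintf("  %-8s accuracy %.4f (sd %.4f)\n", acc$method[i],
                acc$mean[i], acc$sd[i]))
  }
})
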