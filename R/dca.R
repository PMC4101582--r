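#' Fraction of variance explained by the leading principal components
#'
#' Given the non-increasing eigenvalue spectrum of a covariance matrix,
#' returns the ratio between the variance carried by the first m components
#' and the total variance. A degenerate all-zero spectrum yields 1 with a
#' warning.
#'
#' @param variances non-increasing, non-negative eigenvalues.
#' @param m number of leading components, 1 <= m <= length(variances).
#' @return The explained-variance fraction in [0, 1].
#' @examples
#' variabilityRatio(c(3, 1), 1)   # 0.75
#' @export
variabilityRatio <- function(variances, m) {
  if (length(m) != 1 || is.na(m) || m < 1 || m > length(variances))
    stop("argument error: m must satisfy 1 <= m <= length(variances)",
         call. = FALSE)
  total <- sum(variances)
  if (total == 0) {
    warning("all eigenvalues are zero; returning ratio 1")
    return(1)
  }
  sum(variances[seq_len(m)]) / total
}

# orient each loading so its largest-magnitude entry is positive; flips the
# matching left singular vectors to keep the product unchanged
.signFix <- function(u, v) {
  for (i in seq_len(ncol(v))) {
    peak <- which.max(abs(v[, i]))
    if (v[peak, i] < 0) {
      v[, i] <- -v[, i]
      u[, i] <- -u[, i]
    }
  }
  list(u = u, v = v)
}

#' Rank-m principal-component reconstruction of a detail matrix
#'
#' Replaces a detail coefficient matrix by its mean term plus the rank-m
#' truncated singular value decomposition of the centered matrix. With
#' \code{center = "sample"} each sample's own mean coefficient is removed and
#' the principal components are computed over coefficient positions (the
#' transform's native reconstruction rule, well-conditioned when levels are
#' wider than the sample count); with \code{center = "coefficient"} the
#' per-coefficient mean across samples is removed, i.e. classic PCA of the
#' samples.
#'
#' @param detail numeric matrix, samples x coefficients.
#' @param m number of principal components to keep,
#'   m <= min(n_samples, n_coefficients).
#' @param center \code{"sample"} (default) or \code{"coefficient"}.
#' @return A list: \code{reduced} (same shape as \code{detail}),
#'   \code{loadings} (orthonormal coefficient-space directions, n_j x m),
#'   \code{mean} (per-coefficient mean across samples, kept for diagnostics),
#'   \code{variances} (full non-increasing eigenvalue spectrum of the
#'   level covariance), \code{rhoM} (variance fraction explained by the m
#'   kept components).
#' @export
rankReduceDetail <- function(detail, m, center = c("sample", "coefficient")) {
  center <- match.arg(center)
  detail <- as.matrix(detail)
  maxRank <- min(dim(detail))
  if (length(m) != 1 || is.na(m) || m < 1 || m > maxRank)
    stop("argument error: m must satisfy 1 <= m <= min(dim(detail)) = ",
         maxRank, call. = FALSE)
  if (center == "sample") {
    mu <- rowMeans(detail)
    centered <- detail - mu
    nObs <- ncol(detail)
  } else {
    mu <- colMeans(detail)
    centered <- sweep(detail, 2, mu)
    nObs <- nrow(detail)
  }
  sv <- svd(centered)
  fix <- .signFix(sv$u, sv$v)
  variances <- sv$d^2 / max(nObs - 1, 1)
  keep <- seq_len(m)
  reduced <- fix$u[, keep, drop = FALSE] %*%
    (sv$d[keep] * t(fix$v[, keep, drop = FALSE]))
  reduced <- if (center == "sample") reduced + mu
             else sweep(reduced, 2, mu, `+`)
  rhoM <- if (sum(variances) == 0) {
    warning("level has zero variance; explained ratio set to 1")
    1
  } else sum(variances[keep]) / sum(variances)
  list(reduced = reduced, loadings = fix$v[, keep, drop = FALSE],
       mean = colMeans(detail), variances = variances, rhoM = rhoM)
}

.chooseM <- function(variances, rho, maxRank) {
  total <- sum(variances)
  if (total == 0) return(1L)
  cum <- cumsum(variances) / total
  min(which(cum >= rho - 1e-12), maxRank)
}

#' Fit the derivative-component transform and denoise a panel
#'
#' Decomposes every sample spectrum with a J-level DWT, replaces each fine
#' detail matrix (levels 1..tau) by its rank-m principal-component
#' reconstruction while levels above tau and the approximation pass through
#' untouched, and inverts the transform. The result ("meta-data") has exactly
#' the shape of the input.
#'
#' @param spectra a \linkS4class{SpectraMatrix} or numeric matrix.
#' @param config a \linkS4class{DCAConfig}.
#' @param verbose log per-level shapes and explained ratios via
#'   \code{message()}.
#' @return A \linkS4class{DCAModel}; the denoised panel is available through
#'   [metaData()].
#' @examples
#' x <- SpectraMatrix(matrix(rnorm(10 * 1024), 10))
#' model <- dca(x, dcaConfig(wavelet = waveletConfig("db8", 7)))
#' dim(metaData(model))
#' explainedRatios(model)
#' @export
dca <- function(spectra, config = dcaConfig(), verbose = FALSE) {
  if (!is(spectra, "SpectraMatrix"))
    spectra <- SpectraMatrix(spectra)
  decomp <- decomposeSpectra(spectra, config@wavelet)
  tau <- config@tau
  nFine <- min(tau, config@wavelet@level)
  loadings <- vector("list", nFine)
  means <- vector("list", nFine)
  explained <- vector("list", nFine)
  mUsed <- integer(nFine)
  rhoM <- numeric(nFine)
  for (j in seq_len(nFine)) {
    D <- decomp@details[[j]]
    maxRank <- min(dim(D))
    m <- if (!is.na(config@rho)) {
      centered <- if (config@center == "sample") D - rowMeans(D)
                  else sweep(D, 2, colMeans(D))
      .chooseM(svd(centered, nu = 0, nv = 0)$d^2, config@rho, maxRank)
    } else min(config@m, maxRank)
    red <- rankReduceDetail(D, m, center = config@center)
    decomp@details[[j]] <- red$reduced
    loadings[[j]] <- red$loadings
    means[[j]] <- red$mean
    explained[[j]] <- red$variances
    mUsed[j] <- m
    rhoM[j] <- red$rhoM
    if (verbose)
      message(sprintf("level %d: %d x %d, m = %d, rho_m = %.3f",
                      j, nrow(D), ncol(D), m, rhoM[j]))
  }
  metaX <- reconstructSpectra(decomp)
  meta <- SpectraMatrix(metaX, mz = spectra@mz, sampleIds = spectra@sampleIds,
                        labels = spectra@labels)
  new("DCAModel", config = config, loadings = loadings, means = means,
      explained = explained, mUsed = mUsed, rhoM = rhoM, meta = meta,
      nChannels = ncol(metaX))
}

#' Apply a fitted derivative-component transform to new spectra
#'
#' Decomposes new spectra with the stored wavelet settings and projects each
#' fine-level detail row onto the loadings learned at fit time (after the
#' centering the model was fitted with), then inverts the transform. Applying
#' a model to its own training panel reproduces the fitted meta-data.
#'
#' @param model a \linkS4class{DCAModel}.
#' @param spectra a \linkS4class{SpectraMatrix} or numeric matrix with the
#'   same channel count as at fit time.
#' @return A \linkS4class{SpectraMatrix} of denoised spectra.
#' @export
applyModel <- function(model, spectra) {
  asMatrix <- !is(spectra, "SpectraMatrix")
  if (asMatrix) spectra <- SpectraMatrix(as.matrix(spectra))
  if (ncol(spectra@intensities) != model@nChannels)
    stop("shape error: model was fitted on ", model@nChannels,
         " channels, got ", ncol(spectra@intensities), call. = FALSE)
  cfg <- model@config
  decomp <- decomposeSpectra(spectra, cfg@wavelet)
  for (j in seq_along(model@loadings)) {
    D <- decomp@details[[j]]
    V <- model@loadings[[j]]
    if (cfg@center == "sample") {
      mu <- rowMeans(D)
      centered <- D - mu
      decomp@details[[j]] <- (centered %*% V) %*% t(V) + mu
    } else {
      mu <- model@means[[j]]
      centered <- sweep(D, 2, mu)
      decomp@details[[j]] <- sweep((centered %*% V) %*% t(V), 2, mu, `+`)
    }
  }
  metaX <- reconstructSpectra(decomp)
  SpectraMatrix(metaX, mz = spectra@mz, sampleIds = spectra@sampleIds,
                labels = spectra@labels)
}
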