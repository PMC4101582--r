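# Channel-axis DWT machinery. All routines operate on a whole panel at once
# (samples in rows), one independent transform per row.

# symmetric (half-point, edge-repeating) extension indices, 1-based
.symIndex <- function(n, L) {
  i <- (-(L - 1)):(n + L - 2)         # 0-based positions to fetch
  p <- 2L * n
  j <- i %% p
  ifelse(j < n, j, p - 1L - j) + 1L
}

# one analysis level, periodized: odd lengths are padded by repeating the
# last channel, which keeps the step exactly invertible
.dwtPeriodized <- function(X, lo, hi) {
  n <- ncol(X)
  if (n %% 2L == 1L) X <- cbind(X, X[, n, drop = FALSE])
  n2 <- ncol(X)
  half <- n2 %/% 2L
  L <- length(lo)
  cA <- matrix(0, nrow(X), half)
  cD <- matrix(0, nrow(X), half)
  k0 <- 2L * (0:(half - 1L))
  for (m in seq_len(L)) {
    cols <- ((k0 + (m - 1L)) %% n2) + 1L
    block <- X[, cols, drop = FALSE]
    cA <- cA + lo[m] * block
    cD <- cD + hi[m] * block
  }
  list(cA = cA, cD = cD)
}

.idwtPeriodized <- function(cA, cD, lo, hi, nOrig) {
  half <- ncol(cA)
  n2 <- 2L * half
  L <- length(lo)
  out <- matrix(0, nrow(cA), n2)
  k0 <- 2L * (0:(half - 1L))
  for (m in seq_len(L)) {
    cols <- ((k0 + (m - 1L)) %% n2) + 1L
    out[, cols] <- out[, cols] + lo[m] * cA + hi[m] * cD
  }
  out[, seq_len(nOrig), drop = FALSE]
}

.dwtSymmetric <- function(X, lo, hi) {
  n <- ncol(X)
  L <- length(lo)
  ext <- X[, .symIndex(n, L), drop = FALSE]
  nOut <- (n + L - 1L) %/% 2L
  cA <- matrix(0, nrow(X), nOut)
  cD <- matrix(0, nrow(X), nOut)
  k0 <- 2L * (0:(nOut - 1L))
  for (m in seq_len(L)) {
    block <- ext[, k0 + m + 1L, drop = FALSE]
    cA <- cA + lo[m] * block
    cD <- cD + hi[m] * block
  }
  list(cA = cA, cD = cD)
}

.idwtSymmetric <- function(cA, cD, lo, hi, nOrig) {
  nC <- ncol(cA)
  L <- length(lo)
  rec <- matrix(0, nrow(cA), 2L * nC + L - 1L)
  k0 <- 2L * (0:(nC - 1L))
  for (m in seq_len(L)) {
    cols <- k0 + m
    rec[, cols] <- rec[, cols] + lo[m] * cA + hi[m] * cD
  }
  rec[, (L - 1L):(L - 2L + nOrig), drop = FALSE]
}

.asIntensityMatrix <- function(spectra) {
  if (is(spectra, "SpectraMatrix")) spectra@intensities
  else as.matrix(spectra)
}

#' Multilevel wavelet decomposition of a spectra panel
#'
#' Applies a J-level discrete wavelet transform along the m/z axis, one
#' independent transform per sample spectrum, producing detail coefficient
#' matrices cD1..cDJ (fine to coarse) and the level-J approximation cAJ.
#' Under periodization each level's coefficient count is ceiling(n/2) of the
#' previous level (exactly n/2^j for dyadic panels) and the transform is
#' orthonormal; under the symmetric boundary a few extra boundary
#' coefficients appear per level.
#'
#' @param spectra a \linkS4class{SpectraMatrix} or numeric matrix (samples in
#'   rows).
#' @param config a \linkS4class{WaveletConfig}.
#' @param padToDyadic right-pad the panel with its edge value up to the next
#'   power of two before transforming (the padding is cut away again on
#'   reconstruction).
#' @return A \linkS4class{WaveletDecomposition}.
#' @examples
#' X <- matrix(rnorm(10 * 1024), 10)
#' d <- decomposeSpectra(X, waveletConfig("db8", 5))
#' ncol(detailMatrices(d)[[1]])   # 512
#' @seealso [reconstructSpectra()]
#' @export
decomposeSpectra <- function(spectra, config = waveletConfig(),
                             padToDyadic = FALSE) {
  X <- .asIntensityMatrix(spectra)
  nOrig <- ncol(X)
  J <- config@level
  if (padToDyadic && log2(nOrig) %% 1 != 0) {
    target <- 2L^ceiling(log2(nOrig))
    X <- cbind(X, matrix(X[, nOrig], nrow(X), target - nOrig))
  }
  if (config@boundary == "periodization" && 2L^J > ncol(X))
    stop("config error: level ", J, " too deep for ", ncol(X),
         " channels (need n_channels >= 2^J under periodization)",
         call. = FALSE)
  if (J > floor(log2(ncol(X))))
    stop("config error: level ", J, " exceeds floor(log2(n_channels))",
         call. = FALSE)
  f <- waveletFilters(config@wavelet)
  details <- vector("list", J)
  inputLengths <- integer(J)
  cur <- X
  for (j in seq_len(J)) {
    inputLengths[j] <- ncol(cur)
    step <- if (config@boundary == "periodization")
      .dwtPeriodized(cur, f$lo, f$hi) else .dwtSymmetric(cur, f$lo, f$hi)
    details[[j]] <- step$cD
    cur <- step$cA
  }
  new("WaveletDecomposition", details = details, approx = cur,
      config = config, nChannels = nOrig, inputLengths = inputLengths)
}

#' Inverse multilevel wavelet transform
#'
#' Reassembles a panel from its detail and approximation coefficient
#' matrices. The operation is linear in the coefficients and, for
#' coefficients produced by [decomposeSpectra()], reconstructs the original
#' panel to floating-point accuracy.
#'
#' @param decomp a \linkS4class{WaveletDecomposition} (its coefficient
#'   matrices may have been modified, as long as shapes are unchanged).
#' @return A numeric matrix with the original sample and channel counts.
#' @export
reconstructSpectra <- function(decomp) {
  stopifnot(is(decomp, "WaveletDecomposition"))
  cfg <- decomp@config
  f <- waveletFilters(cfg@wavelet)
  J <- cfg@level
  cur <- decomp@approx
  for (j in rev(seq_len(J))) {
    cD <- decomp@details[[j]]
    if (!is.matrix(cD) || nrow(cD) != nrow(cur) || ncol(cD) != ncol(cur))
      stop("shape error: level ", j, " detail matrix is ",
           paste(dim(cD), collapse = "x"), ", expected ",
           paste(dim(cur), collapse = "x"), call. = FALSE)
    cur <- if (cfg@boundary == "periodization")
      .idwtPeriodized(cur, cD, f$lo, f$hi, decomp@inputLengths[j])
    else .idwtSymmetric(cur, cD, f$lo, f$hi, decomp@inputLengths[j])
  }
  cur[, seq_len(decomp@nChannels), drop = FALSE]
}
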