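# Seeded generator of synthetic serum-like spectra: Gaussian peaks on an
# exponentially decaying baseline, an optional class-dependent high-frequency
# ripple ("subtle" structure), per-sample lognormal scale jitter and additive
# white Gaussian noise.

#' Fixed high-frequency ripple template
#'
#' A deterministic, zero-mean, unit-RMS band-limited waveform used as the
#' "subtle" class signature: the standardized sum of 16 cosines whose
#' wavelengths span 2.5 to 7 channels, so its energy is concentrated in the
#' two finest dyadic wavelet bands (cD1/cD2) - precisely the levels the
#' derivative-component transform reconstructs at cutoff tau = 2. The
#' closed form before standardization is
#' sum_j cos(2 pi f_j i / n + j^2), f_j equally spaced in [n/7, n/2.5],
#' j = 1..16.
#'
#' @param nChannels number of channels.
#' @return Numeric vector of length \code{nChannels} with mean 0 and RMS 1.
#' @export
rippleTemplate <- function(nChannels) {
  i <- seq_len(nChannels) - 1
  freqs <- seq(nChannels / 7, nChannels / 2.5, length.out = 16)
  r <- rowSums(vapply(seq_along(freqs), function(j)
    cos(2 * pi * freqs[j] * i / nChannels + j^2), numeric(nChannels)))
  r <- r - mean(r)
  r / sqrt(mean(r^2))
}

#' Parameters of the synthetic spectrum generator
#'
#' @param nPerClass integer vector of per-class sample counts (k classes).
#' @param nChannels number of m/z channels (default 1024).
#' @param mzRange numeric c(low, high) m/z window in Daltons.
#' @param peaks data.frame with columns location (Da), width (Da), height:
#'   the shared Gaussian peak set.
#' @param globalEffects k x nrow(peaks) matrix of per-class multiplicative
#'   peak-height factors.
#' @param subtleAmplitude length-k vector: per-class amplitude of the fixed
#'   ripple template.
#' @param subtleJitterSd per-sample Gaussian jitter of the ripple amplitude
#'   around its class value (default 0).
#' @param baseline numeric c(intercept, decay): the baseline is
#'   intercept * exp(-(mz - low) / decay).
#' @param noiseSd additive Gaussian noise standard deviation.
#' @param sampleScaleSd sdlog of the per-sample lognormal amplitude factor
#'   (0 = no scale jitter).
#' @param classNames optional character class codes (default "C1", "C2", ...).
#' @param seed integer seed driving all randomness of [simulateSpectra()].
#' @return A validated list of class \code{SimulationParams}.
#' @export
simulationParams <- function(nPerClass, nChannels = 1024,
                             mzRange = c(500, 10000), peaks,
                             globalEffects = NULL, subtleAmplitude = NULL,
                             subtleJitterSd = 0,
                             baseline = c(2, 3000), noiseSd = 0.3,
                             sampleScaleSd = 0, classNames = NULL,
                             seed = 1) {
  k <- length(nPerClass)
  if (k < 1 || any(nPerClass < 1))
    stop("argument error: nPerClass must be positive", call. = FALSE)
  if (nChannels < 2)
    stop("argument error: nChannels must be >= 2", call. = FALSE)
  peaks <- as.data.frame(peaks)
  stopifnot(all(c("location", "width", "height") %in% names(peaks)))
  if (any(peaks$width < 0) || noiseSd < 0 || sampleScaleSd < 0 ||
      subtleJitterSd < 0)
    stop("argument error: widths and sds must be >= 0", call. = FALSE)
  if (any(peaks$location < mzRange[1] | peaks$location > mzRange[2]))
    stop("argument error: peak locations must lie within mzRange",
         call. = FALSE)
  if (is.null(globalEffects))
    globalEffects <- matrix(1, k, nrow(peaks))
  globalEffects <- as.matrix(globalEffects)
  if (!all(dim(globalEffects) == c(k, nrow(peaks))))
    stop("argument error: globalEffects must be k x n_peaks", call. = FALSE)
  if (is.null(subtleAmplitude)) subtleAmplitude <- rep(0, k)
  if (length(subtleAmplitude) != k)
    stop("argument error: subtleAmplitude must have one entry per class",
         call. = FALSE)
  if (is.null(classNames)) classNames <- paste0("C", seq_len(k))
  structure(list(nPerClass = as.integer(nPerClass),
                 nChannels = as.integer(nChannels), mzRange = mzRange,
                 peaks = peaks, globalEffects = globalEffects,
                 subtleAmplitude = subtleAmplitude,
                 subtleJitterSd = subtleJitterSd, baseline = baseline,
                 noiseSd = noiseSd, sampleScaleSd = sampleScaleSd,
                 classNames = as.character(classNames),
                 seed = as.integer(seed)),
            class = "SimulationParams")
}

#' Named generator presets
#'
#' Fully documented parameter sets used throughout the test suite:
#' \describe{
#'   \item{binary_global}{two classes of 50 whose peak heights differ on
#'     three of six peaks by a factor 1 + 0.3 * scale; no subtle component;
#'     noise sd 0.3. The differential peaks separate the classes by many
#'     noise standard deviations at their apex channels.}
#'   \item{binary_subtle}{two classes of 50 with identical peaks and
#'     baseline; both carry the ripple (base amplitude 1), class 2 at
#'     1 + 0.125 * scale; noise sd 1. The per-channel class difference is
#'     an order of magnitude below the noise, so the signature is only
#'     recoverable by aggregating the fine wavelet bands.}
#'   \item{three_class}{three classes of 30; class 2's differential peak
#'     heights sit halfway between class 1 and class 3 (factors 1,
#'     1 + 0.2 * scale, 1 + 0.4 * scale), mimicking an intermediate
#'     pathological stage; noise sd 0.3.}
#' }
#'
#' @param name preset name.
#' @param scale effect-size multiplier (default 1): scales the differential
#'   peak-height gaps (global presets) or the subtle amplitude gap.
#' @param seed seed stored in the returned parameters.
#' @return A \code{SimulationParams} list.
#' @export
simulationPreset <- function(name = c("binary_global", "binary_subtle",
                                      "three_class"),
                             scale = 1, seed = 1) {
  name <- match.arg(name)
  peaks <- data.frame(
    location = c(1500, 2500, 3500, 5000, 7000, 9000),
    width = c(120, 150, 200, 160, 250, 180),
    height = c(8, 12, 18, 10, 14, 6))
  diffPeaks <- c(2, 4, 6)
  if (name == "binary_global") {
    ge <- matrix(1, 2, 6)
    ge[2, diffPeaks] <- 1 + 0.3 * scale
    simulationParams(c(50, 50), peaks = peaks, globalEffects = ge,
                     subtleAmplitude = c(0, 0), noiseSd = 0.3,
                     classNames = c("control", "case"), seed = seed)
  } else if (name == "binary_subtle") {
    simulationParams(c(50, 50), peaks = peaks,
                     globalEffects = matrix(1, 2, 6),
                     subtleAmplitude = c(1, 1 + 0.125 * scale),
                     noiseSd = 1, classNames = c("control", "case"),
                     seed = seed)
  } else {
    ge <- matrix(1, 3, 6)
    ge[2, diffPeaks] <- 1 + 0.2 * scale
    ge[3, diffPeaks] <- 1 + 0.4 * scale
    simulationParams(c(30, 30, 30), peaks = peaks, globalEffects = ge,
                     subtleAmplitude = c(0, 0, 0), noiseSd = 0.3,
                     classNames = c("normal", "intermediate", "disease"),
                     seed = seed)
  }
}

#' Generate a synthetic spectra panel
#'
#' The intensity of sample s (class g) at channel x is
#' \deqn{scale_s [baseline(x) + \sum_p h_{g,p} G(x; loc_p, width_p)
#'       + a_s ripple(x)] + \epsilon,}
#' where G is a Gaussian bump, \eqn{a_s} is the class's subtle amplitude
#' plus optional per-sample jitter, \eqn{scale_s} is lognormal and
#' \eqn{\epsilon ~ N(0, noiseSd^2)}. The noise-free part (everything but
#' \eqn{\epsilon}) is returned alongside as ground truth. Fully
#' deterministic given the seed stored in the parameters.
#'
#' @param params a \code{SimulationParams} list from [simulationParams()] or
#'   [simulationPreset()].
#' @return A list: \code{spectra} (a labelled \linkS4class{SpectraMatrix})
#'   and \code{truth} (numeric matrix of noise-free spectra).
#' @examples
#' sim <- simulateSpectra(simulationPreset("binary_global", seed = 7))
#' dim(sim$spectra)
#' @export
simulateSpectra <- function(params) {
  if (!inherits(params, "SimulationParams"))
    stop("argument error: params must come from simulationParams()",
         call. = FALSE)
  k <- length(params$nPerClass)
  n <- sum(params$nPerClass)
  nc <- params$nChannels
  mz <- seq(params$mzRange[1], params$mzRange[2], length.out = nc)
  classIdx <- rep(seq_len(k), params$nPerClass)
  base <- params$baseline[1] * exp(-(mz - params$mzRange[1]) /
                                     params$baseline[2])
  peakProfiles <- vapply(seq_len(nrow(params$peaks)), function(p) {
    with(params$peaks[p, ],
         height * exp(-0.5 * ((mz - location) / width)^2))
  }, numeric(nc))
  ripple <- rippleTemplate(nc)
  classSignal <- vapply(seq_len(k), function(g)
    base + as.vector(peakProfiles %*% params$globalEffects[g, ]),
    numeric(nc))

  .withSeed(params$seed, {
    scales <- if (params$sampleScaleSd > 0)
      stats::rlnorm(n, 0, params$sampleScaleSd) else rep(1, n)
    amps <- params$subtleAmplitude[classIdx] +
      if (params$subtleJitterSd > 0)
        stats::rnorm(n, 0, params$subtleJitterSd) else 0
    noise <- if (params$noiseSd > 0)
      matrix(stats::rnorm(n * nc, 0, params$noiseSd), n, nc) else
      matrix(0, n, nc)
    truth <- scales * (t(classSignal)[classIdx, , drop = FALSE] +
                         outer(amps, ripple))
    x <- truth + noise
    labels <- params$classNames[classIdx]
    ids <- sprintf("%s_%03d", labels, stats::ave(seq_len(n), classIdx,
                                                 FUN = seq_along))
    spectra <- SpectraMatrix(x, mz = mz, sampleIds = ids,
                             labels = if (k >= 2) labels else character(0))
    list(spectra = spectra, truth = truth)
  })
}
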