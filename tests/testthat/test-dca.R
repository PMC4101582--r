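test_that("variability ratio follows the eigenvalue arithmetic", {
  expect_equal(variabilityRatio(c(3, 1), 1), 0.75)
  expect_equal(variabilityRatio(c(2, 1, 0.5), 3), 1.0)
  expect_equal(variabilityRatio(rep(1, 4), 1), 0.25)
  expect_warning(r <- variabilityRatio(c(0, 0), 1), "zero")
  expect_equal(r, 1)
  expect_error(variabilityRatio(c(3, 1), 0), "argument error")
  expect_error(variabilityRatio(c(3, 1), 3), "argument error")
})

test_that("rank reduction matches the Eckart-Young truncation oracle", {
  set.seed(31)
  for (center in c("sample", "coefficient")) {
    for (rep in 1:5) {
      D <- matrix(rnorm(20 * 64), 20, 64)
      for (m in 1:3) {
        out <- rankReduceDetail(D, m, center = center)
        # independent oracle: direct truncated SVD of the centered matrix
        mu <- if (center == "sample") rowMeans(D) else
          rep(1, 20) %o% colMeans(D)
        C <- D - mu
        sv <- svd(C)
        trunc <- sv$u[, 1:m, drop = FALSE] %*%
          diag(sv$d[1:m], m) %*% t(sv$v[, 1:m, drop = FALSE])
        expect_lt(max(abs(out$reduced - (mu + trunc))), 1e-10)
        expect_equal(crossprod(out$loadings), diag(m), tolerance = 1e-8)
        expect_true(all(diff(out$variances) <= 1e-10))
      }
    }
  }
})

test_that("full-rank reduction is exact and low-rank input is recovered", {
  set.seed(32)
  D <- matrix(rnorm(8 * 12), 8, 12)
  for (center in c("sample", "coefficient")) {
    out <- rankReduceDetail(D, 8, center = center)
    expect_lt(max(abs(out$reduced - D)), 1e-8)
  }
  # exactly rank-1 zero-mean input, m = 1
  u <- rnorm(8); v <- rnorm(12)
  R1 <- (u - mean(u)) %o% v
  out <- rankReduceDetail(R1, 1, center = "coefficient")
  expect_lt(max(abs(out$reduced - R1)), 1e-8)
  expect_error(rankReduceDetail(D, 9), "argument error")
})

test_that("the identity limit holds: full m or tau = 0 reproduce the input", {
  set.seed(33)
  X <- matrix(rnorm(10 * 512), 10)
  sm <- SpectraMatrix(X)
  cfgFull <- dcaConfig(wavelet = waveletConfig("db8", 5), tau = 2, m = 999)
  expect_lt(norm(intensities(metaData(dca(sm, cfgFull))) - X, "F") /
              norm(X, "F"), 1e-8)
  cfg0 <- suppressWarnings(dcaConfig(wavelet = waveletConfig("db8", 5),
                                     tau = 0))
  expect_lt(norm(intensities(metaData(dca(sm, cfg0))) - X, "F") /
              norm(X, "F"), 1e-8)
})

test_that("default configuration returns same-shape meta-data and ratios", {
  set.seed(34)
  sm <- SpectraMatrix(matrix(rnorm(10 * 1024), 10))
  model <- dca(sm)   # db8, J = 7, tau = 2, m = 1
  expect_identical(dim(metaData(model)), c(10L, 1024L))
  expect_length(explainedRatios(model), 2L)
  expect_true(all(explainedRatios(model) > 0 &
                    explainedRatios(model) <= 1))
  expect_identical(model@mUsed, c(1L, 1L))
  expect_true(all(is.finite(intensities(metaData(model)))))
})

test_that("coarse levels pass through while fine levels change", {
  set.seed(35)
  sm <- SpectraMatrix(matrix(rnorm(12 * 512), 12))
  cfg <- dcaConfig(wavelet = waveletConfig("db8", 5), tau = 2, m = 1)
  model <- dca(sm, cfg)
  dIn <- decomposeSpectra(sm, cfg@wavelet)
  dOut <- decomposeSpectra(metaData(model), cfg@wavelet)
  for (j in 3:5)
    expect_lt(norm(detailMatrices(dOut)[[j]] - detailMatrices(dIn)[[j]],
                   "F") / norm(detailMatrices(dIn)[[j]], "F"), 1e-10)
  expect_lt(norm(approxMatrix(dOut) - approxMatrix(dIn), "F") /
              norm(approxMatrix(dIn), "F"), 1e-10)
  for (j in 1:2)
    expect_gt(norm(detailMatrices(dOut)[[j]] - detailMatrices(dIn)[[j]],
                   "F") / norm(detailMatrices(dIn)[[j]], "F"), 1e-3)
})

test_that("fidelity to the input improves monotonically with m", {
  set.seed(36)
  X <- matrix(rnorm(15 * 256), 15)
  sm <- SpectraMatrix(X)
  errs <- vapply(1:6, function(m) {
    cfg <- dcaConfig(wavelet = waveletConfig("db4", 4), tau = 2, m = m)
    norm(intensities(metaData(dca(sm, cfg))) - X, "F")
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("the rho rule picks the smallest sufficient m per level", {
  set.seed(37)
  sm <- SpectraMatrix(matrix(rnorm(10 * 256), 10))
  cfg <- dcaConfig(wavelet = waveletConfig("db4", 4), tau = 2, rho = 0.6)
  model <- dca(sm, cfg)
  for (j in 1:2) {
    m <- model@mUsed[j]
    v <- model@explained[[j]]
    expect_gte(variabilityRatio(v, m), 0.6 - 1e-10)
    if (m > 1) expect_lt(variabilityRatio(v, m - 1), 0.6)
  }
})

test_that("applying a model to its own training data reproduces the fit", {
  set.seed(38)
  for (center in c("sample", "coefficient")) {
    sm <- SpectraMatrix(matrix(rnorm(8 * 256), 8))
    cfg <- dcaConfig(wavelet = waveletConfig("db4", 4), tau = 2, m = 2,
                     center = center)
    model <- dca(sm, cfg)
    reapplied <- applyModel(model, sm)
    expect_lt(norm(intensities(reapplied) - intensities(metaData(model)),
                   "F") / norm(intensities(metaData(model)), "F"), 1e-8)
  }
})

test_that("model application projects new coefficients onto the loadings", {
  set.seed(39)
  sm <- SpectraMatrix(matrix(rnorm(10 * 256), 10))
  cfg <- suppressWarnings(
    dcaConfig(wavelet = waveletConfig("db4", 4), tau = 1, m = 2,
              center = "coefficient"))
  model <- dca(sm, cfg)
  ynew <- matrix(rnorm(256), 1)
  applied <- applyModel(model, ynew)
  # brute-force oracle on the level-1 coefficients
  dNew <- decomposeSpectra(ynew, cfg@wavelet)
  c1 <- drop(detailMatrices(dNew)[[1]])
  V <- model@loadings[[1]]
  mu <- model@means[[1]]
  projected <- mu + drop(V %*% crossprod(V, c1 - mu))
  dApp <- decomposeSpectra(applied, cfg@wavelet)
  expect_lt(max(abs(drop(detailMatrices(dApp)[[1]]) - projected)), 1e-10)
  # a sample sitting exactly at the stored mean is unchanged at fine levels
  atMean <- reconstructSpectra(local({
    d <- decomposeSpectra(matrix(0, 1, 256), cfg@wavelet)
    d@details[[1]][1, ] <- mu
    d
  }))
  dAt <- decomposeSpectra(applyModel(model, atMean), cfg@wavelet)
  expect_lt(max(abs(drop(detailMatrices(dAt)[[1]]) - mu)), 1e-8)

  expect_error(applyModel(model, matrix(0, 1, 128)), "shape error")
})

test_that("denoising moves a noisy panel closer to its ground truth", {
  params <- simulationPreset("binary_subtle", seed = 5)
  sim <- simulateSpectra(params)
  model <- dca(sim$spectra)
  distMeta <- norm(intensities(metaData(model)) - sim$truth, "F")
  distRaw <- norm(intensities(sim$spectra) - sim$truth, "F")
  expect_lt(distMeta, distRaw)
})
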