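test_that("t statistics agree with the stats::t.test oracle", {
  set.seed(51)
  lab <- rep(c("a", "b"), c(5, 7))
  for (rep in 1:20) {
    x <- rnorm(12, sd = runif(1, 0.5, 3))
    for (pooled in c(TRUE, FALSE)) {
      mine <- tStatistic(x, lab, pooled = pooled)
      ref <- stats::t.test(x[lab == "a"], x[lab == "b"],
                           var.equal = pooled)
      expect_equal(unname(mine["statistic"]), abs(unname(ref$statistic)),
                   tolerance = 1e-10)
      expect_equal(unname(mine["p"]), ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("the printed worked examples evaluate as expected", {
  r <- tStatistic(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3),
                  pooled = TRUE)
  expect_equal(unname(r["statistic"]), 3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(unname(r["statistic"]), 3.6742, tolerance = 1e-4)
  expect_equal(unname(r["p"]), 0.0213, tolerance = 2e-3)

  f <- fStatistic(c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                  rep(c("a", "b", "c"), each = 3))
  expect_equal(unname(f["statistic"]), 3.0, tolerance = 1e-10)
})

test_that("degenerate features behave as documented", {
  lab <- rep(c("a", "b"), each = 3)
  r <- tStatistic(rep(2, 6), lab)
  expect_identical(unname(r), c(0, 1))
  f <- fStatistic(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_identical(unname(f), c(0, 1))
  expect_error(tStatistic(1:4, c("a", "a", "a", "b")), "argument error")
  expect_error(fStatistic(1:5, c("a", "a", "b", "b", "c")),
               "argument error")
  # equal group variances: pooled and Welch coincide
  x <- c(1, 2, 3, 7, 8, 9)
  expect_equal(tStatistic(x, lab, pooled = TRUE)[["statistic"]],
               tStatistic(x, lab, pooled = FALSE)[["statistic"]],
               tolerance = 1e-10)
})

test_that("F equals t squared for two pooled-variance classes", {
  set.seed(52)
  lab <- rep(c("a", "b"), c(6, 9))
  for (rep in 1:100) {
    x <- rnorm(15)
    t2 <- tStatistic(x, lab, pooled = TRUE)[["statistic"]]^2
    f <- fStatistic(x, lab)[["statistic"]]
    expect_equal(f, t2, tolerance = 1e-10)
  }
})

test_that("F statistics agree with the stats::oneway.test oracle", {
  set.seed(53)
  lab <- rep(c("a", "b", "c"), c(4, 6, 5))
  for (rep in 1:20) {
    x <- rnorm(15)
    mine <- fStatistic(x, lab)
    ref <- stats::oneway.test(x ~ factor(lab), var.equal = TRUE)
    expect_equal(unname(mine["statistic"]), unname(ref$statistic),
                 tolerance = 1e-10)
    expect_equal(unname(mine["p"]), ref$p.value, tolerance = 1e-10)
  }
})

test_that("t and F are invariant to affine rescaling of a feature", {
  set.seed(54)
  lab <- rep(c("a", "b"), c(5, 5))
  x <- rnorm(10)
  for (a in c(-2, 0.5, 10)) {
    expect_equal(tStatistic(a * x + 3, lab)[["statistic"]],
                 tStatistic(x, lab)[["statistic"]], tolerance = 1e-10)
    expect_equal(fStatistic(a * x + 3, lab)[["statistic"]],
                 fStatistic(x, lab)[["statistic"]], tolerance = 1e-10)
  }
})

test_that("biomarker ranking orders channels by discriminative power", {
  sm <- toyPanel(seed = 55)
  tab <- rankBiomarkers(sm, topK = 3)
  expect_identical(nrow(tab), 3L)            # default top 3
  expect_identical(tab$channel[1], 4L)       # the constructed signal channel
  expect_identical(tab$mz[1], mzValues(sm)[4])
  expect_identical(tab$kind[1], "t")
  expect_true(all(diff(tab$statistic) <= 0))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))

  full <- rankBiomarkers(sm, full = TRUE)
  expect_identical(nrow(full), 16L)
  expect_identical(full$rank, 1:16)
  # brute-force oracle: per-channel t statistics, ranked
  bf <- vapply(seq_len(16), function(j)
    tStatistic(intensities(sm)[, j], spectraLabels(sm))[["statistic"]],
    numeric(1))
  expect_identical(full$channel, order(-bf, seq_len(16)))

  # permutation equivariance: channel ids move, statistics do not
  perm <- c(9:16, 1:8)
  smP <- SpectraMatrix(intensities(sm)[, perm],
                       labels = spectraLabels(sm))
  fullP <- rankBiomarkers(smP, full = TRUE)
  expect_equal(fullP$statistic, full$statistic, tolerance = 1e-12)
  expect_identical(perm[fullP$channel], full$channel)
})

test_that("multiclass panels are scored with the F statistic", {
  set.seed(56)
  x <- matrix(rnorm(30 * 8), 30, 8)
  lab <- rep(c("a", "b", "c"), each = 10)
  x[lab == "b", 2] <- x[lab == "b", 2] + 4
  x[lab == "c", 2] <- x[lab == "c", 2] + 8
  tab <- rankBiomarkers(SpectraMatrix(x, labels = lab))
  expect_identical(tab$kind[1], "F")
  expect_identical(tab$channel[1], 2L)
})

test_that("the separability check flags disjoint and overlapping panels", {
  set.seed(57)
  # disjoint 1-D projections on the top biomarker
  x <- matrix(rnorm(40 * 6, sd = 0.2), 40, 6)
  lab <- rep(c("a", "b"), each = 20)
  x[lab == "b", 3] <- x[lab == "b", 3] + 10
  chk <- separabilityCheck(SpectraMatrix(x, labels = lab), topK = 3)
  expect_true(chk$separable)
  expect_equal(chk$trainingAccuracy, 1.0)
  expect_identical(nrow(chk$coords), 40L)
  expect_identical(ncol(chk$coords), 5L)

  # identical class distributions: near-chance, not separable
  y <- matrix(rnorm(60 * 6), 60, 6)
  chk2 <- separabilityCheck(SpectraMatrix(y,
                                          labels = rep(c("a", "b"), 30)),
                            topK = 3)
  expect_false(chk2$separable)
  expect_lt(chk2$trainingAccuracy, 0.95)
})
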