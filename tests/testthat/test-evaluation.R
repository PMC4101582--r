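test_that("stratified folds balance classes and are seed-deterministic", {
  lab <- rep(c("a", "b"), each = 5)
  f <- stratifiedFolds(lab, k = 5, seed = 3)
  expect_setequal(f, 1:5)
  for (fold in 1:5) {
    expect_identical(sum(f == fold & lab == "a"), 1L)
    expect_identical(sum(f == fold & lab == "b"), 1L)
  }

  lab2 <- sample(rep(c("x", "y", "z"), c(40, 35, 25)))
  f1 <- stratifiedFolds(lab2, k = 5, seed = 9)
  f2 <- stratifiedFolds(lab2, k = 5, seed = 9)
  f3 <- stratifiedFolds(lab2, k = 5, seed = 10)
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
  expect_setequal(which(f1 %in% 1:5), seq_along(lab2))  # disjoint cover
  for (cl in c("x", "y", "z")) {
    counts <- table(f1[lab2 == cl])
    expect_lte(max(counts) - min(counts), 1)
  }
  expect_error(stratifiedFolds(rep(c("a", "b"), c(3, 50)), k = 5),
               "argument error")
})

test_that("fold drawing leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  invisible(stratifiedFolds(rep(c("a", "b"), 10), k = 2, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("binarization maps the positive set to +1", {
  lab <- rep(c("normal", "HCC", "cirrhosis"), c(72, 78, 51))
  y <- binarizeLabels(lab, c("HCC", "cirrhosis"))
  expect_identical(sum(y == -1), 72L)
  expect_identical(sum(y == 1), 129L)
  expect_error(binarizeLabels(lab, c("normal", "HCC", "cirrhosis")),
               "argument error")
  expect_error(binarizeLabels(lab, character(0)), "argument error")
  yb <- binarizeLabels(c("1", "-1", "1"), "1")
  expect_identical(yb, c(1, -1, 1))
  expect_identical(binarizeLabels(as.character(yb), "1"), yb)
})

test_that("confusion-derived metrics follow their definitions", {
  m <- classificationMetrics(list(TP = 9, FN = 1, TN = 8, FP = 2))
  expect_equal(unname(m["sensitivity"]), 0.9)
  expect_equal(unname(m["specificity"]), 0.8)
  expect_equal(unname(m["ppv"]), 9 / 11)
  expect_equal(unname(m["accuracy"]), 0.85)

  m2 <- classificationMetrics(list(TP = 5, FN = 0, TN = 3, FP = 2))
  expect_equal(unname(m2["sensitivity"]), 1.0)

  expect_warning(m3 <- classificationMetrics(list(TP = 0, FN = 4, TN = 6,
                                                  FP = 0)),
                 "ppv undefined")
  expect_true(is.nan(m3[["ppv"]]))
  expect_error(classificationMetrics(list(TP = -1, FN = 1, TN = 1, FP = 1)),
               "argument error")

  cc <- confusionCounts(c(1, 1, -1, -1, 1), c(1, -1, -1, 1, 1))
  expect_identical(cc, list(TP = 2L, TN = 1L, FP = 1L, FN = 1L))
})

test_that("a perfectly separated panel is classified without error", {
  sim <- simulateSpectra(simulationPreset("binary_global", seed = 11))
  rep <- crossValidate(sim$spectra, methods = c("dca_svm", "svm"),
                       repeats = 2, seed = 4)
  acc <- rep@summary[rep@summary$metric == "accuracy", ]
  expect_equal(acc$mean, c(1, 1))
  expect_equal(acc$sd, c(0, 0))
  # fold test sets partition the panel in every repeat
  for (r in unique(rep@folds$repeat_)) {
    sub <- rep@folds[rep@folds$repeat_ == r & rep@folds$method == "svm", ]
    expect_identical(sum(sub$TP + sub$TN + sub$FP + sub$FN),
                     nrow(intensities(sim$spectra)))
  }
})

test_that("reports are reproducible and fold sizes are consistent", {
  sim <- simulateSpectra(simulationPreset("binary_global", seed = 12))
  r1 <- crossValidate(sim$spectra, methods = "svm", repeats = 2, seed = 7)
  r2 <- crossValidate(sim$spectra, methods = "svm", repeats = 2, seed = 7)
  expect_identical(r1@folds, r2@folds)
  expect_identical(r1@summary, r2@summary)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  writeEvalReport(r1, f1)
  writeEvalReport(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("multiclass evaluation reports top-1 accuracy and binarized rates", {
  sim <- simulateSpectra(simulationPreset("three_class", seed = 13))
  rep <- crossValidate(sim$spectra, methods = "dca_svm", repeats = 1,
                       seed = 2, positive = c("disease", "intermediate"))
  acc <- rep@summary[rep@summary$metric == "accuracy", "mean"]
  expect_gt(acc, 0.8)
  sens <- rep@summary[rep@summary$metric == "sensitivity", "mean"]
  expect_true(is.finite(sens))
  expect_identical(rep@metadata$positive, c("disease", "intermediate"))
})

test_that("inductive mode fits transforms and filters on training data only", {
  sim <- simulateSpectra(simulationPreset("binary_global", seed = 14))
  cfgInd <- dcaConfig(fitMode = "inductive")
  rep <- crossValidate(sim$spectra, methods = c("dca_svm", "fs_svm"),
                       config = cfgInd, repeats = 1, seed = 5)
  acc <- rep@summary[rep@summary$metric == "accuracy", ]
  expect_true(all(acc$mean > 0.9))
  expect_identical(rep@metadata$fitMode, "inductive")
})

test_that("invalid method sets are rejected", {
  sim <- simulateSpectra(simulationPreset("binary_global", seed = 15))
  expect_error(crossValidate(sim$spectra, methods = character(0)),
               "argument error")
  expect_error(crossValidate(sim$spectra, methods = "pls_lld"),
               "argument error")
})
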