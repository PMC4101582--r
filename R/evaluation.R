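# Repeated stratified k-fold cross-validation harness comparing the
# denoise-then-classify pipeline (dca_svm) against a plain linear SVM (svm)
# and a univariate-filter SVM (fs_svm).

# run expr with a private RNG state seeded by `seed`
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Stratified fold assignment
#'
#' Randomly partitions samples into k folds so that per-class counts across
#' folds differ by at most one. Deterministic for a given seed.
#'
#' @param labels class codes.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return Integer vector of fold ids in 1..k, one per sample.
#' @export
stratifiedFolds <- function(labels, k = 5, seed = 1) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < k))
    stop("argument error: every class needs at least k = ", k, " samples",
         call. = FALSE)
  folds <- integer(length(labels))
  .withSeed(seed, {
    for (cl in sort(names(counts))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Collapse multiclass labels to +1/-1
#'
#' Classes in \code{positive} map to +1, all others to -1. The positive set
#' must be a nonempty proper subset of the observed classes.
#'
#' @param labels class codes.
#' @param positive character vector of class codes to treat as positive.
#' @return Numeric vector of +1/-1.
#' @export
binarizeLabels <- function(labels, positive) {
  labels <- as.character(labels)
  classes <- unique(labels)
  positive <- as.character(positive)
  if (length(positive) == 0 || !all(positive %in% classes) ||
      all(classes %in% positive))
    stop("argument error: positive must be a nonempty proper subset of the ",
         "class set", call. = FALSE)
  ifelse(labels %in% positive, 1, -1)
}

#' Confusion counts of binary predictions
#'
#' @param truth +1/-1 truth vector.
#' @param predicted +1/-1 prediction vector.
#' @return Named list TP, TN, FP, FN.
#' @export
confusionCounts <- function(truth, predicted) {
  truth <- as.numeric(truth); predicted <- as.numeric(predicted)
  list(TP = sum(truth == 1 & predicted == 1),
       TN = sum(truth == -1 & predicted == -1),
       FP = sum(truth == -1 & predicted == 1),
       FN = sum(truth == 1 & predicted == -1))
}

#' Diagnostic metrics from confusion counts
#'
#' Accuracy (TP+TN)/total, sensitivity TP/(TP+FN), specificity TN/(TN+FP)
#' and positive prediction ratio TP/(TP+FP). A zero denominator yields NaN
#' with a warning rather than an error.
#'
#' @param counts named list or vector with TP, TN, FP, FN.
#' @return Named numeric vector accuracy, sensitivity, specificity, ppv.
#' @examples
#' classificationMetrics(list(TP = 9, FN = 1, TN = 8, FP = 2))
#' @export
classificationMetrics <- function(counts) {
  cn <- vapply(c("TP", "TN", "FP", "FN"), function(f) counts[[f]],
               numeric(1))
  if (any(cn < 0))
    stop("argument error: counts must be non-negative", call. = FALSE)
  total <- sum(cn)
  if (total == 0)
    stop("argument error: at least one evaluated sample required",
         call. = FALSE)
  ratio <- function(num, den, name) {
    if (den == 0) {
      warning(name, " undefined (zero denominator)")
      return(NaN)
    }
    num / den
  }
  c(accuracy = (cn[["TP"]] + cn[["TN"]]) / total,
    sensitivity = ratio(cn[["TP"]], cn[["TP"]] + cn[["FN"]], "sensitivity"),
    specificity = ratio(cn[["TN"]], cn[["TN"]] + cn[["FP"]], "specificity"),
    ppv = ratio(cn[["TP"]], cn[["TP"]] + cn[["FP"]], "ppv"))
}

# p < alpha univariate filter; falls back to the single best channel when
# nothing passes
.filterChannels <- function(X, labels, alpha = 0.05) {
  k <- length(unique(labels))
  res <- if (k == 2) .tStats(X, labels) else .fStats(X, labels)
  keep <- which(res$p < alpha)
  if (length(keep) == 0) keep <- which.min(res$p)
  keep
}

.trainPredict <- function(Xtr, ytr, Xte, C, tolerance = 1e-4) {
  model <- trainMulticlassSvm(Xtr, ytr, C = C, tolerance = tolerance)
  predictLabels(model, Xte)
}

#' Repeated stratified cross-validation of the classification pipelines
#'
#' For each repeat a fresh stratified fold assignment is drawn (repeat r uses
#' seed + r - 1); within each fold the selected pipelines are fitted on the
#' training folds and evaluated on the held-out fold:
#' \describe{
#'   \item{dca_svm}{linear SVM on the derivative-component denoised panel;}
#'   \item{svm}{linear SVM on the raw intensities;}
#'   \item{fs_svm}{linear SVM on the channels passing a univariate filter
#'     (two-sample t-test for binary panels, one-way ANOVA otherwise) at
#'     p < alpha.}
#' }
#' In the default transductive mode the denoising transform and the filter
#' are fitted once on the full panel before cross-validation; in inductive
#' mode they are refitted on each training split and applied to the held-out
#' fold, so no information leaks from test samples.
#'
#' Multiclass accuracy is plain top-1; sensitivity, specificity and positive
#' prediction ratio are derived from an explicit binarization: for binary
#' panels the positive class defaults to the lexicographically smaller code,
#' for multiclass panels they are reported only when \code{positive} names
#' the positive class set.
#'
#' @param spectra a \linkS4class{SpectraMatrix}.
#' @param labels class codes; defaults to the panel's labels.
#' @param methods nonempty subset of \code{c("dca_svm", "svm", "fs_svm")}.
#' @param config a \linkS4class{DCAConfig} controlling the denoising and the
#'   fit mode.
#' @param C SVM regularization constant.
#' @param k folds (default 5).
#' @param repeats repeats of the whole k-fold cycle (default 10).
#' @param seed integer seed; repeat r uses seed + r - 1.
#' @param positive class codes treated as positive for the confusion-derived
#'   metrics.
#' @param alpha filter threshold for fs_svm (default 0.05, unadjusted).
#' @return An \linkS4class{EvalReport}.
#' @export
crossValidate <- function(spectra, labels = NULL,
                          methods = c("dca_svm", "svm"),
                          config = dcaConfig(), C = 1, k = 5, repeats = 10,
                          seed = 1, positive = NULL, alpha = 0.05) {
  stopifnot(is(spectra, "SpectraMatrix"))
  if (is.null(labels)) labels <- spectra@labels
  labels <- as.character(labels)
  if (length(labels) != nrow(spectra@intensities))
    stop("argument error: one label per sample required", call. = FALSE)
  allowed <- c("dca_svm", "svm", "fs_svm")
  methods <- unique(methods)
  if (length(methods) == 0 || !all(methods %in% allowed))
    stop("argument error: methods must be a nonempty subset of ",
         paste(allowed, collapse = ", "), call. = FALSE)
  X <- spectra@intensities
  classes <- sort(unique(labels))
  binary <- length(classes) == 2
  if (binary && is.null(positive)) positive <- classes[1]
  transductive <- config@fitMode == "transductive"

  metaFull <- if ("dca_svm" %in% methods && transductive)
    intensities(metaData(dca(spectra, config))) else NULL
  filterFull <- if ("fs_svm" %in% methods && transductive)
    .filterChannels(X, labels, alpha) else NULL

  rows <- list()
  for (r in seq_len(repeats)) {
    folds <- stratifiedFolds(labels, k = k, seed = seed + r - 1)
    for (f in seq_len(k)) {
      te <- folds == f
      tr <- !te
      for (method in methods) {
        if (method == "svm") {
          pred <- .trainPredict(X[tr, , drop = FALSE], labels[tr],
                                X[te, , drop = FALSE], C)
        } else if (method == "dca_svm") {
          if (transductive) {
            pred <- .trainPredict(metaFull[tr, , drop = FALSE], labels[tr],
                                  metaFull[te, , drop = FALSE], C)
          } else {
            sub <- SpectraMatrix(X[tr, , drop = FALSE], mz = spectra@mz,
                                 sampleIds = spectra@sampleIds[tr],
                                 labels = labels[tr])
            model <- dca(sub, config)
            Mtr <- intensities(metaData(model))
            Mte <- intensities(applyModel(model, X[te, , drop = FALSE]))
            pred <- .trainPredict(Mtr, labels[tr], Mte, C)
          }
        } else {
          chan <- if (transductive) filterFull
                  else .filterChannels(X[tr, , drop = FALSE], labels[tr],
                                       alpha)
          pred <- .trainPredict(X[tr, chan, drop = FALSE], labels[tr],
                                X[te, chan, drop = FALSE], C)
        }
        truth <- labels[te]
        acc <- mean(pred == truth)
        if (!is.null(positive)) {
          cc <- confusionCounts(binarizeLabels(c(truth, classes), positive)[
                                  seq_along(truth)],
                                binarizeLabels(c(pred, classes), positive)[
                                  seq_along(pred)])
          met <- suppressWarnings(classificationMetrics(cc))
        } else {
          cc <- list(TP = NA_integer_, TN = NA_integer_, FP = NA_integer_,
                     FN = NA_integer_)
          met <- c(accuracy = acc, sensitivity = NA_real_,
                   specificity = NA_real_, ppv = NA_real_)
        }
        rows[[length(rows) + 1]] <- data.frame(
          repeat_ = r, fold = f, method = method, accuracy = acc,
          sensitivity = unname(met["sensitivity"]),
          specificity = unname(met["specificity"]),
          ppv = unname(met["ppv"]),
          TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN,
          stringsAsFactors = FALSE)
      }
    }
  }
  foldsDf <- do.call(rbind, rows)
  metricNames <- c("accuracy", "sensitivity", "specificity", "ppv")
  summ <- do.call(rbind, lapply(methods, function(method) {
    sub <- foldsDf[foldsDf$method == method, ]
    do.call(rbind, lapply(metricNames, function(mn) {
      v <- sub[[mn]]
      data.frame(method = method, metric = mn,
                 mean = mean(v), sd = stats::sd(v),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(summ) <- NULL
  metadata <- list(
    schema = "1", seed = seed, k = k, repeats = repeats, methods = methods,
    C = C, fitMode = config@fitMode, center = config@center,
    wavelet = config@wavelet@wavelet, level = config@wavelet@level,
    boundary = config@wavelet@boundary, tau = config@tau,
    m = if (is.na(config@rho)) config@m else NA_integer_,
    rho = config@rho, alpha = alpha,
    positive = if (is.null(positive)) NA_character_ else positive,
    nSamples = nrow(X), nChannels = ncol(X),
    classCounts = as.list(table(labels)))
  new("EvalReport", folds = foldsDf, summary = summ, metadata = metadata)
}

#' Write an evaluation report as versioned JSON
#'
#' Serializes the metadata, per-method summary and per-fold table. The
#' output is byte-stable: the same report always produces the same file.
#'
#' @param report an \linkS4class{EvalReport}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeEvalReport <- function(report, path) {
  stopifnot(is(report, "EvalReport"))
  payload <- list(schema = report@metadata$schema,
                  metadata = report@metadata,
                  summary = report@summary,
                  folds = report@folds)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
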