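# Linear soft-margin SVM wrappers. The quadratic program is solved by the
# SMO solver in e1071/libsvm; this layer fixes the label orientation, exposes
# the dual variables, hyperplane normal and bias, and implements the
# one-against-one / max-wins multiclass scheme with a deterministic tie-break.

#' @importFrom e1071 svm
NULL

#' Prediction generic
#'
#' Predict class codes for new samples from a trained model.
#'
#' @param model a trained \linkS4class{SvmModel} or
#'   \linkS4class{MulticlassModel}.
#' @param samples a \linkS4class{SpectraMatrix} or numeric matrix.
#' @return Character vector of predicted class codes.
#' @export
setGeneric("predictLabels",
           function(model, samples) standardGeneric("predictLabels"))

#' Train a binary soft-margin linear SVM
#'
#' Solves the C-SVM problem (hinge-loss soft margin, linear kernel) and
#' returns the dual solution: support-vector multipliers alpha with
#' 0 <= alpha <= C and sum(alpha * c) = 0, the hyperplane normal
#' w = sum(alpha * c * y) and the bias b. Samples with decision value
#' w.y + b >= 0 are assigned the +1 class (a decision value of exactly 0
#' resolves to +1).
#'
#' @param samples training samples: a \linkS4class{SpectraMatrix} (typically
#'   denoised meta-data) or numeric matrix.
#' @param labels numeric vector of +1/-1 labels (both classes present).
#' @param C positive regularization constant (default 1).
#' @param tolerance SMO termination tolerance.
#' @return A validated \linkS4class{SvmModel}.
#' @examples
#' x <- matrix(c(-1, 1), ncol = 1)
#' m <- trainBinarySvm(x, c(-1, 1), C = 1e3)
#' m@w   # 1
#' @export
trainBinarySvm <- function(samples, labels, C = 1, tolerance = 1e-6) {
  X <- .asIntensityMatrix(samples)
  labels <- as.numeric(labels)
  if (!all(labels %in% c(-1, 1)))
    stop("argument error: labels must be +1/-1", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("argument error: both classes must be present", call. = FALSE)
  if (length(labels) != nrow(X))
    stop("argument error: one label per sample required", call. = FALSE)
  if (C <= 0) stop("argument error: C must be positive", call. = FALSE)
  fit <- e1071::svm(X, factor(labels, levels = c(1, -1)), scale = FALSE,
                    kernel = "linear", cost = C, tolerance = tolerance)
  coefs <- drop(fit$coefs)                 # alpha_i * c_i, solver orientation
  sv <- as.matrix(fit$SV)
  w <- drop(crossprod(sv, coefs))
  b <- -fit$rho
  # orient the decision so that positive values mean class +1
  d <- drop(X %*% w) + b
  if (mean(d[labels == 1]) < mean(d[labels == -1])) {
    coefs <- -coefs; w <- -w; b <- -b
  }
  new("SvmModel", alphas = abs(coefs), supportVectors = sv,
      supportLabels = sign(coefs), bias = b, cost = C, w = w,
      classMap = c("1", "-1"))
}

#' Decision values of a linear SVM
#'
#' Returns sum_i alpha_i c_i (y_i . y') + b for each sample, identical to
#' w . y' + b for the linear kernel. The predicted class is the sign, with 0
#' resolved to +1.
#'
#' @param model an \linkS4class{SvmModel}.
#' @param samples a \linkS4class{SpectraMatrix} or numeric matrix with the
#'   training channel count.
#' @return Numeric vector of decision values.
#' @export
decisionValues <- function(model, samples) {
  X <- .asIntensityMatrix(samples)
  if (ncol(X) != length(model@w))
    stop("shape error: model expects ", length(model@w), " channels, got ",
         ncol(X), call. = FALSE)
  drop(X %*% model@w) + model@bias
}

#' @rdname predictLabels
#' @export
setMethod("predictLabels", "SvmModel", function(model, samples) {
  d <- decisionValues(model, samples)
  ifelse(d >= 0, model@classMap[1], model@classMap[2])
})

#' Train a one-against-one multiclass linear SVM
#'
#' Builds one binary SVM per unordered class pair - k(k-1)/2 models for k
#' classes - each trained only on that pair's samples, with the
#' lexicographically smaller class code mapped to +1.
#'
#' @param samples training samples (\linkS4class{SpectraMatrix} or matrix).
#' @param labels class codes, k >= 2 distinct values.
#' @param C positive regularization constant.
#' @param tolerance SMO termination tolerance.
#' @return A \linkS4class{MulticlassModel}.
#' @export
trainMulticlassSvm <- function(samples, labels, C = 1, tolerance = 1e-6) {
  X <- .asIntensityMatrix(samples)
  labels <- as.character(labels)
  classSet <- sort(unique(labels))
  k <- length(classSet)
  if (k < 2) stop("argument error: need at least 2 classes", call. = FALSE)
  small <- names(which(table(labels) < 3))
  if (length(small))
    warning("class(es) with fewer than 3 samples: ",
            paste(small, collapse = ", "))
  models <- list()
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      ci <- classSet[i]; cj <- classSet[j]
      sel <- labels %in% c(ci, cj)
      y <- ifelse(labels[sel] == ci, 1, -1)
      m <- trainBinarySvm(X[sel, , drop = FALSE], y, C = C,
                          tolerance = tolerance)
      m@classMap <- c(ci, cj)
      models[[paste(ci, cj, sep = "|")]] <- m
    }
  }
  new("MulticlassModel", classSet = classSet, models = models, cost = C)
}

#' @rdname predictLabels
#' @details For a \linkS4class{MulticlassModel}, every pairwise model casts
#'   one vote per sample ("max-wins"). Vote ties are broken by the largest
#'   sum of absolute decision values accumulated over the comparisons each
#'   tied class won, then by the lexicographically smallest class code.
#' @export
setMethod("predictLabels", "MulticlassModel", function(model, samples) {
  X <- .asIntensityMatrix(samples)
  n <- nrow(X)
  k <- length(model@classSet)
  votes <- matrix(0L, n, k, dimnames = list(NULL, model@classSet))
  strength <- matrix(0, n, k, dimnames = list(NULL, model@classSet))
  for (m in model@models) {
    d <- decisionValues(m, X)
    winner <- ifelse(d >= 0, m@classMap[1], m@classMap[2])
    for (cl in m@classMap) {
      won <- winner == cl
      votes[won, cl] <- votes[won, cl] + 1L
      strength[won, cl] <- strength[won, cl] + abs(d[won])
    }
  }
  vapply(seq_len(n), function(s) {
    top <- which(votes[s, ] == max(votes[s, ]))
    if (length(top) > 1) {
      best <- top[strength[s, top] == max(strength[s, top])]
      model@classSet[min(best)]
    } else {
      model@classSet[top]
    }
  }, character(1))
})

# dual objective sum(alpha) - 1/2 ||w||^2, used in diagnostics and tests
.dualObjective <- function(model) {
  sum(model@alphas) - 0.5 * sum(model@w^2)
}

# primal objective 1/2 ||w||^2 + C * sum(hinge losses)
.primalObjective <- function(model, samples, labels) {
  d <- decisionValues(model, samples)
  xi <- pmax(0, 1 - as.numeric(labels) * d)
  0.5 * sum(model@w^2) + model@cost * sum(xi)
}
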