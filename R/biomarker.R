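# Feature scoring for biomarker discovery: per-channel two-sample t
# statistics (Welch or pooled-variance) for binary panels, one-way ANOVA F
# statistics for multiclass panels, computed directly from the group moments
# so that thousands of channels score in one pass.

.groupMoments <- function(X, labels) {
  classes <- sort(unique(labels))
  n <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  means <- vapply(classes, function(cl)
    colMeans(X[labels == cl, , drop = FALSE]), numeric(ncol(X)))
  vars <- vapply(classes, function(cl)
    apply(X[labels == cl, , drop = FALSE], 2, stats::var), numeric(ncol(X)))
  if (ncol(X) == 1) { means <- rbind(means); vars <- rbind(vars) }
  list(classes = classes, n = n, means = means, vars = vars)
}

# vectorized over channels; X is samples x channels with exactly two classes
.tStats <- function(X, labels, pooled = FALSE) {
  g <- .groupMoments(X, labels)
  if (length(g$classes) != 2)
    stop("argument error: t statistic needs exactly 2 classes", call. = FALSE)
  if (any(g$n < 2))
    stop("argument error: both groups need >= 2 observations", call. = FALSE)
  n1 <- g$n[1]; n2 <- g$n[2]
  dm <- abs(g$means[, 1] - g$means[, 2])
  v1 <- g$vars[, 1]; v2 <- g$vars[, 2]
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(dm))
  } else {
    a <- v1 / n1; b <- v2 / n2
    se2 <- a + b
    df <- se2^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  t <- dm / sqrt(se2)
  # degenerate channels: zero spread in both groups
  zero <- se2 == 0
  t[zero & dm == 0] <- 0
  t[zero & dm > 0] <- Inf
  p <- ifelse(is.finite(t), 2 * stats::pt(t, df, lower.tail = FALSE),
              0)
  p[zero & dm == 0] <- 1
  list(statistic = unname(t), p = unname(p))
}

.fStats <- function(X, labels) {
  g <- .groupMoments(X, labels)
  k <- length(g$classes)
  if (k < 2) stop("argument error: need >= 2 classes", call. = FALSE)
  if (any(g$n < 2))
    stop("argument error: every group needs >= 2 observations",
         call. = FALSE)
  nT <- sum(g$n)
  grand <- as.vector(g$means %*% g$n) / nT
  between <- as.vector((g$means - grand)^2 %*% g$n) / (k - 1)
  within <- as.vector(g$vars %*% (g$n - 1)) / (nT - k)
  f <- between / within
  zero <- within == 0
  f[zero & between == 0] <- 0
  f[zero & between > 0] <- Inf
  p <- ifelse(is.finite(f),
              stats::pf(f, k - 1, nT - k, lower.tail = FALSE), 0)
  p[zero & between == 0] <- 1
  list(statistic = unname(f), p = unname(p))
}

#' Two-sample t statistic for one feature
#'
#' Absolute-value two-sample t statistic |mean(x) - mean(y)| /
#' sqrt(s_x^2/n1 + s_y^2/n2) (Welch, the default) or its pooled-variance
#' form with s_p^2 = ((n1-1)s_x^2 + (n2-1)s_y^2) / (n1+n2-2), with a
#' two-sided p-value (df = n1+n2-2 pooled, Welch-Satterthwaite otherwise).
#' A feature that is constant within both groups with equal means scores
#' t = 0, p = 1.
#'
#' @param values numeric feature vector.
#' @param labels two-class label vector aligned with \code{values}.
#' @param pooled use the pooled-variance form (default FALSE = Welch).
#' @return Named numeric \code{c(statistic, p)}.
#' @examples
#' tStatistic(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3), pooled = TRUE)
#' @export
tStatistic <- function(values, labels, pooled = FALSE) {
  r <- .tStats(matrix(values, ncol = 1), as.character(labels),
               pooled = pooled)
  c(statistic = r$statistic, p = r$p)
}

#' One-way ANOVA F statistic for one feature
#'
#' Between-group mean square over within-group mean square, with a p-value
#' from F(k-1, nT-k). Identical groups score F = 0, p = 1.
#'
#' @param values numeric feature vector.
#' @param labels label vector with k >= 2 classes, every group of size >= 2.
#' @return Named numeric \code{c(statistic, p)}.
#' @examples
#' fStatistic(c(1, 2, 3, 2, 3, 4, 3, 4, 5), rep(c("a", "b", "c"), each = 3))
#' @export
fStatistic <- function(values, labels) {
  r <- .fStats(matrix(values, ncol = 1), as.character(labels))
  c(statistic = r$statistic, p = r$p)
}

#' Rank channels of a denoised panel as candidate biomarkers
#'
#' Scores every channel with the two-sample t statistic (two classes; Welch
#' by default, pooled by flag) or the one-way ANOVA F statistic (more than
#' two classes), and returns the channels ranked by decreasing statistic
#' (equivalently increasing p). Ties are broken by the lower channel index.
#' Channel indices are reported 1-based together with the channel's m/z
#' value. Constant channels score 0 with p = 1 and are counted in a message.
#'
#' @param meta a \linkS4class{SpectraMatrix} (typically DCA meta-data) or
#'   numeric matrix.
#' @param labels class codes; defaults to the panel's own labels.
#' @param topK number of top-ranked channels to return (default 3); use
#'   \code{full = TRUE} for the complete table.
#' @param stat \code{"welch"} (default) or \code{"pooled"}; only used for
#'   two-class panels.
#' @param adjust add a Benjamini-Hochberg adjusted p-value column.
#' @param full return all channels instead of the top \code{topK}.
#' @return A data.frame with columns rank, channel, mz, statistic, p_value,
#'   kind (and p_adjusted when \code{adjust}).
#' @export
rankBiomarkers <- function(meta, labels = NULL, topK = 3,
                           stat = c("welch", "pooled"), adjust = FALSE,
                           full = FALSE) {
  stat <- match.arg(stat)
  X <- .asIntensityMatrix(meta)
  mz <- if (is(meta, "SpectraMatrix")) meta@mz else seq_len(ncol(X))
  if (is.null(labels) && is(meta, "SpectraMatrix")) labels <- meta@labels
  if (is.null(labels) || length(labels) == 0)
    stop("argument error: labels are required", call. = FALSE)
  labels <- as.character(labels)
  if (topK < 1 || topK > ncol(X))
    stop("argument error: topK must be in 1..n_channels", call. = FALSE)
  k <- length(unique(labels))
  res <- if (k == 2) .tStats(X, labels, pooled = stat == "pooled")
         else .fStats(X, labels)
  kind <- if (k == 2) "t" else "F"
  nZero <- sum(res$statistic == 0 & res$p == 1)
  if (nZero > 0)
    message(nZero, " zero-variance channel(s) scored 0 with p = 1")
  ord <- order(-res$statistic, seq_along(res$statistic))
  tab <- data.frame(rank = seq_along(ord), channel = ord, mz = mz[ord],
                    statistic = res$statistic[ord], p_value = res$p[ord],
                    kind = kind, stringsAsFactors = FALSE)
  if (adjust) tab$p_adjusted <- stats::p.adjust(tab$p_value, method = "BH")
  attr(tab, "stat") <- if (k == 2) stat else "anova"
  if (full) tab else tab[seq_len(topK), , drop = FALSE]
}

#' Linear-separability check on the top-ranked biomarkers
#'
#' Trains a linear SVM with a large cost on the top-k biomarker channels
#' only and reports the training accuracy; the panel is called separable on
#' those biomarkers when the training accuracy is exactly 1. The per-sample
#' coordinates on the selected channels are returned for external 3-D
#' plotting.
#'
#' @param meta a \linkS4class{SpectraMatrix} or matrix.
#' @param labels class codes; defaults to the panel's labels.
#' @param table an existing ranking from [rankBiomarkers()]; computed when
#'   NULL.
#' @param topK number of biomarker channels to use (default 3).
#' @param C large cost approximating a hard margin (default 1e6).
#' @return A list: \code{trainingAccuracy}, \code{separable},
#'   \code{channels}, and \code{coords} (a data.frame of sample id, label
#'   and the selected channels' intensities).
#' @export
separabilityCheck <- function(meta, labels = NULL, table = NULL, topK = 3,
                              C = 1e6) {
  X <- .asIntensityMatrix(meta)
  if (is.null(labels) && is(meta, "SpectraMatrix")) labels <- meta@labels
  if (is.null(labels) || length(labels) == 0)
    stop("argument error: labels are required", call. = FALSE)
  labels <- as.character(labels)
  if (topK < 1) stop("argument error: topK must be >= 1", call. = FALSE)
  if (is.null(table))
    table <- rankBiomarkers(meta, labels, topK = topK)
  channels <- table$channel[seq_len(min(topK, nrow(table)))]
  Xk <- X[, channels, drop = FALSE]
  model <- trainMulticlassSvm(Xk, labels, C = C)
  pred <- predictLabels(model, Xk)
  acc <- mean(pred == labels)
  ids <- if (is(meta, "SpectraMatrix")) meta@sampleIds
         else paste0("S", seq_len(nrow(X)))
  coords <- data.frame(id = ids, label = labels, Xk,
                       stringsAsFactors = FALSE)
  names(coords)[-(1:2)] <- paste0("mz_", signif(table$mz[seq_along(channels)],
                                                8))
  list(trainingAccuracy = acc, separable = acc == 1, channels = channels,
       coords = coords)
}
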