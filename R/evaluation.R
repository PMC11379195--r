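#' ROC curve and trapezoidal AUC
#'
#' Sweeps the decision threshold over the distinct score values (one point
#' per distinct score, so ties are grouped), producing the usual
#' (false-positive-rate, true-positive-rate) staircase from (0, 0) to
#' (1, 1), and integrates it with the trapezoidal rule.
#'
#' @param scores numeric scores, larger = more cancer-like.
#' @param labels class labels (\code{"Cancer"} positive); both classes must
#'   be present.
#' @return an object of class \code{"roc_result"}: list with a \code{points}
#'   data.frame (threshold, fpr, tpr) and \code{auc}.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as_label_factor(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have the same length", call. = FALSE)
  }
  n_pos <- sum(labels == "Cancer")
  n_neg <- sum(labels == "Normal")
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- as.numeric(labels[ord] == "Cancer")
  # group tied scores: cumulative counts at the last index of each tie block
  last <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  points <- data.frame(threshold = c(Inf, s[last]),
                       fpr = c(0, fp / n_neg),
                       tpr = c(0, tp / n_pos))
  auc <- sum(diff(points$fpr) * (points$tpr[-1] + points$tpr[-nrow(points)]) / 2)
  structure(list(points = points, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.4f (%d positives, %d negatives, %d threshold points)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "s",
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Two-component PCA projection for cohort QC
#'
#' Mean-centered principal-component projection of the samples (no scaling),
#' used to eyeball cancer/normal separation and spot swapped or aberrant
#' samples before any modelling. The sign of each component is fixed so that
#' its largest-magnitude loading is positive.
#'
#' @param x complete [meth_matrix()] or numeric matrix.
#' @param k number of components (default 2); must not exceed
#'   \code{min(n, p)}.
#' @return matrix of sample coordinates (n x k) with attributes
#'   \code{"sdev"} (component standard deviations) and \code{"rotation"}.
#' @export
pca_project <- function(x, k = 2) {
  v <- values_of(x)
  if (anyNA(v)) stop("matrix must be complete for PCA", call. = FALSE)
  if (nrow(v) < 2) stop("need at least 2 samples", call. = FALSE)
  if (k > min(dim(v))) {
    stop(sprintf("k = %d exceeds min(n, p) = %d", k, min(dim(v))), call. = FALSE)
  }
  pc <- stats::prcomp(v, center = TRUE, scale. = FALSE, rank. = k)
  flip <- vapply(seq_len(k), function(j) {
    load <- pc$rotation[, j]
    sign(load[which.max(abs(load))]) < 0
  }, logical(1))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  scores[, flip] <- -scores[, flip, drop = FALSE]
  rot[, flip] <- -rot[, flip, drop = FALSE]
  structure(scores, sdev = pc$sdev[seq_len(k)], rotation = rot)
}

# Pairwise-concordance AUC: fraction of (positive, negative) pairs where the
# positive outranks the negative, ties counted half. O(n_pos * n_neg);
# used as an independent cross-check of the trapezoidal integral.
concordance_auc <- function(scores, labels) {
  labels <- as_label_factor(labels)
  pos <- scores[labels == "Cancer"]
  neg <- scores[labels == "Normal"]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}
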