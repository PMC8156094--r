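# SVM baseline on the 9 per-subject summary statistics. The margin is
# mapped through a logistic so both model families emit a fall
# probability in (0, 1) for ROC analysis.

#' Fit the SVM baseline classifier
#'
#' An RBF-kernel support vector machine on standardized features. The
#' decision score is oriented so that larger means more faller-like and
#' calibrated to `(0, 1)` via the logistic of the margin.
#'
#' @param features Numeric matrix or data.frame of summary features
#'   (9 columns for the TUG pipeline).
#' @param labels 0/1 labels (1 = faller); both classes required.
#' @param kernel,cost Passed to [e1071::svm()].
#' @param index Optional integer multiset of row indices (a row listed k
#'   times carries weight k in training).
#' @return An `svm_fit`.
#' @export
fit_svm <- function(features, labels, kernel = "radial", cost = 1,
                    index = NULL) {
  x <- as.matrix(features)
  if (is.null(index)) index <- seq_len(nrow(x))
  y <- labels[index]
  if (length(unique(y)) < 2) stopf("training set contains a single class")
  xt <- x[index, , drop = FALSE]
  # guard: constant columns break e1071's internal scaling
  keep <- apply(xt, 2, function(col) stats::sd(col) > 0)
  if (!any(keep)) stopf("all features are constant")
  fit <- e1071::svm(xt[, keep, drop = FALSE], factor(y, levels = c(0, 1)),
                    kernel = kernel, cost = cost, scale = TRUE)
  dv <- attr(stats::predict(fit, xt[, keep, drop = FALSE],
                            decision.values = TRUE), "decision.values")
  # e1071 reports the margin for its first label; flip so + means faller
  flip <- if (startsWith(colnames(dv)[1], "0")) -1 else 1
  structure(list(svm = fit, keep = keep, flip = flip,
                 manifest = list(n = length(index), class_balance = mean(y))),
            class = "svm_fit")
}

#' @export
predict_fall_probability.svm_fit <- function(fit, newdata, batch_size = NULL) {
  x <- as.matrix(newdata)[, fit$keep, drop = FALSE]
  dv <- attr(stats::predict(fit$svm, x, decision.values = TRUE),
             "decision.values")
  stats::plogis(fit$flip * as.numeric(dv))
}
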