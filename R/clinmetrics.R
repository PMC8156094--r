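# Screening statistics: confusion matrices, Acc/Se/Sp/F1/Youden J,
# ROC/AUC with C-statistic inference, clinical-cutoff dichotomization,
# Youden-optimal cutoffs, and 2x2 odds ratios with Woolf CIs.
# The positive class is "faller" (label 1) throughout.

#' Build a confusion matrix
#'
#' @param pred,truth Integer vectors of 0/1 labels (1 = faller, the
#'   positive class), equal length.
#' @return A `confusion_matrix` with integer fields `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) == 0) stopf("empty input")
  if (length(pred) != length(truth)) stopf("pred and truth lengths differ")
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stopf("labels must be 0/1")
  confusion_matrix(tp = sum(pred == 1 & truth == 1),
                   fp = sum(pred == 1 & truth == 0),
                   fn = sum(pred == 0 & truth == 1),
                   tn = sum(pred == 0 & truth == 0))
}

#' @rdname confusion
#' @param tp,fp,fn,tn Nonnegative integer counts.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("confusion counts must be nonnegative integers")
  if (sum(counts) < 1) stopf("confusion matrix must contain at least one count")
  structure(as.list(as.integer(counts)), names = names(counts),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(pred = c("faller", "non_faller"),
                              truth = c("faller", "non_faller")))
  print(m)
  invisible(x)
}

#' Screening metrics of a confusion matrix
#'
#' Acc = (tp+tn)/n, Se = tp/(tp+fn), Sp = tn/(tn+fp),
#' F1 = 2tp/(2tp+fp+fn), J = Se + Sp - 1 (Youden's index). A metric with
#' a zero denominator is returned as `NA` (explicit sentinel), never as a
#' silent 0.
#'
#' @param cm A `confusion_matrix`.
#' @return Named numeric vector `c(acc, se, sp, f1, j)`.
#' @export
basic_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  se <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else NA_real_
  sp <- if (cm$tn + cm$fp > 0) cm$tn / (cm$tn + cm$fp) else NA_real_
  f1 <- if (2 * cm$tp + cm$fp + cm$fn > 0)
    2 * cm$tp / (2 * cm$tp + cm$fp + cm$fn) else NA_real_
  c(acc = (cm$tp + cm$tn) / n, se = se, sp = sp, f1 = f1, j = se + sp - 1)
}

#' Area under the ROC curve
#'
#' The Mann–Whitney concordance probability that a random faller's score
#' exceeds a random non-faller's, counting ties as 1/2 (equal to the
#' trapezoidal ROC area). Computed with midranks.
#'
#' @param scores Numeric scores (higher = more faller-like).
#' @param labels 0/1 labels (1 = faller).
#' @return The AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stopf("scores and labels lengths differ")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' C-statistic test of AUC against 0.5
#'
#' Tests the null of a random-guess classifier (AUC = 0.5) against
#' AUC > 0.5. The standard error is Hanley–McNeil:
#' `SE^2 = (A(1-A) + (n1-1)(Q1-A^2) + (n0-1)(Q2-A^2)) / (n1 n0)` with
#' `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`; `z = (A - 0.5)/SE`, one-sided
#' normal p, and a 95% CI `A +/- 1.96 SE` clipped to `[0, 1]`.
#'
#' @inheritParams roc_auc
#' @return List with `auc`, `se`, `z`, `ci_low`, `ci_high`,
#'   `p_one_sided`, `degenerate` (TRUE when SE collapsed to 0 and the CI
#'   was clipped).
#' @export
c_statistic_test <- function(scores, labels) {
  a <- roc_auc(scores, labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
               (n1 * n0))
  degenerate <- !is.finite(se) || se == 0
  z <- if (degenerate) sign(a - 0.5) * Inf else (a - 0.5) / se
  if (a == 0.5) z <- 0
  list(auc = a, se = se, z = z,
       ci_low = max(0, a - 1.96 * se), ci_high = min(1, a + 1.96 * se),
       p_one_sided = stats::pnorm(z, lower.tail = FALSE),
       degenerate = degenerate)
}

#' Define a clinical cutoff rule
#'
#' The direction is always explicit: `high_is_faller` predicts faller
#' when `value >= cutoff` (TUG time, "14 s or more"); `low_is_faller`
#' when `value <= cutoff` (4-stage balance "30 s or less", 30-second
#' chair stand "8 or fewer"). The boundary is inclusive in both cases.
#'
#' @param variable Name of the clinical variable.
#' @param cutoff Numeric cutoff.
#' @param direction `"high_is_faller"` or `"low_is_faller"`.
#' @return A `cutoff_rule`.
#' @export
cutoff_rule <- function(variable, cutoff,
                        direction = c("high_is_faller", "low_is_faller")) {
  direction <- match.arg(direction)
  structure(list(variable = variable, cutoff = cutoff, direction = direction),
            class = "cutoff_rule")
}

#' Dichotomize a continuous clinical score
#'
#' @param values Numeric vector.
#' @param rule A [cutoff_rule()].
#' @return Integer vector of predicted 0/1 labels (1 = faller).
#' @export
dichotomize <- function(values, rule) {
  stopifnot(inherits(rule, "cutoff_rule"))
  if (rule$direction == "high_is_faller")
    as.integer(values >= rule$cutoff)
  else
    as.integer(values <= rule$cutoff)
}

#' Youden-optimal cutoff
#'
#' Sweeps the sorted unique observed values as candidate cutoffs and
#' returns the one maximizing J = Se + Sp - 1. Ties are broken toward
#' higher sensitivity, then toward the lower cutoff.
#'
#' @param values Numeric clinical scores.
#' @param labels 0/1 true labels.
#' @param direction Passed to [cutoff_rule()].
#' @return List with `cutoff`, `j_max`, and `table` (one row per
#'   candidate: cutoff, se, sp, j).
#' @export
youden_optimal_cutoff <- function(values, labels,
                                  direction = c("high_is_faller", "low_is_faller")) {
  direction <- match.arg(direction)
  if (length(unique(labels)) < 2) stopf("both classes must be present")
  cand <- sort(unique(values))
  tab <- do.call(rbind, lapply(cand, function(cut) {
    m <- basic_metrics(confusion(
      dichotomize(values, cutoff_rule("x", cut, direction)), labels))
    data.frame(cutoff = cut, se = m[["se"]], sp = m[["sp"]], j = m[["j"]])
  }))
  best <- tab[order(-tab$j, -tab$se, tab$cutoff), ][1, ]
  list(cutoff = best$cutoff, j_max = best$j, table = tab)
}

#' Odds ratio of a 2x2 table with Woolf confidence interval
#'
#' For a table with cells a (exposed faller), b (exposed non-faller),
#' c (unexposed faller), d (unexposed non-faller):
#' `OR = ad / bc`, Woolf 95% CI
#' `exp(ln OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`, and a two-sided
#' normal p-value on ln OR. A single zero cell triggers the
#' Haldane–Anscombe 0.5 correction (flagged); two zero cells in one row
#' or column make the OR undefined (`NA` sentinel).
#'
#' @param x A `confusion_matrix` (a = tp, b = fp, c = fn, d = tn), a 2x2
#'   matrix `rbind(c(a, b), c(c, d))`, or a length-4 vector `c(a, b, c, d)`.
#' @return List with `or`, `ci_low`, `ci_high`, `p`, `corrected`.
#' @export
odds_ratio_2x2 <- function(x) {
  if (inherits(x, "confusion_matrix")) cells <- c(x$tp, x$fp, x$fn, x$tn)
  else if (is.matrix(x)) cells <- c(x[1, 1], x[1, 2], x[2, 1], x[2, 2])
  else if (length(x) == 4) cells <- as.numeric(x)
  else stopf("x must be a confusion_matrix, 2x2 matrix, or length-4 vector")
  if (any(cells < 0)) stopf("cells must be nonnegative")
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  two_zero <- (a == 0 && b == 0) || (c == 0 && d == 0) ||
    (a == 0 && c == 0) || (b == 0 && d == 0)
  if (two_zero)
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                p = NA_real_, corrected = FALSE))
  corrected <- any(cells == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- log(or) / se
  list(or = or,
       ci_low = exp(log(or) - 1.96 * se), ci_high = exp(log(or) + 1.96 * se),
       p = 2 * stats::pnorm(-abs(z)), corrected = corrected)
}
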