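# Sliding-window segmentation of preprocessed signals into fixed-length
# 3-channel CNN inputs, and the 9 per-subject summary statistics used as
# SVM inputs (mean, SD, CV per channel).

#' Cut a 3-channel signal into sliding windows
#'
#' Windows of `window_s` seconds start at 0, `stride_s`, `2*stride_s`, ...;
#' the count is `floor((L_s - window_s) / stride_s) + 1`. A final partial
#' window is never emitted (zero-padding upstream guarantees coverage).
#'
#' @param mat Numeric matrix, samples x 3 channels.
#' @param rate Sample rate in Hz.
#' @param window_s,stride_s Window length and stride in seconds; both
#'   must be integer multiples of the sample period.
#' @return A list with `x` (array `n_segments x window_samples x 3`) and
#'   `start_idx` (1-based start sample of each window).
#' @export
sliding_windows <- function(mat, rate, window_s = 3, stride_s = 1) {
  win <- window_s * rate
  stride <- stride_s * rate
  if (abs(win - round(win)) > 1e-9 || abs(stride - round(stride)) > 1e-9)
    stopf("window and stride must be integer multiples of the sample period")
  win <- as.integer(round(win)); stride <- as.integer(round(stride))
  L <- nrow(mat)
  if (L < win) stopf("signal length %d shorter than window %d", L, win)
  n_seg <- (L - win) %/% stride + 1L
  starts <- 1L + stride * (seq_len(n_seg) - 1L)
  x <- array(0, c(n_seg, win, 3L))
  for (k in seq_len(n_seg))
    x[k, , ] <- mat[starts[k]:(starts[k] + win - 1L), ]
  list(x = x, start_idx = starts)
}

#' Segment one modality/location of a preprocessed cohort
#'
#' Builds the stack of fixed-length 3-channel windows fed to the CNN,
#' carrying the subject id and label of every window. Windows lying
#' entirely in the zero-padded tail are flagged and, by default, dropped.
#'
#' @param cohort A preprocessed `tug_cohort` (see [preprocess_cohort()]).
#' @param modality `"gyro"` or `"accel"`.
#' @param location `"neck"`, `"right_foot"` or `"left_foot"`.
#' @param window_s,stride_s Passed to [sliding_windows()].
#' @param drop_padding Drop padding-only windows (default TRUE).
#' @return A `segment_set`: list with array `x`, vectors `subject_id`,
#'   `label`, `start_idx`, `is_padding_only`, and the tags `modality`,
#'   `location`, `rate`.
#' @export
segment_cohort <- function(cohort, modality = c("gyro", "accel"),
                           location = SENSOR_LOCATIONS,
                           window_s = 3, stride_s = 1, drop_padding = TRUE) {
  modality <- match.arg(modality)
  location <- match.arg(location)
  if (is.null(cohort$true_n))
    stopf("cohort has no padding information; run preprocess_cohort() first")
  ids <- names(cohort$recordings)
  pieces <- lapply(ids, function(id) {
    rec <- cohort$recordings[[id]][[location]]
    if (is.null(rec)) return(NULL)
    sw <- sliding_windows(rec[[modality]], rec$sample_rate_hz, window_s, stride_s)
    n <- dim(sw$x)[1]
    lab <- cohort$subjects$label[cohort$subjects$subject_id == id]
    list(x = sw$x, subject_id = rep(id, n), label = rep(lab, n),
         start_idx = sw$start_idx,
         true_n = rep(cohort$true_n[[id]], n))
  })
  pieces <- Filter(Negate(is.null), pieces)
  x <- do.call(abind_first, lapply(pieces, `[[`, "x"))
  segset <- structure(list(
    x = x,
    subject_id = unlist(lapply(pieces, `[[`, "subject_id")),
    label = as.integer(unlist(lapply(pieces, `[[`, "label"))),
    start_idx = unlist(lapply(pieces, `[[`, "start_idx")),
    is_padding_only = logical(dim(x)[1]),
    modality = modality, location = location,
    rate = cohort$sample_rate_hz), class = "segment_set")
  segset <- flag_padding_segments(
    segset, stats::setNames(unlist(lapply(pieces, function(p) p$true_n[1])),
                            vapply(pieces, function(p) p$subject_id[1], character(1))))
  if (drop_padding) segset <- subset_segments(segset, !segset$is_padding_only)
  segset
}

# rbind for 3-d arrays along the first dimension
abind_first <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  ns <- vapply(parts, function(p) dim(p)[1], integer(1))
  out <- array(0, c(sum(ns), d[2], d[3]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' Flag windows lying entirely in the zero-padded tail
#'
#' A window is padding-only iff its (0-based) start sample is at or
#' beyond the subject's true (unpadded) length.
#'
#' @param segset A `segment_set`.
#' @param true_lengths Named integer vector of unpadded sample counts per
#'   subject.
#' @return The `segment_set` with `is_padding_only` set.
#' @export
flag_padding_segments <- function(segset, true_lengths) {
  tn <- unname(true_lengths[segset$subject_id])
  segset$is_padding_only <- (segset$start_idx - 1L) >= tn
  segset
}

#' Subset a segment set by index or logical mask
#' @param segset A `segment_set`.
#' @param keep Logical mask or integer indices over segments.
#' @return The subset `segment_set`.
#' @export
subset_segments <- function(segset, keep) {
  segset$x <- segset$x[keep, , , drop = FALSE]
  for (f in c("subject_id", "label", "start_idx", "is_padding_only"))
    segset[[f]] <- segset[[f]][keep]
  segset
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("segment_set: %d windows of %d x 3 (%s, %s), %d subjects\n",
              dim(x$x)[1], dim(x$x)[2], x$modality, x$location,
              length(unique(x$subject_id))))
  invisible(x)
}

#' Per-channel summary features of a recording
#'
#' Computes the mean, population standard deviation (ddof = 0) and
#' coefficient of variation (CV = sd/mean) of each of the three channels
#' over the unpadded extent only — 9 values, the SVM input. When
#' `|mean| < eps` the CV is undefined; it is set to 0 with a warning.
#'
#' @param mat Numeric matrix, samples x 3 channels.
#' @param true_n Unpadded sample count (>= 2); rows beyond it are ignored.
#' @param eps Mean magnitude below which the CV is declared undefined.
#' @return Named numeric vector of 9 features
#'   (`<channel>_mean`, `<channel>_sd`, `<channel>_cv`).
#' @export
summary_features <- function(mat, true_n = nrow(mat), eps = 1e-8) {
  if (true_n < 2) stopf("need >= 2 samples within the true extent")
  m <- mat[seq_len(true_n), , drop = FALSE]
  ch <- colnames(m) %||% paste0("c", seq_len(ncol(m)))
  out <- numeric(0)
  for (j in seq_len(ncol(m))) {
    mu <- mean(m[, j])
    sdev <- sqrt(mean((m[, j] - mu)^2))   # population sd
    cv <- if (abs(mu) < eps) {
      warnf("channel %s mean below %g; CV set to 0", ch[j], eps)
      0
    } else sdev / mu
    v <- c(mu, sdev, cv)
    names(v) <- paste0(ch[j], c("_mean", "_sd", "_cv"))
    out <- c(out, v)
  }
  out
}

#' Per-subject feature table for the SVM
#'
#' @param cohort A preprocessed `tug_cohort`.
#' @param modality `"gyro"` or `"accel"`.
#' @param location Sensor location.
#' @return A data.frame with `subject_id`, `label` and the 9 features.
#' @export
cohort_features <- function(cohort, modality = c("gyro", "accel"),
                            location = SENSOR_LOCATIONS) {
  modality <- match.arg(modality)
  location <- match.arg(location)
  ids <- names(cohort$recordings)
  rows <- lapply(ids, function(id) {
    rec <- cohort$recordings[[id]][[location]]
    if (is.null(rec)) return(NULL)
    tn <- if (!is.null(cohort$true_n)) cohort$true_n[[id]] else n_samples(rec)
    f <- summary_features(rec[[modality]], tn)
    cbind(data.frame(subject_id = id,
                     label = cohort$subjects$label[cohort$subjects$subject_id == id]),
          as.data.frame(as.list(f)))
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
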