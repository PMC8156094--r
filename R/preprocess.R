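# Signal curation chain: Fourier-domain resampling, cohort-wide min-max
# normalization per modality, and zero-padding to the longest recording.
# The chain order is resample -> normalize -> pad.

#' Fourier-domain resampling of a numeric vector
#'
#' Resamples `x` to `n_out` points by truncating (or zero-extending) its
#' discrete Fourier spectrum, i.e. an ideal low-pass at the new Nyquist
#' frequency followed by reconstruction — the classical FFT `resample`
#' algorithm. Assumes the signal is periodic over its support; energy of
#' components below the new Nyquist is preserved.
#'
#' @param x Numeric vector.
#' @param n_out Target length (>= 2).
#' @return Numeric vector of length `n_out`.
#' @export
fourier_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out < 2) stopf("resampled length %d < 2", n_out)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  Y <- complex(length.out = n_out)
  m <- min(n, n_out)
  nh <- m %/% 2 + 1L                      # positive-frequency bins incl. DC
  Y[seq_len(nh)] <- X[seq_len(nh)]
  nneg <- m - nh                          # negative-frequency bins
  if (nneg > 0)
    Y[(n_out - nneg + 1L):n_out] <- X[(n - nneg + 1L):n]
  if (m %% 2 == 0) {
    if (n_out < n) {
      # fold the energy of the old conjugate Nyquist bin into the new one
      Y[nh] <- Y[nh] + X[n - nh + 2L]
    } else {
      # split the Nyquist bin symmetrically when upsampling
      Y[nh] <- Y[nh] / 2
      Y[n_out - nh + 2L] <- Y[nh]
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Resample a recording to a lower rate
#'
#' Each of the six channels is independently Fourier-resampled to
#' `round(n_samples * target_rate_hz / sample_rate_hz)` points, removing
#' all frequency content above the new Nyquist (`target_rate_hz / 2`).
#'
#' @param rec A `sensor_recording`.
#' @param target_rate_hz Target rate, strictly below the recording rate
#'   (default 100).
#' @return The resampled `sensor_recording`.
#' @export
fft_resample <- function(rec, target_rate_hz = 100) {
  if (target_rate_hz >= rec$sample_rate_hz)
    stopf("target rate %g Hz must be below the recording rate %g Hz",
          target_rate_hz, rec$sample_rate_hz)
  n_out <- round(n_samples(rec) * target_rate_hz / rec$sample_rate_hz)
  if (n_out < 2) stopf("resampled length %d < 2", n_out)
  res <- function(m) {
    out <- apply(m, 2, fourier_resample, n_out = n_out)
    colnames(out) <- colnames(m)
    out
  }
  sensor_recording(rec$subject_id, rec$location, target_rate_hz,
                   res(rec$accel), res(rec$gyro))
}

#' Fit cohort-wide min-max normalization
#'
#' Computes, per modality (acceleration / angular velocity), the signed
#' minimum and maximum over all samples, channels, locations and subjects
#' in scope. With `scope = "train_only"` only `train_ids` contribute the
#' extremes, the statistically sound alternative to the default
#' all-subjects fit.
#'
#' @param cohort A `tug_cohort`.
#' @param scope `"all_subjects"` (default) or `"train_only"`.
#' @param train_ids Subject ids defining the scope when `train_only`.
#' @return A `norm_state` with fields `accel_min`, `accel_max`,
#'   `gyro_min`, `gyro_max`, `scope`.
#' @export
fit_normalization <- function(cohort, scope = c("all_subjects", "train_only"),
                              train_ids = NULL) {
  scope <- match.arg(scope)
  ids <- if (scope == "train_only") {
    if (is.null(train_ids)) stopf("train_ids required for scope='train_only'")
    intersect(names(cohort$recordings), train_ids)
  } else names(cohort$recordings)
  if (length(ids) == 0) stopf("no recordings in scope")
  a_min <- Inf; a_max <- -Inf; g_min <- Inf; g_max <- -Inf
  for (id in ids) for (rec in cohort$recordings[[id]]) {
    a_min <- min(a_min, rec$accel); a_max <- max(a_max, rec$accel)
    g_min <- min(g_min, rec$gyro); g_max <- max(g_max, rec$gyro)
  }
  if (a_max <= a_min || g_max <= g_min)
    stopf("degenerate normalization range (max == min)")
  structure(list(accel_min = a_min, accel_max = a_max,
                 gyro_min = g_min, gyro_max = g_max, scope = scope),
            class = "norm_state")
}

#' Apply min-max normalization to a recording
#'
#' Maps `accel' = (accel - accel_min) / (accel_max - accel_min)` and
#' analogously for the gyroscope. Values of out-of-scope data may fall
#' outside `[0, 1]`; they are NOT clipped, a warning reports them.
#'
#' @param rec A `sensor_recording`.
#' @param state A fitted `norm_state`.
#' @return The normalized `sensor_recording`.
#' @export
apply_normalization <- function(rec, state) {
  accel <- (rec$accel - state$accel_min) / (state$accel_max - state$accel_min)
  gyro <- (rec$gyro - state$gyro_min) / (state$gyro_max - state$gyro_min)
  tol <- 1e-12
  n_out <- sum(accel < -tol | accel > 1 + tol) + sum(gyro < -tol | gyro > 1 + tol)
  if (n_out > 0)
    warnf("%d normalized value(s) outside [0, 1] for %s/%s (out-of-scope data)",
          n_out, rec$subject_id, rec$location)
  sensor_recording(rec$subject_id, rec$location, rec$sample_rate_hz, accel, gyro)
}

#' Zero-pad all recordings of a cohort to the longest length
#'
#' Zeros are appended at the end only; the true (unpadded) length per
#' subject is stored in `cohort$true_n` so downstream stages can identify
#' padding-only windows. The common length is the longest recording
#' rounded up to a whole `align_s` seconds, so that an integer-second
#' sliding window grid lands exactly on the end of the padded signals
#' and every real sample falls inside at least one window.
#'
#' @param cohort A `tug_cohort` whose recordings share one sample rate.
#' @param align_s Alignment quantum in seconds (default 1, matching the
#'   default window stride; 0 disables alignment).
#' @return The cohort with equal-length recordings and `true_n` set.
#' @export
zero_pad <- function(cohort, align_s = 1) {
  rates <- unlist(lapply(cohort$recordings, function(r)
    vapply(r, function(x) x$sample_rate_hz, numeric(1))))
  if (length(unique(rates)) != 1)
    stopf("all recordings must share one sample rate before padding")
  lens <- vapply(cohort$recordings, function(r) max(vapply(r, n_samples, numeric(1))),
                 numeric(1))
  l_max <- max(lens)
  if (align_s > 0) {
    quantum <- align_s * rates[1]
    l_max <- as.integer(ceiling(l_max / quantum) * quantum)
  }
  pad <- function(rec) {
    n <- n_samples(rec)
    if (n == l_max) return(rec)
    z <- matrix(0, l_max - n, 3)
    sensor_recording(rec$subject_id, rec$location, rec$sample_rate_hz,
                     rbind(rec$accel, z), rbind(rec$gyro, z))
  }
  cohort$true_n <- stats::setNames(as.integer(lens), names(cohort$recordings))
  cohort$recordings <- lapply(cohort$recordings, function(r) lapply(r, pad))
  cohort$padded_to <- as.integer(l_max)
  cohort
}

#' Run the full preprocessing chain on a cohort
#'
#' Resample to `target_rate_hz` -> fit and apply min-max normalization ->
#' zero-pad to the longest recording.
#'
#' @param cohort A `tug_cohort`.
#' @param target_rate_hz Target sample rate (default 100 Hz).
#' @param norm_scope `"all_subjects"` or `"train_only"`.
#' @param train_ids Subject ids for `train_only` scope.
#' @return The preprocessed cohort, with `norm_state`, `true_n` and
#'   `padded_to` fields set and `sample_rate_hz` updated.
#' @export
preprocess_cohort <- function(cohort, target_rate_hz = 100,
                              norm_scope = "all_subjects", train_ids = NULL) {
  cohort$recordings <- lapply(cohort$recordings, function(r)
    lapply(r, fft_resample, target_rate_hz = target_rate_hz))
  cohort$sample_rate_hz <- target_rate_hz
  state <- fit_normalization(cohort, norm_scope, train_ids)
  cohort$recordings <- lapply(cohort$recordings, function(r)
    lapply(r, apply_normalization, state = state))
  cohort$norm_state <- state
  zero_pad(cohort)
}
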