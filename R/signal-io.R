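# Reading and writing of sensor recordings (CSV) and cohort metadata (TSV).

SIGNAL_COLUMNS <- c("t_s", "accel_ap_g", "accel_ml_g", "accel_si_g",
                    "gyro_roll_dps", "gyro_pitch_dps", "gyro_yaw_dps")

#' Construct a sensor recording
#'
#' A `sensor_recording` holds one subject x one sensor location: a
#' uniformly sampled 6-channel kinematic time series, acceleration in G
#' (AP, ML, SI) and angular velocity in degree/s (roll, pitch, yaw).
#'
#' @param subject_id,location Identifiers; `location` is one of
#'   `"neck"`, `"right_foot"`, `"left_foot"`.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param accel,gyro Numeric matrices with 3 columns and identical row
#'   counts.
#' @return An object of class `sensor_recording`.
#' @export
sensor_recording <- function(subject_id, location, sample_rate_hz, accel, gyro) {
  if (!location %in% SENSOR_LOCATIONS)
    stopf("unknown sensor location '%s'", location)
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  if (nrow(accel) != nrow(gyro) || ncol(accel) != 3 || ncol(gyro) != 3)
    stopf("accel and gyro must be n x 3 matrices with identical n")
  structure(list(subject_id = subject_id, location = location,
                 sample_rate_hz = sample_rate_hz,
                 accel = accel, gyro = gyro),
            class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("sensor_recording %s/%s: %d samples @ %g Hz (%.2f s)\n",
              x$subject_id, x$location, n_samples(x), x$sample_rate_hz,
              duration_s(x)))
  invisible(x)
}

#' Number of samples / duration of a recording
#' @param rec A `sensor_recording`.
#' @return Integer sample count, or duration in seconds.
#' @export
n_samples <- function(rec) nrow(rec$accel)

#' @rdname n_samples
#' @export
duration_s <- function(rec) n_samples(rec) / rec$sample_rate_hz

#' Write a sensor recording to CSV
#'
#' Columns: `t_s, accel_ap_g, accel_ml_g, accel_si_g, gyro_roll_dps,
#' gyro_pitch_dps, gyro_yaw_dps`; time starts at 0.
#'
#' @param rec A `sensor_recording`.
#' @param path Output file path.
#' @export
write_recording <- function(rec, path) {
  n <- n_samples(rec)
  dt <- data.table::data.table(
    t_s = (seq_len(n) - 1) / rec$sample_rate_hz,
    accel_ap_g = rec$accel[, 1], accel_ml_g = rec$accel[, 2],
    accel_si_g = rec$accel[, 3],
    gyro_roll_dps = rec$gyro[, 1], gyro_pitch_dps = rec$gyro[, 2],
    gyro_yaw_dps = rec$gyro[, 3])
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a sensor recording from CSV
#'
#' Channels are mapped by header name, never by position. The time column
#' is authoritative: the sample rate is inferred from the median time step
#' and the signal is not resampled at read time.
#'
#' @param path CSV file written by [write_recording()] (or equivalent).
#' @param expected_rate_hz Optional; a mismatch of the inferred rate
#'   beyond 1% is an error.
#' @param subject_id,location Identifiers to attach (default parsed from
#'   the file name `<subject>_<location>.csv` when possible).
#' @return A `sensor_recording`.
#' @export
read_recording <- function(path, expected_rate_hz = NULL,
                           subject_id = NULL, location = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  dt <- data.table::fread(path, data.table = FALSE)
  missing_cols <- setdiff(SIGNAL_COLUMNS, names(dt))
  if (length(missing_cols))
    stopf("format error in %s: missing column(s) %s", path,
          paste(missing_cols, collapse = ", "))
  t <- dt$t_s
  if (length(t) < 2) stopf("recording %s has fewer than 2 samples", path)
  steps <- diff(t)
  if (any(steps <= 0))
    stopf("time column not strictly increasing at row %d in %s",
          which(steps <= 0)[1] + 1L, path)
  med <- stats::median(steps)
  jitter <- abs(steps - med) / med
  if (any(jitter > 0.001))
    stopf("non-uniform sampling in %s: first bad index %d (dt=%.6g, median=%.6g)",
          path, which(jitter > 0.001)[1] + 1L, steps[which(jitter > 0.001)[1]], med)
  rate <- 1 / med
  if (!is.null(expected_rate_hz) &&
      abs(rate - expected_rate_hz) / expected_rate_hz > 0.01)
    stopf("sample rate %.3f Hz in %s differs from expected %.3f Hz by more than 1%%",
          rate, path, expected_rate_hz)
  base <- sub("\\.csv$", "", basename(path))
  if (is.null(location)) {
    m <- regmatches(base, regexpr("(neck|right_foot|left_foot)$", base))
    location <- if (length(m)) m else SENSOR_LOCATIONS[1]
  }
  if (is.null(subject_id))
    subject_id <- sub("_(neck|right_foot|left_foot)$", "", base)
  accel <- as.matrix(dt[, c("accel_ap_g", "accel_ml_g", "accel_si_g")])
  gyro <- as.matrix(dt[, c("gyro_roll_dps", "gyro_pitch_dps", "gyro_yaw_dps")])
  colnames(accel) <- c("ap", "ml", "si")
  colnames(gyro) <- c("roll", "pitch", "yaw")
  sensor_recording(subject_id, location, rate, accel, gyro)
}

#' Write a cohort to disk
#'
#' Writes `metadata.tsv` (one row per subject) and one CSV per
#' subject-location under `dir/signals/`.
#'
#' @param cohort A `tug_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  sig_dir <- file.path(dir, "signals")
  dir.create(sig_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(cohort$subjects, file.path(dir, "metadata.tsv"), sep = "\t")
  for (id in names(cohort$recordings))
    for (loc in names(cohort$recordings[[id]]))
      write_recording(cohort$recordings[[id]][[loc]],
                      file.path(sig_dir, sprintf("%s_%s.csv", id, loc)))
  invisible(dir)
}

#' Read a cohort from disk
#'
#' Subjects missing a required location are excluded with a warning
#' naming them; it is an error if no usable subject remains.
#'
#' @param meta_path Path to the metadata TSV (requires `subject_id` and
#'   `label` columns; labels must be 0/1).
#' @param signals_dir Directory holding `<subject>_<location>.csv` files.
#' @param locations Character vector of required sensor locations.
#' @param expected_rate_hz Passed to [read_recording()].
#' @return A `tug_cohort`.
#' @export
read_cohort <- function(meta_path, signals_dir,
                        locations = SENSOR_LOCATIONS,
                        expected_rate_hz = NULL) {
  meta <- data.table::fread(meta_path, data.table = FALSE)
  if (!all(c("subject_id", "label") %in% names(meta)))
    stopf("metadata must contain subject_id and label columns")
  if (anyDuplicated(meta$subject_id))
    stopf("duplicated subject_id in metadata: %s",
          paste(unique(meta$subject_id[duplicated(meta$subject_id)]), collapse = ", "))
  if (!all(meta$label %in% c(0L, 1L)))
    stopf("labels must be 0 (non-faller) or 1 (faller)")
  has_all <- vapply(meta$subject_id, function(id)
    all(file.exists(file.path(signals_dir, sprintf("%s_%s.csv", id, locations)))),
    logical(1))
  if (any(!has_all)) {
    excluded <- meta$subject_id[!has_all]
    warnf("excluding %d subject(s) with missing sensor file(s): %s",
          length(excluded), paste(excluded, collapse = ", "))
    meta <- meta[has_all, , drop = FALSE]
  }
  if (nrow(meta) == 0) stopf("no usable subjects (all missing required locations)")
  recordings <- lapply(meta$subject_id, function(id) {
    r <- lapply(stats::setNames(locations, locations), function(loc)
      read_recording(file.path(signals_dir, sprintf("%s_%s.csv", id, loc)),
                     expected_rate_hz, subject_id = id, location = loc))
    r
  })
  names(recordings) <- meta$subject_id
  rate <- recordings[[1]][[1]]$sample_rate_hz
  structure(list(subjects = meta, recordings = recordings, params = NULL,
                 sample_rate_hz = rate),
            class = "tug_cohort")
}
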