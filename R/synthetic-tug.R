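# Synthetic Timed-Up-and-Go (TUG) IMU cohort generator.
#
# Emulates a 250 Hz tri-axial accelerometer (+/-16 G) and gyroscope
# (+/-2000 degree/s) worn at the neck and on both feet while a subject
# stands up from a chair, walks 3 m, turns, walks back and sits down.
# Fallers (label 1) differ from non-fallers (label 0) in total duration,
# cadence, step-time variability and mediolateral sway amplitude.

PHASE_NAMES <- c("sit_to_stand", "walk_out", "turn", "walk_back", "turn_and_sit")
SENSOR_LOCATIONS <- c("neck", "right_foot", "left_foot")

#' Simulation parameters for the synthetic TUG cohort
#'
#' Defines acquisition constants (sampling rate, sensor ranges) and the
#' per-class gait effect parameters of the generator. Class names are
#' `non_faller` and `faller`; every per-class parameter is a list with
#' those two components.
#'
#' @param sample_rate_hz Sampling rate in Hz (acquisition default 250).
#' @param accel_range_g Accelerometer full scale in G; signals are clipped
#'   to `[-accel_range_g, accel_range_g]`.
#' @param gyro_range_dps Gyroscope full scale in degree/s.
#' @param walk_distance_m Walkway length in metres (3 m TUG protocol).
#' @param cadence_hz Per-class step frequency, each a `c(mean, sd)` pair
#'   in steps per second.
#' @param phase_durations_s Per-class 5 x 2 matrix (rows: sit-to-stand,
#'   walk out, turn, walk back, turn-and-sit; columns mean, sd) in seconds.
#' @param step_time_cv Per-class coefficient of variation of inter-step
#'   intervals (dimensionless).
#' @param ml_sway_gain Per-class multiplier on the mediolateral sway
#'   amplitude (dimensionless).
#' @param noise_sd Additive white sensor noise, `c(accel_g = ..., gyro_dps = ...)`.
#' @param dropout_prob Probability that a subject is missing one sensor
#'   location (default 0, i.e. complete data).
#' @param seed Master seed from which per-subject seeds are derived.
#' @param preset `"default"` uses moderately overlapping class effects;
#'   `"strong"` widens every class contrast (slower cadence, larger sway,
#'   higher step-time variability, longer phases for fallers) and lowers
#'   noise, giving a strongly separated cohort for power/sanity studies.
#'
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(sample_rate_hz = 250,
                       accel_range_g = 16,
                       gyro_range_dps = 2000,
                       walk_distance_m = 3,
                       cadence_hz = NULL,
                       phase_durations_s = NULL,
                       step_time_cv = NULL,
                       ml_sway_gain = NULL,
                       noise_sd = c(accel_g = 0.05, gyro_dps = 4),
                       dropout_prob = 0,
                       seed = 1L,
                       preset = c("default", "strong")) {
  preset <- match.arg(preset)
  phase_mat <- function(means, sds) {
    m <- cbind(mean = means, sd = sds)
    rownames(m) <- PHASE_NAMES
    m
  }
  if (preset == "default") {
    cadence_hz <- cadence_hz %||%
      list(non_faller = c(mean = 1.9, sd = 0.12), faller = c(mean = 1.45, sd = 0.18))
    phase_durations_s <- phase_durations_s %||% list(
      non_faller = phase_mat(c(1.5, 3.2, 1.5, 3.2, 2.0), c(0.3, 0.6, 0.3, 0.6, 0.4)),
      faller     = phase_mat(c(2.5, 5.0, 2.5, 5.0, 3.2), c(0.7, 1.6, 0.7, 1.6, 0.8)))
    step_time_cv <- step_time_cv %||% c(non_faller = 0.05, faller = 0.17)
    ml_sway_gain <- ml_sway_gain %||% c(non_faller = 1.0, faller = 2.0)
  } else {
    cadence_hz <- cadence_hz %||%
      list(non_faller = c(mean = 2.0, sd = 0.08), faller = c(mean = 1.2, sd = 0.1))
    phase_durations_s <- phase_durations_s %||% list(
      non_faller = phase_mat(c(1.5, 3.0, 1.5, 3.0, 2.0), c(0.2, 0.4, 0.2, 0.4, 0.3)),
      faller     = phase_mat(c(3.0, 6.0, 3.0, 6.0, 4.0), c(0.4, 0.8, 0.4, 0.8, 0.5)))
    step_time_cv <- step_time_cv %||% c(non_faller = 0.03, faller = 0.25)
    ml_sway_gain <- ml_sway_gain %||% c(non_faller = 1.0, faller = 3.0)
    if (missing(noise_sd)) noise_sd <- c(accel_g = 0.02, gyro_dps = 2)
  }
  p <- structure(list(
    sample_rate_hz = sample_rate_hz, accel_range_g = accel_range_g,
    gyro_range_dps = gyro_range_dps, walk_distance_m = walk_distance_m,
    cadence_hz = cadence_hz, phase_durations_s = phase_durations_s,
    step_time_cv = step_time_cv, ml_sway_gain = ml_sway_gain,
    noise_sd = noise_sd, dropout_prob = dropout_prob,
    seed = as.integer(seed)), class = "sim_params")
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  pos <- c(p$sample_rate_hz, p$accel_range_g, p$gyro_range_dps, p$walk_distance_m)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stopf("scale parameters must be strictly positive")
  for (cl in c("non_faller", "faller")) {
    if (p$cadence_hz[[cl]][["mean"]] <= 0)
      stopf("cadence mean for %s must be positive", cl)
    if (any(p$phase_durations_s[[cl]][, "mean"] <= 0))
      stopf("phase duration means for %s must be positive", cl)
    if (any(p$phase_durations_s[[cl]][, "sd"] < 0))
      stopf("phase duration sds must be nonnegative")
  }
  if (sum(p$phase_durations_s$faller[, "mean"]) <
      sum(p$phase_durations_s$non_faller[, "mean"]))
    stopf("faller mean total duration must be >= non-faller mean total duration")
  if (any(p$noise_sd < 0)) stopf("noise_sd must be nonnegative")
  if (p$dropout_prob < 0 || p$dropout_prob >= 1)
    stopf("dropout_prob must be in [0, 1)")
  invisible(p)
}

# Add raised-cosine impulses of half-width `width`/2 centred at `centers`
# (seconds) to signal `x` sampled at times `t`.
raised_cosine_train <- function(x, t, centers, width, amp) {
  for (c0 in centers) {
    i <- which(t >= c0 - width / 2 & t <= c0 + width / 2)
    if (length(i))
      x[i] <- x[i] + amp * 0.5 * (1 - cos(2 * pi * (t[i] - c0 + width / 2) / width))
  }
  x
}

# Draw inter-step intervals with the requested mean (1/cadence) and CV and
# return step event times filling (t0 + margin, t1 - margin).
draw_step_times <- function(t0, t1, cadence, cv, margin = 0.25) {
  mean_int <- 1 / cadence
  span <- (t1 - t0) - 2 * margin
  if (span <= mean_int) return(numeric(0))
  n_max <- ceiling(span / mean_int * 2) + 4
  ints <- stats::rnorm(n_max, mean_int, cv * mean_int)
  ints <- pmax(ints, 0.2 * mean_int)
  times <- t0 + margin + cumsum(ints)
  times[times < t1 - margin]
}

#' Simulate one subject's TUG recordings
#'
#' Generates metadata and one six-channel recording per sensor location
#' (`neck`, `right_foot`, `left_foot`). The signal is a concatenation of
#' phase templates — a biphasic pitch-rate transfer pulse for sit-to-stand,
#' cadence-frequency raised-cosine step bursts during the walk phases
#' (alternating between feet, superposed at reduced amplitude at the neck),
#' a half-sine yaw-rate lobe for each turn, and a closing sit-down pulse —
#' plus additive white noise, clipped to the sensor ranges.
#'
#' @param params A [sim_params()] object.
#' @param label 1 (faller) or 0 (non-faller).
#' @param subject_seed Integer seed; the recording is deterministic given
#'   `(params, label, subject_seed)`.
#' @param subject_id Identifier stored in the records.
#' @return A list with `subject` (one-row data.frame) and `recordings`
#'   (named list of three `sensor_recording` objects).
#' @export
simulate_subject <- function(params, label, subject_seed, subject_id = "S001") {
  validate_sim_params(params)
  if (!label %in% c(0L, 1L)) stopf("label must be 0 (non-faller) or 1 (faller)")
  cl <- if (label == 1) "faller" else "non_faller"
  with_seed(subject_seed, {
    ph <- params$phase_durations_s[[cl]]
    cad_par <- params$cadence_hz[[cl]]
    durations <- NULL
    cadence <- NULL
    for (attempt in 0:99) {
      if (attempt > 0) set.seed(as.integer(subject_seed) + attempt)
      d <- stats::rnorm(5, ph[, "mean"], ph[, "sd"])
      cad <- stats::rnorm(1, cad_par[["mean"]], cad_par[["sd"]])
      if (all(d > 0) && cad > 0.3) {
        durations <- d; cadence <- cad; break
      }
    }
    if (is.null(durations))
      stopf("could not draw positive phase durations for subject %s after 100 attempts",
            subject_id)
    names(durations) <- PHASE_NAMES
    fs <- params$sample_rate_hz
    n <- round(sum(durations) * fs)
    t <- (seq_len(n) - 1) / fs
    bounds <- cumsum(c(0, durations))
    cv <- params$step_time_cv[[cl]]
    sway <- params$ml_sway_gain[[cl]]

    # Step events over both walk phases; parity assigns steps to feet.
    steps <- c(draw_step_times(bounds[2], bounds[3], cadence, cv),
               draw_step_times(bounds[4], bounds[5], cadence, cv))
    odd <- steps[seq_along(steps) %% 2 == 1]
    even <- steps[seq_along(steps) %% 2 == 0]
    step_w <- 0.5 / cadence

    in_walk <- (t >= bounds[2] & t < bounds[3]) | (t >= bounds[4] & t < bounds[5])
    # Turn lobes: half-sine yaw rate integrating to a 180 degree turn.
    yaw_base <- numeric(n)
    turn1 <- t >= bounds[3] & t < bounds[4]
    d_turn <- durations[["turn"]]
    yaw_base[turn1] <- (90 * pi / d_turn) * sin(pi * (t[turn1] - bounds[3]) / d_turn)
    turn2_end <- bounds[5] + 0.5 * durations[["turn_and_sit"]]
    turn2 <- t >= bounds[5] & t < turn2_end
    d_turn2 <- 0.5 * durations[["turn_and_sit"]]
    yaw_base[turn2] <- (90 * pi / d_turn2) * sin(pi * (t[turn2] - bounds[5]) / d_turn2)

    # Transfer (sit-to-stand / stand-to-sit) biphasic pitch-rate pulses.
    pitch_base <- numeric(n)
    sts <- t < bounds[2]
    pitch_base[sts] <- 60 * sin(2 * pi * (t[sts] - bounds[1]) / durations[["sit_to_stand"]])
    std <- t >= turn2_end
    d_sit <- sum(durations) - (turn2_end - 0)
    if (d_sit > 0)
      pitch_base[std] <- -60 * sin(2 * pi * (t[std] - turn2_end) / d_sit)
    # SI transient accompanying the transfers.
    si_trans <- numeric(n)
    si_trans[sts] <- 0.35 * sin(pi * t[sts] / durations[["sit_to_stand"]])
    if (d_sit > 0) si_trans[std] <- -0.3 * sin(pi * (t[std] - turn2_end) / d_sit)

    sway_sig <- numeric(n)
    sway_sig[in_walk] <- sin(2 * pi * (cadence / 2) * t[in_walk])
    ap_sig <- numeric(n)
    ap_sig[in_walk] <- sin(2 * pi * 2 * cadence * t[in_walk])

    make_channels <- function(location) {
      if (location == "neck") {
        own <- steps; amp_step <- 0.5; amp_pitch_step <- 40
        sway_amp <- 0.25 * sway; yaw_gain <- 1; trans_gain <- 1
      } else {
        own <- if (location == "right_foot") even else odd
        amp_step <- 1.2; amp_pitch_step <- 160
        sway_amp <- 0.12 * sway; yaw_gain <- 0.8; trans_gain <- 0.4
      }
      si <- raised_cosine_train(si_trans * trans_gain, t, own, step_w, amp_step)
      ap <- 0.4 * ap_sig + raised_cosine_train(numeric(n), t, own, step_w, 0.3 * amp_step)
      ml <- sway_amp * sway_sig
      pitch <- raised_cosine_train(pitch_base * trans_gain, t, own, step_w, amp_pitch_step)
      roll <- 20 * sway * sway_sig * (if (location == "neck") 1 else 0.5)
      yaw <- yaw_gain * yaw_base
      ns <- params$noise_sd
      accel <- cbind(ap = ap, ml = ml, si = si) +
        matrix(stats::rnorm(3 * n, 0, ns[["accel_g"]]), n, 3)
      gyro <- cbind(roll = roll, pitch = pitch, yaw = yaw) +
        matrix(stats::rnorm(3 * n, 0, ns[["gyro_dps"]]), n, 3)
      colnames(accel) <- c("ap", "ml", "si")
      colnames(gyro) <- c("roll", "pitch", "yaw")
      accel[] <- pmin(pmax(accel, -params$accel_range_g), params$accel_range_g)
      gyro[] <- pmin(pmax(gyro, -params$gyro_range_dps), params$gyro_range_dps)
      sensor_recording(subject_id, location, fs, accel, gyro)
    }
    recordings <- lapply(stats::setNames(SENSOR_LOCATIONS, SENSOR_LOCATIONS),
                         make_channels)

    # Clinical scores and demographics drawn with class-dependent shifts.
    if (label == 1) {
      four_stage <- min(40, max(4, stats::rnorm(1, 26, 5)))
      chair <- max(0, round(stats::rnorm(1, 7, 2)))
      p_fell <- 0.4
      age <- min(96, max(65, round(stats::rnorm(1, 78, 7))))
    } else {
      four_stage <- min(40, max(4, stats::rnorm(1, 35, 3)))
      chair <- max(0, round(stats::rnorm(1, 12, 2.5)))
      p_fell <- 0.15
      age <- min(96, max(65, round(stats::rnorm(1, 73, 6))))
    }
    followup <- if (stats::runif(1) < 0.11) NA_integer_ else
      stats::rbinom(1, 1, p_fell)
    sex <- sample(c("F", "M"), 1)
    subject <- data.frame(
      subject_id = subject_id, label = as.integer(label),
      tug_time_s = n / fs, four_stage_s = round(four_stage, 1),
      chair_stands = as.integer(chair), followup_fall = followup,
      age_years = age, sex = sex,
      height_cm = round(stats::rnorm(1, if (sex == "F") 162 else 176, 7), 1),
      mass_kg = round(stats::rnorm(1, 78, 14), 1),
      stringsAsFactors = FALSE)
    list(subject = subject, recordings = recordings)
  })
}

#' Simulate a labeled TUG cohort
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param faller_fraction Fraction of fallers in (0, 1); the cohort has
#'   exactly `round(n_subjects * faller_fraction)` fallers.
#' @param params A [sim_params()] object; `params$seed` drives all
#'   randomness (per-subject seeds are derived from it).
#' @return A `tug_cohort`: list with `subjects` (metadata data.frame),
#'   `recordings` (per subject, named list of locations) and `params`.
#' @export
simulate_cohort <- function(n_subjects, faller_fraction, params = sim_params()) {
  if (!is_count(n_subjects) || n_subjects < 2)
    stopf("n_subjects must be an integer >= 2")
  if (faller_fraction <= 0 || faller_fraction >= 1)
    stopf("faller_fraction must be in (0, 1)")
  n_fallers <- round(n_subjects * faller_fraction)
  if (n_fallers == 0 || n_fallers == n_subjects)
    stopf("rounding produced an empty class (n=%d, fraction=%.3f)",
          n_subjects, faller_fraction)
  labels <- c(rep(1L, n_fallers), rep(0L, n_subjects - n_fallers))
  ids <- sprintf("S%03d", seq_len(n_subjects))
  draws <- with_seed(params$seed, list(
    seeds = sample.int(.Machine$integer.max - 1L, n_subjects),
    drop_loc = ifelse(stats::runif(n_subjects) < params$dropout_prob,
                      sample(SENSOR_LOCATIONS, n_subjects, replace = TRUE),
                      NA_character_)))
  subjects <- vector("list", n_subjects)
  recordings <- vector("list", n_subjects)
  names(recordings) <- ids
  for (i in seq_len(n_subjects)) {
    s <- simulate_subject(params, labels[i], draws$seeds[i], ids[i])
    if (!is.na(draws$drop_loc[i]))
      s$recordings[[draws$drop_loc[i]]] <- NULL
    subjects[[i]] <- s$subject
    recordings[[i]] <- s$recordings
  }
  structure(list(subjects = do.call(rbind, subjects),
                 recordings = recordings, params = params,
                 sample_rate_hz = params$sample_rate_hz),
            class = "tug_cohort")
}

#' @export
print.tug_cohort <- function(x, ...) {
  cat(sprintf("TUG cohort: %d subjects (%d fallers, %d non-fallers), %g Hz\n",
              nrow(x$subjects), sum(x$subjects$label == 1),
              sum(x$subjects$label == 0), x$sample_rate_hz))
  invisible(x)
}
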