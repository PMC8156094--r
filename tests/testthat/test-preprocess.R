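test_that("resampling 250 -> 100 Hz scales the length by the rate ratio", {
  rec <- sensor_recording("S1", "neck", 250, matrix(rnorm(2500 * 3), 2500, 3),
                          matrix(rnorm(2500 * 3), 2500, 3))
  out <- fft_resample(rec, 100)
  expect_equal(n_samples(out), 1000)
  expect_equal(out$sample_rate_hz, 100)
  expect_error(fft_resample(out, 100), "below")
})

test_that("resampling preserves DC exactly and band-limited content accurately", {
  n <- 2500; fs <- 250
  t <- (seq_len(n) - 1) / fs
  const <- rep(0.37, n)
  expect_equal(fourier_resample(const, 1000), rep(0.37, 1000), tolerance = 1e-9)
  # 10 Hz unit sine survives with amplitude within 1% (amplitude taken
  # as RMS * sqrt(2): the coarser sample grid misses the analytic peak)
  s10 <- sin(2 * pi * 10 * t)
  r10 <- fourier_resample(s10, 1000)
  expect_equal(sqrt(2 * mean(r10^2)), 1, tolerance = 0.01)
  # 80 Hz sine is above the new 50 Hz Nyquist: wiped out
  s80 <- sin(2 * pi * 80 * t)
  r80 <- fourier_resample(s80, 1000)
  expect_lt(sqrt(mean(r80^2)) / sqrt(mean(s80^2)), 0.01)
})

test_that("energy of sub-Nyquist content is preserved within 1% (Parseval)", {
  set.seed(31)
  fs <- 250; n <- 2000
  t <- (seq_len(n) - 1) / fs
  for (i in 1:5) {
    freqs <- runif(6, 0.5, 45)   # strictly below the new 50 Hz Nyquist
    amps <- runif(6, 0.2, 1)
    x <- as.numeric(cos(2 * pi * outer(t, freqs)) %*% amps)
    y <- fourier_resample(x, n * 100 / fs)
    expect_equal(mean(y^2), mean(x^2), tolerance = 0.01)
  }
})

test_that("normalization extremes come from the whole in-scope cohort", {
  mk <- function(id, lo, hi) {
    m <- matrix(seq(lo, hi, length.out = 30), 10, 3)
    list(neck = sensor_recording(id, "neck", 100, m, m * 10))
  }
  co <- structure(list(
    subjects = data.frame(subject_id = c("A", "B"), label = c(0L, 1L)),
    recordings = list(A = mk("A", -2, 3), B = mk("B", -1, 5)),
    sample_rate_hz = 100), class = "tug_cohort")
  st <- fit_normalization(co)
  expect_equal(st$accel_min, -2)
  expect_equal(st$accel_max, 5)
  expect_equal(st$gyro_min, -20)
  expect_equal(st$gyro_max, 50)
  # train-only scope ignores the excluded subject's extremes
  st_tr <- fit_normalization(co, "train_only", train_ids = "A")
  expect_equal(st_tr$accel_max, 3)
  # applying maps min -> 0, max -> 1, midpoint -> 0.5
  na <- apply_normalization(co$recordings$A$neck, st)
  expect_equal(min(na$accel), 0)
  expect_equal(na$accel[1, 1], 0)
  mid <- apply_normalization(
    sensor_recording("m", "neck", 100, matrix(1.5, 2, 3), matrix(15, 2, 3)), st)
  expect_equal(unname(mid$accel[1, 1]), 0.5)
  # out-of-scope values above the fitted max exceed 1 and warn, unclipped
  expect_warning(nb <- apply_normalization(co$recordings$B$neck, st_tr),
                 "outside")
  expect_gt(max(nb$accel), 1)
})

test_that("normalized cohort attains 0 and 1 exactly per modality", {
  cp <- fast_cohort(6, seed = 9L)
  acc <- unlist(lapply(cp$recordings, function(r) lapply(r, function(x)
    x$accel[seq_len(cp$true_n[[x$subject_id]]), ])))
  gyr <- unlist(lapply(cp$recordings, function(r) lapply(r, function(x)
    x$gyro[seq_len(cp$true_n[[x$subject_id]]), ])))
  expect_equal(min(acc), 0)
  expect_equal(max(acc), 1)
  expect_equal(min(gyr), 0)
  expect_equal(max(gyr), 1)
})

test_that("zero padding appends zeros only and round-trips by truncation", {
  co <- fast_cohort(4, seed = 12L, preprocessed = FALSE)
  res <- co
  res$recordings <- lapply(res$recordings, function(r) lapply(r, fft_resample))
  res$sample_rate_hz <- 100
  before <- res$recordings
  padded <- zero_pad(res)
  l_max <- padded$padded_to
  for (id in names(padded$recordings)) {
    tn <- padded$true_n[[id]]
    rec <- padded$recordings[[id]]$neck
    expect_equal(n_samples(rec), l_max)
    if (tn < l_max)
      expect_true(all(rec$accel[(tn + 1):l_max, ] == 0))
    expect_equal(rec$accel[seq_len(tn), ], before[[id]]$neck$accel,
                 tolerance = 1e-12)
  }
  # already-equal lengths pass through unchanged
  again <- zero_pad(padded)
  expect_identical(again$recordings, padded$recordings)
})
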