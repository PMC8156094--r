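test_that("stratified split preserves class proportions with round-half-up", {
  subj <- data.frame(subject_id = sprintf("S%03d", 1:100),
                     label = rep(c(1L, 0L), each = 50))
  sp <- stratified_split(subj, 0.2, seed = 5)
  expect_length(sp$test, 20)
  expect_length(sp$train, 80)
  lab <- setNames(subj$label, subj$subject_id)
  expect_equal(sum(lab[sp$test] == 1), 10)
  expect_length(intersect(sp$train, sp$test), 0)
  # 53 fallers / 45 non-fallers: test gets round(10.6) = 11 and round(9) = 9
  subj2 <- data.frame(subject_id = sprintf("P%03d", 1:98),
                      label = rep(c(1L, 0L), c(53, 45)))
  sp2 <- stratified_split(subj2, 0.2, seed = 5)
  lab2 <- setNames(subj2$label, subj2$subject_id)
  expect_equal(sum(lab2[sp2$test] == 1), 11)
  expect_equal(sum(lab2[sp2$test] == 0), 9)
  expect_error(stratified_split(data.frame(subject_id = c("a", "b"),
                                           label = c(1L, 0L)), 0.2),
               "too small")
})

test_that("bootstrap multiset has the prescribed size and uniform multiplicities", {
  ids <- letters[1:10]
  set.seed(11)
  ms <- bootstrap_resample(ids, 100)
  expect_length(ms, 1000)
  expect_true(all(ms %in% ids))
  counts <- table(factor(ms, levels = ids))
  # multiplicities ~ Binomial(1000, 1/10): chi-square GOF should not reject
  expect_gt(chisq.test(counts)$p.value, 0.01)
  set.seed(12)
  expect_equal(bootstrap_resample("solo", 1), "solo")
})

test_that("SVM bagging recovers strong synthetic class structure", {
  co <- simulate_cohort(24, 0.5, sim_params(seed = 31, preset = "strong"))
  cp <- preprocess_cohort(co)
  ms <- run_bagging(cp, "svm", "gyro", "neck",
                    bagging_config(n_iterations = 8, resample_factor = 5,
                                   master_seed = 41))
  auc <- ms$summary$mean[ms$summary$metric == "auc"]
  expect_gt(auc, 0.8)
  # percentile CI brackets the mean for every metric
  expect_true(all(ms$summary$ci_low <= ms$summary$mean + 1e-12))
  expect_true(all(ms$summary$ci_high >= ms$summary$mean - 1e-12))
  # per-iteration table retained with one row per iteration
  expect_equal(nrow(ms$iterations), 8)
  # reruns are identical (seeded protocol)
  ms2 <- run_bagging(cp, "svm", "gyro", "neck",
                     bagging_config(n_iterations = 8, resample_factor = 5,
                                    master_seed = 41))
  expect_equal(ms$iterations, ms2$iterations)
})

test_that("a single iteration degenerates the CI to the point value", {
  co <- simulate_cohort(12, 0.5, fast_params(33L))
  cp <- preprocess_cohort(co)
  ms <- run_bagging(cp, "svm", "accel", "neck",
                    bagging_config(n_iterations = 1, resample_factor = 3,
                                   master_seed = 7))
  expect_equal(ms$summary$ci_low, ms$summary$mean)
  expect_equal(ms$summary$ci_high, ms$summary$mean)
})

test_that("subject-level evaluation aggregates window probabilities", {
  co <- simulate_cohort(16, 0.5, sim_params(seed = 35, preset = "strong"))
  cp <- preprocess_cohort(co)
  ms <- run_bagging(cp, "svm", "gyro", "neck",
                    bagging_config(n_iterations = 4, resample_factor = 5,
                                   master_seed = 43, eval_level = "subject"))
  expect_equal(nrow(ms$iterations), 4)
  expect_true(all(ms$iterations$acc >= 0 & ms$iterations$acc <= 1))
})

test_that("traditional TUG bootstrap: sizes, perfect separation, and null", {
  subj <- data.frame(subject_id = sprintf("S%02d", 1:30),
                     label = rep(c(1L, 0L), c(15, 15)),
                     tug_time_s = c(rnorm(15, 20, 1), rnorm(15, 10, 1)))
  ms <- tug_reference_bootstrap(subj, cutoff_s = 14, n_iterations = 5,
                                master_seed = 3)
  # every faller above, every non-faller below the cutoff: Se = Sp = 1
  expect_true(all(ms$iterations$se == 1))
  expect_true(all(ms$iterations$sp == 1))
  # the test multiset is exactly 2000 (100 x 20) draws per iteration
  expect_true(all(ms$iterations$n_test == 2000))
  # label-independent times: AUC CI contains 0.5
  set.seed(51)
  subj_null <- transform(subj, tug_time_s = rnorm(30, 14, 3))
  msn <- tug_reference_bootstrap(subj_null, n_iterations = 30,
                                 master_seed = 9)
  a <- msn$summary[msn$summary$metric == "auc", ]
  expect_lte(a$ci_low, 0.5)
  expect_gte(a$ci_high, 0.5)
  expect_error(tug_reference_bootstrap(subj[1:12, ]), "at least 10")
})
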