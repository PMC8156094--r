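test_that("confusion matrix counts and identities hold", {
  pred <- c(rep(1, 5), rep(0, 5))
  cm <- confusion(pred, pred)
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(5, 0, 0, 5))
  cm2 <- confusion(pred, 1 - pred)
  expect_equal(c(cm2$tp, cm2$tn), c(0, 0))
  expect_error(confusion(integer(0), integer(0)), "empty")
  # follow-up fall report: 25 true fallers, 62 true non-fallers, 28 FP, 6 FN
  cm3 <- confusion_matrix(tp = 25 - 6, fp = 28, fn = 6, tn = 62 - 28)
  expect_equal(cm3$tp, 19)
  expect_equal(cm3$tn, 34)
})

test_that("screening metrics reproduce worked clinical examples", {
  # geriatrician prediction of follow-up falls; exact fractions first
  m <- basic_metrics(confusion_matrix(19, 28, 6, 34))
  expect_equal(unname(m["acc"]), 53 / 87)
  expect_equal(unname(m["se"]), 19 / 25)
  expect_equal(unname(m["sp"]), 34 / 62)
  expect_equal(unname(m["f1"]), 38 / 72)
  expect_equal(round(unname(m["acc"]), 3), 0.609)
  expect_equal(round(unname(m["f1"]), 2), 0.53)
  # TUG >= 14 s rule on a 54-faller / 46-non-faller cohort
  m2 <- basic_metrics(confusion_matrix(30, 5, 24, 41))
  expect_equal(unname(m2["acc"]), 0.71)
  expect_equal(unname(m2["se"]), 30 / 54)
  expect_equal(unname(m2["sp"]), 41 / 46)
  expect_equal(round(unname(m2["j"]), 2), 0.45)
  # perfect classifier
  mp <- basic_metrics(confusion_matrix(10, 0, 0, 10))
  expect_equal(unname(mp), c(1, 1, 1, 1, 1))
  # zero denominator -> NA sentinel, never 0
  expect_true(is.na(basic_metrics(confusion_matrix(0, 0, 0, 5))["se"]))
})

test_that("metric identities hold for random confusion matrices (property)", {
  set.seed(61)
  for (i in 1:30) {
    cts <- rmultinom(1, sample(10:200, 1), rep(0.25, 4))[, 1]
    if (sum(cts[c(1, 3)]) == 0 || sum(cts[c(2, 4)]) == 0) next
    cm <- confusion_matrix(cts[1], cts[2], cts[3], cts[4])
    m <- basic_metrics(cm)
    n <- sum(cts)
    expect_equal(m[["acc"]] * n, cm$tp + cm$tn)
    expect_equal(m[["j"]], m[["se"]] + m[["sp"]] - 1)
  }
})

test_that("AUC equals brute-force pair counting, with ties as 1/2", {
  scores <- c(0.9, 0.8, 0.85, 0.1)
  labels <- c(1, 1, 0, 0)
  expect_equal(roc_auc(scores, labels), 0.75)   # 3 of 4 pairs concordant
  expect_equal(roc_auc(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(1, 6), rep(c(0, 1), 3)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
  brute <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(71)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(n, y), sample(c(0, 1, 8), 1))  # induce ties sometimes
    expect_equal(roc_auc(s, y), brute(s, y))
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(73)
  y <- rbinom(100, 1, 0.4)
  s <- rnorm(100, y)
  a <- roc_auc(s, y)
  expect_equal(roc_auc(exp(s), y), a)
  expect_equal(roc_auc(qlogis(plogis(s)), y), a)
  expect_equal(roc_auc(rank(s), y), a)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(79)
  for (i in 1:5) {
    y <- rbinom(60, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- rnorm(60, y * runif(1, 0, 2))
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(s, y), ref)
  }
})

test_that("C-statistic inference behaves at the null and under separation", {
  null <- c_statistic_test(rep(c(1, 1), 10), rep(c(0, 1), 10))
  expect_equal(null$auc, 0.5)
  expect_equal(null$z, 0)
  expect_equal(null$p_one_sided, 0.5)
  set.seed(83)
  y <- rep(c(0, 1), each = 100)
  s <- rnorm(200, 3 * y)
  big <- c_statistic_test(s, y)
  expect_lt(big$p_one_sided, 0.001)
  expect_true(big$ci_low <= big$auc && big$auc <= big$ci_high)
  # Hanley-McNeil SE within 20% of a bootstrap SE at n = 50 + 50
  y2 <- rep(c(0, 1), each = 50)
  s2 <- rnorm(100, 0.8 * y2)
  hm <- c_statistic_test(s2, y2)$se
  boot <- replicate(400, {
    i <- sample(100, replace = TRUE)
    if (length(unique(y2[i])) < 2) NA else roc_auc(s2[i], y2[i])
  })
  expect_equal(hm, sd(boot, na.rm = TRUE), tolerance = 0.2)
})

test_that("dichotomization honours direction and inclusive boundaries", {
  tug <- cutoff_rule("tug_time_s", 14, "high_is_faller")
  expect_equal(dichotomize(c(13.9, 14, 14.1), tug), c(0L, 1L, 1L))
  stand <- cutoff_rule("chair_stands", 8, "low_is_faller")
  expect_equal(dichotomize(c(8, 9), stand), c(1L, 0L))
  all_faller <- cutoff_rule("x", -Inf, "high_is_faller")
  expect_equal(dichotomize(rnorm(5), all_faller), rep(1L, 5))
})

test_that("Youden-optimal cutoff matches exhaustive search", {
  # perfectly separable toy: cutoff 20 gives J = 1
  v <- c(20, 30, 10, 12); y <- c(1, 1, 0, 0)
  opt <- youden_optimal_cutoff(v, y, "high_is_faller")
  expect_equal(opt$cutoff, 20)
  expect_equal(opt$j_max, 1)
  set.seed(89)
  for (i in 1:10) {
    vv <- round(rnorm(40), 1)
    yy <- rbinom(40, 1, 0.5)
    if (length(unique(yy)) < 2) next
    opt <- youden_optimal_cutoff(vv, yy, "high_is_faller")
    brute <- max(vapply(sort(unique(vv)), function(cut)
      basic_metrics(confusion(as.integer(vv >= cut), yy))[["j"]],
      numeric(1)))
    expect_equal(opt$j_max, brute)
  }
  # labels independent of values: J_max stays small at n = 200
  set.seed(97)
  v0 <- rnorm(200); y0 <- rbinom(200, 1, 0.5)
  expect_lte(youden_optimal_cutoff(v0, y0, "high_is_faller")$j_max, 0.3)
})

test_that("odds ratios reproduce the reconstructed clinical 2x2 tables", {
  tug <- odds_ratio_2x2(c(30, 5, 24, 41))
  expect_equal(tug$or, 10.25, tolerance = 1e-6)
  expect_equal(tug$ci_low, 3.51, tolerance = 0.01)
  expect_equal(tug$ci_high, 29.96, tolerance = 0.01)
  stand <- odds_ratio_2x2(c(27, 3, 27, 43))
  expect_equal(stand$or, 14.33, tolerance = 1e-2)
  expect_equal(stand$ci_low, 3.96, tolerance = 0.01)
  expect_equal(stand$ci_high, 51.87, tolerance = 0.01)
})

test_that("odds ratio symmetry, independence and zero-cell handling", {
  o <- odds_ratio_2x2(c(12, 4, 4, 12))
  expect_equal(o$or, (12 / 4)^2)
  swap <- odds_ratio_2x2(c(4, 12, 12, 4))
  expect_equal(swap$or, 1 / o$or)
  # proportional rows: OR exactly 1
  expect_equal(odds_ratio_2x2(c(10, 20, 5, 10))$or, 1)
  # one zero cell: Haldane-Anscombe correction, flagged
  z <- odds_ratio_2x2(c(10, 0, 5, 10))
  expect_true(z$corrected)
  expect_true(is.finite(z$or))
  # two zero cells in a line: undefined sentinel
  expect_true(is.na(odds_ratio_2x2(c(0, 0, 5, 10))$or))
})
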