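# Bootstrap-bagging evaluation protocol: stratified 80/20 subject split,
# B bootstrap iterations resampling each set with replacement at
# `resample_factor` times its size, per-iteration train/evaluate, and
# mean with percentile 95% CI aggregation across iterations. Also the
# training-free traditional-TUG bootstrap comparator.

#' Bagging protocol configuration
#'
#' @param n_iterations Bootstrap iterations (study protocol: 100).
#' @param test_fraction Held-out subject fraction (0.2).
#' @param resample_factor Each set is resampled with replacement to
#'   `resample_factor` times its subject count (study protocol: 100).
#' @param master_seed Seed; iteration i uses `master_seed + i`, so
#'   results are independent of execution order.
#' @param eval_level `"segment"` (metrics over test windows) or
#'   `"subject"` (mean window probability per subject, then threshold).
#' @param resplit_each_iter Redraw the 80/20 split every iteration
#'   instead of splitting once (default FALSE).
#' @return A `bagging_config`.
#' @export
bagging_config <- function(n_iterations = 100L, test_fraction = 0.2,
                           resample_factor = 100L, master_seed = 1L,
                           eval_level = c("segment", "subject"),
                           resplit_each_iter = FALSE) {
  if (n_iterations < 1) stopf("n_iterations must be >= 1")
  if (test_fraction <= 0 || test_fraction >= 1)
    stopf("test_fraction must be in (0, 1)")
  if (resample_factor < 1) stopf("resample_factor must be >= 1")
  structure(list(n_iterations = as.integer(n_iterations),
                 test_fraction = test_fraction,
                 resample_factor = as.integer(resample_factor),
                 master_seed = as.integer(master_seed),
                 eval_level = match.arg(eval_level),
                 resplit_each_iter = isTRUE(resplit_each_iter)),
            class = "bagging_config")
}

#' Stratified subject-level train/test split
#'
#' Each class is split independently so both sets preserve the cohort's
#' class proportions; the per-class test count is round-half-up of
#' `test_fraction * n_class`. The split is at subject level: no subject
#' appears in both sets.
#'
#' @param subjects Data frame with `subject_id` and `label` columns.
#' @param test_fraction Held-out fraction.
#' @param seed RNG seed for the draw.
#' @return List with character vectors `train` and `test`.
#' @export
stratified_split <- function(subjects, test_fraction = 0.2, seed = 1L) {
  with_seed(seed, {
    train <- character(0); test <- character(0)
    for (cl in c(1L, 0L)) {
      ids <- subjects$subject_id[subjects$label == cl]
      n_test <- floor(test_fraction * length(ids) + 0.5)   # round half up
      if (n_test < 1 || length(ids) - n_test < 1)
        stopf("class %d too small (%d subjects) to populate both sets",
              cl, length(ids))
      t_ids <- sample(ids, n_test)
      test <- c(test, t_ids)
      train <- c(train, setdiff(ids, t_ids))
    }
    list(train = train, test = test)
  })
}

#' Bootstrap-resample a subject set
#'
#' Uniform sampling with replacement to `factor * length(ids)` draws.
#' The returned multiset — not the unique set — defines the data fed to
#' training or evaluation: a subject drawn k times contributes its
#' windows (or feature row) k times. Uses the current RNG stream.
#'
#' @param ids Character vector of subject ids.
#' @param factor Resampling factor.
#' @return Character vector of `factor * length(ids)` draws.
#' @export
bootstrap_resample <- function(ids, factor = 100L) {
  if (length(ids) == 0) stopf("empty subject set")
  sample(ids, factor * length(ids), replace = TRUE)
}

# Aggregate a per-iteration metric table into mean + percentile 95% CI,
# plus the across-iteration C-statistic inference on the AUC.
summarize_iterations <- function(iters) {
  metrics <- c("acc", "se", "sp", "j", "f1", "auc")
  tab <- do.call(rbind, lapply(metrics, function(m) {
    v <- iters[[m]]
    data.frame(metric = m, mean = mean(v, na.rm = TRUE),
               ci_low = unname(stats::quantile(v, 0.025, na.rm = TRUE)),
               ci_high = unname(stats::quantile(v, 0.975, na.rm = TRUE)))
  }))
  aucs <- iters$auc[!is.na(iters$auc)]
  se_mean <- stats::sd(aucs) / sqrt(length(aucs))
  z <- if (length(aucs) < 2 || se_mean == 0) {
    if (mean(aucs) == 0.5) 0 else sign(mean(aucs) - 0.5) * Inf
  } else (mean(aucs) - 0.5) / se_mean
  structure(list(
    summary = tab, iterations = iters,
    c_statistic = list(z = z,
                       ci_low = mean(aucs) - 1.96 * se_mean,
                       ci_high = mean(aucs) + 1.96 * se_mean,
                       p_one_sided = stats::pnorm(z, lower.tail = FALSE))),
    class = "metric_summary")
}

#' @export
print.metric_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf("bagging summary over %d iterations:\n", nrow(x$iterations)))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-4s %.3f (%.3f, %.3f)\n", toupper(s$metric[i]),
                s$mean[i], s$ci_low[i], s$ci_high[i]))
  cat(sprintf("  C-statistic z = %.2f, AUC CI (%.3f, %.3f), p = %.3g\n",
              x$c_statistic$z, x$c_statistic$ci_low, x$c_statistic$ci_high,
              x$c_statistic$p_one_sided))
  invisible(x)
}

eval_metrics <- function(p, y, eval_level, subj = NULL) {
  if (eval_level == "subject") {
    agg <- tapply(p, subj, mean)
    y <- as.integer(tapply(y, subj, function(v) v[1]))
    p <- as.numeric(agg)
  }
  cm <- confusion(classify(p), y)
  m <- basic_metrics(cm)
  auc <- if (length(unique(y)) == 2) roc_auc(p, y) else NA_real_
  c(m, auc = auc)
}

#' Run the bootstrap-bagging evaluation of a classifier
#'
#' Per iteration: bootstrap-resample the train and test subject sets,
#' assemble the (multiset) windows or feature rows, fit the model on the
#' training multiset, predict on the test multiset, and compute
#' Acc/Se/Sp/J/F1 at threshold 0.5 plus the AUC. Aggregates means and
#' percentile 95% CIs across iterations. Iterations whose test multiset
#' contains one class are redrawn (at most 10 times, logged).
#'
#' @param cohort A preprocessed `tug_cohort`.
#' @param model_kind `"cnn"` or `"svm"`.
#' @param modality `"gyro"` or `"accel"`.
#' @param location Sensor location.
#' @param config A [bagging_config()].
#' @param model_config A [cnn_config()] for the CNN (ignored for SVM).
#' @param window_s,stride_s Segmentation parameters (CNN only).
#' @return A `metric_summary`; `$iterations` holds the per-iteration
#'   table and the subject split(s).
#' @export
run_bagging <- function(cohort, model_kind = c("cnn", "svm"),
                        modality = c("gyro", "accel"),
                        location = SENSOR_LOCATIONS,
                        config = bagging_config(),
                        model_config = cnn_config(),
                        window_s = 3, stride_s = 1) {
  model_kind <- match.arg(model_kind)
  modality <- match.arg(modality)
  location <- match.arg(location)
  stopifnot(inherits(config, "bagging_config"))

  if (model_kind == "cnn") {
    segset <- segment_cohort(cohort, modality, location, window_s, stride_s)
    rows_of <- split(seq_along(segset$subject_id), segset$subject_id)
    label_of <- tapply(segset$label, segset$subject_id, function(v) v[1])
  } else {
    feats <- cohort_features(cohort, modality, location)
    fmat <- as.matrix(feats[, setdiff(names(feats), c("subject_id", "label"))])
    rows_of <- split(seq_len(nrow(feats)), feats$subject_id)
    label_of <- stats::setNames(feats$label, feats$subject_id)
  }
  usable <- cohort$subjects[cohort$subjects$subject_id %in% names(rows_of), ]
  split0 <- if (!config$resplit_each_iter)
    stratified_split(usable, config$test_fraction, config$master_seed) else NULL

  iters <- vector("list", config$n_iterations)
  for (it in seq_len(config$n_iterations)) {
    iter_seed <- config$master_seed + it
    sp <- if (config$resplit_each_iter)
      stratified_split(usable, config$test_fraction, iter_seed * 2L + 1L)
    else split0
    stopifnot(length(intersect(sp$train, sp$test)) == 0)  # leakage guard
    res <- with_seed(iter_seed, {
      train_ms <- NULL; test_ms <- NULL
      for (redraw in 0:10) {
        train_ms <- bootstrap_resample(sp$train, config$resample_factor)
        test_ms <- bootstrap_resample(sp$test, config$resample_factor)
        if (length(unique(label_of[test_ms])) == 2 &&
            length(unique(label_of[train_ms])) == 2) break
        if (redraw == 10) stopf("test multiset single-class after 10 redraws")
        message(sprintf("iteration %d: single-class multiset, redrawing", it))
      }
      list(train_ms = train_ms, test_ms = test_ms)
    })
    if (model_kind == "cnn") {
      train_idx <- unlist(rows_of[res$train_ms], use.names = FALSE)
      mc <- model_config
      mc$seed <- as.integer((model_config$seed + it) %% .Machine$integer.max)
      fit <- train_classifier(segset$x, segset$label, mc, index = train_idx)
      test_unique <- unique(res$test_ms)
      p_unique <- lapply(stats::setNames(test_unique, test_unique), function(id)
        predict_fall_probability(fit, segset$x[rows_of[[id]], , , drop = FALSE]))
      p <- unlist(p_unique[res$test_ms], use.names = FALSE)
      y <- unlist(lapply(res$test_ms, function(id)
        segset$label[rows_of[[id]]]), use.names = FALSE)
      subj <- rep(seq_along(res$test_ms),
                  vapply(res$test_ms, function(id) length(rows_of[[id]]),
                         integer(1)))
    } else {
      train_idx <- unlist(rows_of[res$train_ms], use.names = FALSE)
      fit <- fit_svm(fmat, feats$label, index = train_idx)
      test_idx <- unlist(rows_of[res$test_ms], use.names = FALSE)
      p <- predict_fall_probability(fit, fmat[test_idx, , drop = FALSE])
      y <- feats$label[test_idx]
      subj <- seq_along(test_idx)
    }
    m <- eval_metrics(p, y, config$eval_level, subj)
    iters[[it]] <- data.frame(iteration = it, t(m), n_test = length(y))
  }
  out <- summarize_iterations(do.call(rbind, iters))
  out$split <- split0
  out$model_kind <- model_kind
  out$modality <- modality
  out$location <- location
  out
}

#' Traditional-TUG bootstrap comparator
#'
#' The training-free reference: per iteration, select `n_per_class`
#' fallers and non-fallers without replacement, draw `n_draws` subjects
#' with replacement from those selected, classify each draw by
#' `tug_time_s >= cutoff_s`, and compute the screening metrics (AUC from
#' the continuous TUG time). Aggregation as in [run_bagging()].
#'
#' @param subjects Data frame with `subject_id`, `label`, `tug_time_s`.
#' @param cutoff_s TUG decision cutoff in seconds (clinical default 14).
#' @param n_iterations Bootstrap iterations (default 100).
#' @param n_per_class Subjects selected per class (default 10).
#' @param n_draws With-replacement draws forming the test multiset
#'   (default 2000, i.e. 100 x 20).
#' @param master_seed Seed.
#' @return A `metric_summary`.
#' @export
tug_reference_bootstrap <- function(subjects, cutoff_s = 14,
                                    n_iterations = 100L, n_per_class = 10L,
                                    n_draws = 2000L, master_seed = 1L) {
  if (is.null(subjects$tug_time_s)) stopf("tug_time_s column required")
  fallers <- subjects$subject_id[subjects$label == 1]
  nonfallers <- subjects$subject_id[subjects$label == 0]
  if (length(fallers) < n_per_class || length(nonfallers) < n_per_class)
    stopf("need at least %d subjects per class", n_per_class)
  tug <- stats::setNames(subjects$tug_time_s, subjects$subject_id)
  lab <- stats::setNames(subjects$label, subjects$subject_id)
  rule <- cutoff_rule("tug_time_s", cutoff_s, "high_is_faller")
  iters <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    iters[[it]] <- with_seed(master_seed + it, {
      sel <- c(sample(fallers, n_per_class), sample(nonfallers, n_per_class))
      draws <- sample(sel, n_draws, replace = TRUE)
      y <- as.integer(lab[draws])
      times <- as.numeric(tug[draws])
      cm <- confusion(dichotomize(times, rule), y)
      m <- basic_metrics(cm)
      auc <- if (length(unique(y)) == 2) roc_auc(times, y) else NA_real_
      data.frame(iteration = it, t(c(m, auc = auc)), n_test = length(y))
    })
  }
  out <- summarize_iterations(do.call(rbind, iters))
  out$model_kind <- "clinical_tug"
  out
}
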