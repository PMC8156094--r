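# End-to-end experiment orchestration: simulate (or load) a cohort,
# preprocess, segment, run the bagging evaluation for each requested
# model x modality x location, the traditional-TUG comparator, and the
# clinical-cutoff screening tables.

#' Experiment configuration
#'
#' Bundles every stage's options under one serializable object so a
#' report can be regenerated from its embedded configuration.
#'
#' @param sim A [sim_params()] object.
#' @param n_subjects,faller_fraction Cohort shape (defaults mirror a
#'   98-subject cohort with 53 fallers).
#' @param target_rate_hz,norm_scope Preprocessing options.
#' @param window_s,stride_s Segmentation options.
#' @param model_kinds,modalities,locations The grid of bagging runs.
#' @param cnn A [cnn_config()].
#' @param bagging A [bagging_config()].
#' @param clinical_rules Named list of [cutoff_rule()]s evaluated on the
#'   cohort metadata.
#' @param tug_cutoff_s Cutoff for the traditional-TUG comparator.
#' @param cache_dir Optional directory; the simulated + preprocessed
#'   cohort is cached there keyed by an md5 of the generating options,
#'   so re-running an unchanged config skips recomputation.
#' @param out_dir Optional directory for JSON/TSV report files.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(sim = sim_params(),
                              n_subjects = 98L, faller_fraction = 53 / 98,
                              target_rate_hz = 100, norm_scope = "all_subjects",
                              window_s = 3, stride_s = 1,
                              model_kinds = c("cnn", "svm"),
                              modalities = c("gyro", "accel"),
                              locations = SENSOR_LOCATIONS,
                              cnn = cnn_config(),
                              bagging = bagging_config(),
                              clinical_rules = default_clinical_rules(),
                              tug_cutoff_s = 14,
                              cache_dir = NULL, out_dir = NULL) {
  structure(list(sim = sim, n_subjects = as.integer(n_subjects),
                 faller_fraction = faller_fraction,
                 target_rate_hz = target_rate_hz, norm_scope = norm_scope,
                 window_s = window_s, stride_s = stride_s,
                 model_kinds = model_kinds, modalities = modalities,
                 locations = locations, cnn = cnn, bagging = bagging,
                 clinical_rules = clinical_rules, tug_cutoff_s = tug_cutoff_s,
                 cache_dir = cache_dir, out_dir = out_dir),
            class = "experiment_config")
}

#' Clinical screening rules of the STEADI battery
#'
#' TUG time >= 14 s, 4-stage balance <= 30 s, 30-second chair stand
#' <= 8 stands all predict "faller"; boundaries inclusive.
#'
#' @return Named list of [cutoff_rule()]s keyed by metadata column.
#' @export
default_clinical_rules <- function() {
  list(tug_time_s = cutoff_rule("tug_time_s", 14, "high_is_faller"),
       four_stage_s = cutoff_rule("four_stage_s", 30, "low_is_faller"),
       chair_stands = cutoff_rule("chair_stands", 8, "low_is_faller"))
}

#' Clinical-cutoff screening table
#'
#' For each rule: dichotomize the score, build the confusion matrix
#' against the fall-risk label, and report Acc/Se/Sp/J plus the ROC AUC
#' of the continuous score and the Youden-optimal cutoff.
#'
#' @param subjects Cohort metadata data.frame.
#' @param rules Named list of [cutoff_rule()]s (names = columns).
#' @return A data.frame, one row per rule.
#' @export
clinical_table <- function(subjects, rules = default_clinical_rules()) {
  rows <- lapply(names(rules), function(var) {
    rule <- rules[[var]]
    v <- subjects[[var]]
    keep <- !is.na(v)
    v <- v[keep]; y <- subjects$label[keep]
    m <- basic_metrics(confusion(dichotomize(v, rule), y))
    # orient scores so larger = more faller-like for the ROC sweep
    sc <- if (rule$direction == "high_is_faller") v else -v
    opt <- youden_optimal_cutoff(v, y, rule$direction)
    o <- odds_ratio_2x2(confusion(dichotomize(v, rule), y))
    data.frame(variable = var, cutoff = rule$cutoff,
               direction = rule$direction,
               acc = m[["acc"]], se = m[["se"]], sp = m[["sp"]], j = m[["j"]],
               auc = roc_auc(sc, y),
               optimal_cutoff = opt$cutoff, j_max = opt$j_max,
               odds_ratio = o$or, or_ci_low = o$ci_low, or_ci_high = o$ci_high)
  })
  do.call(rbind, rows)
}

#' Run a full experiment
#'
#' simulate (or load from cache) -> preprocess -> segment -> bagging per
#' (model x modality x location) -> traditional-TUG comparator ->
#' clinical tables. Any stage failure aborts with the stage name.
#'
#' @param config An [experiment_config()].
#' @return A report list: `config`, `cohort_summary`, `clinical`,
#'   `ml_summaries` (named `kind_modality_location`), `tug_reference`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$bagging$n_iterations < 1)
    stopf("validation error: n_iterations must be >= 1")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  cohort <- stage("simulate+preprocess", {
    key <- NULL
    if (!is.null(config$cache_dir)) {
      dir.create(config$cache_dir, recursive = TRUE, showWarnings = FALSE)
      tmp <- tempfile()
      saveRDS(list(config$sim, config$n_subjects, config$faller_fraction,
                   config$target_rate_hz, config$norm_scope), tmp)
      key <- file.path(config$cache_dir,
                       paste0("cohort-", unname(tools::md5sum(tmp)), ".rds"))
      unlink(tmp)
    }
    if (!is.null(key) && file.exists(key)) readRDS(key)
    else {
      co <- simulate_cohort(config$n_subjects, config$faller_fraction, config$sim)
      co <- preprocess_cohort(co, config$target_rate_hz, config$norm_scope)
      if (!is.null(key)) saveRDS(co, key)
      co
    }
  })
  ml <- list()
  for (kind in config$model_kinds)
    for (mod in config$modalities)
      for (loc in config$locations) {
        nm <- paste(kind, mod, loc, sep = "_")
        ml[[nm]] <- stage(nm, run_bagging(
          cohort, kind, mod, loc, config$bagging, config$cnn,
          config$window_s, config$stride_s))
      }
  # study protocol selects 10 per class; cap at what a small cohort allows
  n_per_class <- min(10L, sum(cohort$subjects$label == 1),
                     sum(cohort$subjects$label == 0))
  tug_ref <- stage("tug_reference", tug_reference_bootstrap(
    cohort$subjects, config$tug_cutoff_s,
    n_iterations = config$bagging$n_iterations,
    n_per_class = n_per_class, n_draws = 100L * 2L * n_per_class,
    master_seed = config$bagging$master_seed))
  clin <- stage("clinical", clinical_table(cohort$subjects, config$clinical_rules))
  report <- list(
    config = config,
    cohort_summary = list(n = nrow(cohort$subjects),
                          n_fallers = sum(cohort$subjects$label == 1),
                          rate_hz = cohort$sample_rate_hz,
                          padded_to = cohort$padded_to),
    clinical = clin, ml_summaries = ml, tug_reference = tug_ref)
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write an experiment report to disk
#'
#' Emits `clinical.tsv`, one `<name>_iterations.tsv` per bagging run,
#' and `summary.json` with all aggregated metrics.
#'
#' @param report A [run_experiment()] result.
#' @param dir Output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(report$clinical, file.path(dir, "clinical.tsv"), sep = "\t")
  summaries <- list()
  all_runs <- c(report$ml_summaries, list(clinical_tug = report$tug_reference))
  for (nm in names(all_runs)) {
    ms <- all_runs[[nm]]
    data.table::fwrite(ms$iterations,
                       file.path(dir, paste0(nm, "_iterations.tsv")), sep = "\t")
    s <- as.list(stats::setNames(ms$summary$mean, ms$summary$metric))
    s$auc_ci_low <- ms$summary$ci_low[ms$summary$metric == "auc"]
    s$auc_ci_high <- ms$summary$ci_high[ms$summary$metric == "auc"]
    s$c_statistic_z <- ms$c_statistic$z
    s$c_statistic_p <- ms$c_statistic$p_one_sided
    summaries[[nm]] <- s
  }
  jsonlite::write_json(list(cohort = report$cohort_summary, models = summaries),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
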