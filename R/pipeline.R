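# End-to-end orchestration: simulate -> prepare -> train -> calibrate ->
# audit -> utility -> explain -> cluster -> report, from a single
# configuration, with every artifact written to the output directory and
# listed in a hashed manifest.

#' Pipeline configuration
#'
#' @param seed master integer seed; stage seeds are derived from it.
#' @param outdir output directory (created if absent).
#' @param synthetic named list of [synth_config()] overrides.
#' @param split `"random-by-patient"` or `"temporal"`.
#' @param test_fraction test fraction for the random split.
#' @param cutoff_year cutoff for the temporal split.
#' @param rebalance training rebalancing method (see [rebalance_training()]).
#' @param learners character vector from `c("lr", "gbt")`.
#' @param gbt_grid hyperparameter grid for the GBT learner (NULL: default).
#' @param calibration `"none"`, `"global"`, or `"stratified:<attribute>"`
#'   (attribute one of sex, residency, instability).
#' @param fairness_attributes protected attributes to audit.
#' @param dca_thresholds decision-curve threshold grid.
#' @param explain named list: `model` (learner explained), `subsample_fraction`
#'   of the test set, `background_n` background rows, `n_samples` Shapley
#'   permutations, `top_k`, `risk_threshold`.
#' @return object of class `dhd_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            outdir = tempfile("dhd_run_"),
                            synthetic = list(),
                            split = c("random-by-patient", "temporal"),
                            test_fraction = 0.10,
                            cutoff_year = 2014,
                            rebalance = "class_weight",
                            learners = c("lr", "gbt"),
                            gbt_grid = NULL,
                            calibration = "stratified:instability",
                            fairness_attributes = c("sex", "residency",
                                                    "instability"),
                            dca_thresholds = seq(0.01, 0.60, by = 0.01),
                            explain = list()) {
  split <- match.arg(split)
  stop_if_not(all(learners %in% c("lr", "gbt")),
              "learners must be drawn from 'lr', 'gbt'")
  stop_if_not(calibration == "none" || calibration == "global" ||
                grepl("^stratified:", calibration),
              "calibration must be 'none', 'global' or 'stratified:<attribute>'")
  ex <- utils::modifyList(list(model = "gbt", subsample_fraction = 0.10,
                               background_n = 100L, n_samples = 12L,
                               top_k = 10L, risk_threshold = 0.5), explain)
  if (grepl("^stratified:", calibration)) {
    a <- sub("^stratified:", "", calibration)
    stop_if_not(a %in% c("sex", "residency", "instability"),
                "unknown stratification attribute '%s'", a)
  }
  structure(list(seed = as.integer(seed), outdir = outdir,
                 synthetic = synthetic, split = split,
                 test_fraction = test_fraction, cutoff_year = cutoff_year,
                 rebalance = rebalance, learners = learners,
                 gbt_grid = gbt_grid, calibration = calibration,
                 fairness_attributes = fairness_attributes,
                 dca_thresholds = dca_thresholds, explain = ex),
            class = "dhd_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()] arguments.
#' @return a `dhd_config`.
#' @export
read_pipeline_config <- function(path) {
  stop_if_not(requireNamespace("yaml", quietly = TRUE),
              "reading YAML configs requires the yaml package")
  do.call(pipeline_config, yaml::read_yaml(path))
}

.stage <- function(name, log, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  log(sprintf("stage %-9s done in %.1fs", name,
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full analysis pipeline
#'
#' Executes simulate, prepare, train, calibrate, audit, utility, explain,
#' cluster and report stages from one configuration, writing every
#' intermediate artifact, a JSON summary (discrimination / calibration /
#' fairness tables), a log with seeds and versions, and a hashed manifest of
#' all outputs. Re-running with an identical configuration reproduces the
#' artifacts bit-for-bit.
#'
#' @param config a `dhd_config` (see [pipeline_config()]).
#' @return invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config) {
  stop_if_not(inherits(config, "dhd_config"), "config must be a dhd_config")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(config$outdir, "log.txt")
  cat(sprintf("dhdrisk %s | R %s | seed %d\n",
              as.character(utils::packageVersion("dhdrisk")),
              paste(R.version$major, R.version$minor, sep = "."),
              config$seed), file = logfile)
  log <- function(msg) {
    cat(msg, "\n", sep = "", file = logfile, append = TRUE)
    message(msg)
  }
  out <- function(...) file.path(config$outdir, ...)
  summary <- list(seed = config$seed)

  # --- simulate ---
  sim <- .stage("simulate", log, {
    sc <- do.call(synth_config,
                  utils::modifyList(list(seed = config$seed), config$synthetic))
    generate_admissions(sc)
  })
  write_admissions(sim$admissions, out("admissions.csv"))
  write_ground_truth(sim$ground_truth, out("ground_truth.json"))
  summary$n_admissions_raw <- nrow(sim$admissions)
  summary$bayes_auc <- sim$ground_truth$bayes_auc

  # --- prepare ---
  prep <- .stage("prepare", log, {
    ex <- apply_exclusions(sim$admissions)
    cohort <- build_lookback_features(ex$admissions)
    splits <- if (config$split == "temporal")
      temporal_split(cohort, config$cutoff_year)
    else split_by_patient(cohort, config$test_fraction, seed = config$seed)
    stop_if_not(length(intersect(unique(splits$train$patient_id),
                                 unique(splits$test$patient_id))) == 0,
                "patient leak across the train/test split")
    train <- rebalance_training(splits$train, config$rebalance,
                                seed = config$seed)
    list(tally = ex$tally, train = train, test = splits$test)
  })
  jsonlite::write_json(unclass(prep$tally), out("exclusions.json"),
                       auto_unbox = TRUE)
  jsonlite::write_json(list(seed = config$seed, scheme = config$split,
                            train_patients = unique(prep$train$patient_id),
                            test_patients = unique(prep$test$patient_id)),
                       out("split_manifest.json"))
  summary$n_train <- length(prep$train$outcome)
  summary$n_test <- length(prep$test$outcome)
  summary$test_prevalence <- mean(prep$test$outcome)

  strat_attr <- if (grepl("^stratified:", config$calibration))
    sub("^stratified:", "", config$calibration) else NULL

  models <- list()
  summary$models <- list()
  summary$fairness <- list()
  for (lrn in config$learners) {
    # --- train ---
    model <- .stage(paste0("train:", lrn), log, {
      dhd_fit(prep$train, lrn,
              grid = if (lrn == "gbt") config$gbt_grid else NULL,
              seed = config$seed)
    })
    save_dhd_model(model, out(sprintf("model_%s.rds", lrn)))
    p_train_raw <- predict(model, prep$train, calibrated = FALSE)
    p_raw <- predict(model, prep$test, calibrated = FALSE)
    y <- prep$test$outcome

    # --- calibrate (fitted on the training data, refit stage) ---
    cal <- .stage(paste0("calibrate:", lrn), log, {
      if (config$calibration == "none") NULL
      else if (config$calibration == "global")
        fit_platt(p_train_raw, prep$train$outcome)
      else fit_groupwise_platt(
        prediction_set(p_train_raw, prep$train$outcome,
                       prep$train$attributes), strat_attr)
    })
    if (!is.null(cal)) model <- attach_calibrator(model, cal)
    p_cal <- predict(model, prep$test)
    models[[lrn]] <- model

    m_raw <- calibration_metrics(p_raw, y)
    m_cal <- calibration_metrics(p_cal, y)
    write_calibration_report(m_cal, out(sprintf("calibration_%s.json", lrn)),
                             out(sprintf("reliability_%s.csv", lrn)))
    summary$models[[lrn]] <- list(
      hyperparameters = model$hyperparameters,
      auc_raw = auc(p_raw, y), auc_calibrated = auc(p_cal, y),
      brier_raw = m_raw$brier, brier_calibrated = m_cal$brier,
      ece_raw = m_raw$ece, ece_calibrated = m_cal$ece,
      calibration_intercept_raw = m_raw$calibration_intercept,
      calibration_slope_raw = m_raw$calibration_slope,
      calibration_intercept = m_cal$calibration_intercept,
      calibration_slope = m_cal$calibration_slope)

    # --- audit: raw, global-Platt and configured scheme, per Figs 4-5 ---
    fair <- .stage(paste0("audit:", lrn), log, {
      ps_raw <- prediction_set(p_raw, y, prep$test$attributes)
      schemes <- list(raw = fairness_report(ps_raw,
                                            config$fairness_attributes))
      g <- fit_platt(p_train_raw, prep$train$outcome)
      schemes$global_platt <- fairness_report(
        prediction_set(predict(g, p_raw), y, prep$test$attributes),
        config$fairness_attributes)
      if (!is.null(strat_attr)) {
        gw <- fit_groupwise_platt(
          prediction_set(p_train_raw, prep$train$outcome,
                         prep$train$attributes), strat_attr)
        p_gw <- predict(gw, p_raw, prep$test$attributes[[strat_attr]])
        schemes[[paste0("stratified_", strat_attr)]] <- fairness_report(
          prediction_set(p_gw, y, prep$test$attributes),
          config$fairness_attributes)
      }
      schemes
    })
    for (sch in names(fair)) {
      write_fairness_report(fair[[sch]],
                            out(sprintf("fairness_%s_%s.json", lrn, sch)),
                            out(sprintf("fairness_%s_%s.csv", lrn, sch)))
    }
    summary$fairness[[lrn]] <- lapply(fair, as.data.frame)

    # --- utility ---
    dc <- .stage(paste0("utility:", lrn), log, {
      decision_curve(prediction_set(p_cal, y, prep$test$attributes),
                     config$dca_thresholds)
    })
    write_decision_curve(dc, out(sprintf("decision_curve_%s.csv", lrn)))
    near <- function(t) which.min(abs(dc$threshold - t))
    summary$models[[lrn]]$nb_model_t10 <- dc$nb_model[near(0.10)]
    summary$models[[lrn]]$nb_all_t10 <- dc$nb_all[near(0.10)]
    summary$models[[lrn]]$snb_model_t10 <- dc$snb_model[near(0.10)]
  }

  # --- explain (raw model score scale; calibration is a monotone rescale) ---
  ecfg <- config$explain
  emodel <- models[[ecfg$model]]
  expl <- .stage("explain", log, {
    set.seed(config$seed + 1L)
    n_test <- length(prep$test$outcome)
    sub <- sort(sample.int(n_test, max(2L, ceiling(ecfg$subsample_fraction *
                                                     n_test))))
    bg_idx <- sample.int(length(prep$train$outcome),
                         min(ecfg$background_n, length(prep$train$outcome)))
    background <- prep$train$features[bg_idx, , drop = FALSE]
    scores_sub <- predict(emodel, .subset_cohort(prep$test, sub),
                          calibrated = FALSE)
    atts <- lapply(seq_along(sub), function(i) {
      shapley_attributions(emodel,
                           prep$test$features[sub[i], , drop = FALSE],
                           background, mode = "sampled",
                           n_samples = ecfg$n_samples,
                           seed = config$seed + i, id = sub[i])
    })
    pimp <- permutation_importance(emodel, prep$test, n_repeats = 3,
                                   seed = config$seed)
    list(attributions = atts, scores = scores_sub, importance = pimp,
         subsample = sub)
  })
  utils::write.csv(expl$importance, out("permutation_importance.csv"),
                   row.names = FALSE)
  atts_long <- do.call(rbind, lapply(expl$attributions, function(a) {
    data.frame(instance = a$id, feature = names(a$contributions),
               value = unname(a$contributions), stringsAsFactors = FALSE)
  }))
  utils::write.csv(atts_long, out("attributions.csv"), row.names = FALSE)

  # --- cluster ---
  clus <- .stage("cluster", log, {
    fs <- summarize_attributions(expl$attributions, expl$scores,
                                 risk_threshold = ecfg$risk_threshold,
                                 top_k = ecfg$top_k)
    list(summary = fs, pca = pca_quadrants(fs))
  })
  write_explanation_summary(clus$summary, clus$pca,
                            out("feature_summary.csv"), out("pca.json"))
  summary$explanation <- list(
    n_high_risk = attr(clus$summary, "n_high_risk"),
    variance_explained = clus$pca$variance_explained,
    pc12_variance_pct = 100 * sum(clus$pca$variance_explained[1:2]),
    quadrant_counts = as.list(table(clus$pca$quadrant)),
    noise_importance = expl$importance$importance[
      expl$importance$feature == "noise_hist"])

  # --- report ---
  .stage("report", log, {
    jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                         digits = NA, na = "null")
    files <- setdiff(list.files(config$outdir), "manifest.json")
    manifest <- data.frame(file = files,
                           md5 = unname(tools::md5sum(out(files))),
                           stringsAsFactors = FALSE)
    jsonlite::write_json(manifest, out("manifest.json"))
    TRUE
  })
  invisible(summary)
}
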