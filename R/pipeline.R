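# End-to-end orchestration: simulate (or load) -> encode/normalize -> split
# -> under-sample -> train (steps i-iv) -> evaluate + baselines -> WJR/Dtc
# root cause -> LASSO/Cox/KM survival factors -> logistic risk score, with
# every artifact written to an output directory and a run log echoing every
# seed. The stage functions are the package's public API; this wrapper is
# the headless equivalent of an interactive front end.

#' Pipeline run configuration
#'
#' @param cohort A `cohort_spec` to simulate, or a path to a cohort CSV.
#' @param train_ratio Train fraction of the labeled records.
#' @param net_cfg,loss_cfg Network and loss configurations.
#' @param wjr_runs Number of repeated trainings for the WJR analysis.
#' @param wjr_method `"semisupervised"` or `"supervised"` WJR runs.
#' @param dtc_threshold Dtc flag threshold.
#' @param risk_threshold Survival threshold for the risk score.
#' @param run_baselines Fit the baseline-classifier suite (default `TRUE`).
#' @param seed Master seed; all stage seeds derive from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = default_spec(), train_ratio = 0.8,
                       net_cfg = NULL, loss_cfg = loss_config(),
                       wjr_runs = 20L,
                       wjr_method = c("semisupervised", "supervised"),
                       dtc_threshold = 1.5, risk_threshold = 0,
                       run_baselines = TRUE, seed = 1L) {
  wjr_method <- match.arg(wjr_method)
  if (!inherits(loss_cfg, "loss_config")) stopf("loss_cfg must be a loss_config")
  if (!is.null(net_cfg) && !inherits(net_cfg, "net_config")) {
    stopf("net_cfg must be a net_config")
  }
  if (!inherits(cohort, "cohort_spec") && !is.character(cohort)) {
    stopf("cohort must be a cohort_spec or a CSV path")
  }
  if (wjr_runs < 1) stopf("wjr_runs must be at least 1")
  structure(list(cohort = cohort, train_ratio = train_ratio,
                 net_cfg = net_cfg, loss_cfg = loss_cfg,
                 wjr_runs = as.integer(wjr_runs), wjr_method = wjr_method,
                 dtc_threshold = dtc_threshold,
                 risk_threshold = risk_threshold,
                 run_baselines = isTRUE(run_baselines),
                 seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, log_lines, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
  elapsed <- proc.time()[["elapsed"]] - t0
  log_lines$lines <- c(log_lines$lines,
                       sprintf("stage=%s elapsed_s=%.2f", name, elapsed))
  res
}

#' Run the full survival-analysis pipeline
#'
#' Executes every stage on a simulated or loaded cohort and writes all
#' reports into `outdir`. Every CSV/JSON artifact is a pure function of the
#' configuration and its seed; the run log additionally records wall times.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results and the
#'   artifact paths.
#' @export
run_pipeline <- function(config, outdir) {
  if (!inherits(config, "run_config")) stopf("config must be a run_config")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_env <- new.env()
  log_env$lines <- c(sprintf("seed=%d", config$seed),
                     sprintf("wjr_runs=%d wjr_method=%s", config$wjr_runs,
                             config$wjr_method))
  paths <- list()

  cohort <- stage("cohort", log_env, {
    if (is.character(config$cohort)) read_cohort(config$cohort)
    else generate_cohort(config$cohort)
  })
  paths$cohort <- file.path(outdir, "cohort.csv")
  write_cohort(cohort, paths$cohort)
  if (inherits(config$cohort, "cohort_spec")) {
    paths$spec <- file.path(outdir, "cohort_spec.json")
    write_cohort_spec(config$cohort, paths$spec)
  }

  summary_tab <- stage("summarize", log_env, summarize_cohort(cohort))
  paths$summary <- file.path(outdir, "table_summary.csv")
  write_summary(summary_tab, paths$summary)

  prep <- stage("encode_normalize", log_env, {
    norm <- normalize_features(cohort_features(cohort))
    labeled <- which(cohort$followed == 1)
    censored <- which(cohort$followed == 0)
    list(X = norm$X, ranges = norm$ranges, labeled = labeled,
         censored = censored)
  })

  split <- stage("split", log_env, {
    lab <- prep$labeled
    split_cohort(cohort$outcome[lab], cohort$time[lab],
                 train_ratio = config$train_ratio,
                 seed = derive_seed(config$seed, 2))
  })
  paths$split <- file.path(outdir, "split.json")
  write_split(split, paths$split)

  lab_idx <- prep$labeled
  X_train <- prep$X[lab_idx[split$train_idx], , drop = FALSE]
  y_train <- cohort$outcome[lab_idx[split$train_idx]]
  X_test <- prep$X[lab_idx[split$test_idx], , drop = FALSE]
  y_test <- cohort$outcome[lab_idx[split$test_idx]]
  X_cens <- prep$X[prep$censored, , drop = FALSE]

  net_cfg <- config$net_cfg %||% net_config(input_dim = ncol(prep$X))
  net_cfg$seed <- derive_seed(config$seed, 3)

  trained <- stage("train", log_env, {
    keep <- undersample_majority(y_train, seed = derive_seed(config$seed, 4))
    m0 <- train_initial(X_train[keep, , drop = FALSE], y_train[keep], net_cfg)
    pl <- pseudo_label(m0, X_cens, ids = cohort$patient_id[prep$censored])
    m1 <- train_cost_sensitive(X_train, y_train, X_cens, pl$label,
                               net_cfg = net_cfg, loss_cfg = config$loss_cfg)
    list(supervised = m0, model = m1, pseudo = pl)
  })
  paths$model <- file.path(outdir, "model.json")
  save_model(trained$model, paths$model)
  paths$history <- file.path(outdir, "training_history.csv")
  utils::write.csv(trained$model$history, paths$history, row.names = FALSE)
  paths$pseudo <- file.path(outdir, "pseudo_labels.csv")
  utils::write.csv(as.data.frame(trained$pseudo), paths$pseudo,
                   row.names = FALSE)
  log_env$lines <- c(log_env$lines,
                     sprintf("pseudo_labels death=%d survival=%d",
                             sum(trained$pseudo$label == 1),
                             sum(trained$pseudo$label == 0)))

  eval_res <- stage("evaluate", log_env, {
    p <- predict(trained$model, X_test, type = "prob")[, "death"]
    p0 <- predict(trained$supervised, X_test, type = "prob")[, "death"]
    m <- metrics_from_probs(y_test, p)
    m$nri_vs_supervised <- reclassification_metrics(y_test, p0, p)$nri
    m$idi_vs_supervised <- reclassification_metrics(y_test, p0, p)$idi
    list(metrics = m, p_death = p, p_supervised = p0)
  })
  paths$metrics <- file.path(outdir, "metrics.json")
  write_metrics(eval_res$metrics, paths$metrics)

  if (config$run_baselines) {
    baselines <- stage("baselines", log_env,
                       baseline_suite(X_train, y_train, X_test, y_test,
                                      seed = derive_seed(config$seed, 5)))
    paths$baselines <- file.path(outdir, "baselines.json")
    write_metrics(baselines, paths$baselines)
  } else {
    baselines <- NULL
  }

  rc <- stage("root_cause", log_env,
              root_cause_analysis(X_train, y_train, X_test, y_test,
                                  X_censored = X_cens, R = config$wjr_runs,
                                  net_cfg = net_cfg,
                                  loss_cfg = config$loss_cfg,
                                  method = config$wjr_method,
                                  seed = derive_seed(config$seed, 6),
                                  threshold = config$dtc_threshold))
  paths$wjr <- file.path(outdir, "wjr_subgroups.csv")
  utils::write.csv(as.data.frame(rc$wjr), paths$wjr, row.names = FALSE)
  paths$dtc <- file.path(outdir, "dtc_report.csv")
  write_dtc(rc$dtc, paths$dtc)

  sf <- stage("survival_factors", log_env, {
    lab_all <- lab_idx
    X_lab <- prep$X[lab_all, , drop = FALSE]
    y_lab <- cohort$outcome[lab_all]
    t_lab <- cohort$time[lab_all]
    las <- lasso_select(X_lab, y_lab, seed = derive_seed(config$seed, 8))
    sel <- if (length(las$selected) > 0) las$selected else colnames(X_lab)
    cox <- stepwise_cox(as.data.frame(X_lab)[, sel, drop = FALSE],
                        y_lab, pmax(t_lab, 1e-6))
    km_var <- if (length(cox$variables) > 0) cox$variables[1] else sel[1]
    km_group <- ifelse(prep$X[lab_all, km_var] >
                         stats::median(prep$X[lab_all, km_var]),
                       "high", "low")
    km <- km_estimate(t_lab, y_lab, km_group)
    list(lasso = las, cox = cox, km = km, km_var = km_var)
  })
  paths$cox <- file.path(outdir, "cox_result.csv")
  write_cox(sf$cox, paths$cox)
  paths$km <- file.path(outdir, "km_curves.csv")
  write_km(sf$km, paths$km)

  risk <- stage("risk_score", log_env, {
    keep <- undersample_majority(y_train, seed = derive_seed(config$seed, 9))
    rm_fit <- fit_risk_model(X_train[keep, , drop = FALSE], y_train[keep])
    scores <- risk_score(rm_fit, X_test)
    preds <- classify_by_threshold(scores, config$risk_threshold)
    rep <- threshold_separation_report(scores, y_test, config$risk_threshold)
    list(model = rm_fit, scores = scores, predictions = preds, report = rep)
  })
  paths$risk_model <- file.path(outdir, "risk_model.json")
  write_risk_model(risk$model, paths$risk_model)
  paths$risk_scores <- file.path(outdir, "risk_scores.csv")
  utils::write.csv(data.frame(patient_id = cohort$patient_id[lab_idx[split$test_idx]],
                              score = risk$scores, predicted = risk$predictions,
                              outcome = y_test),
                   paths$risk_scores, row.names = FALSE)

  paths$log <- file.path(outdir, "run_log.txt")
  writeLines(log_env$lines, paths$log)

  invisible(list(cohort = cohort, summary = summary_tab, split = split,
                 trained = trained, evaluation = eval_res,
                 baselines = baselines, root_cause = rc,
                 survival_factors = sf, risk = risk, paths = paths))
}
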