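# Classification metrics, ROC/AUC, reclassification metrics (NRI/IDI), and
# the baseline-classifier comparison harness. The positive class throughout
# is death (label 1), so sensitivity is the death recall rate.

#' Confusion counts and threshold metrics
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), accuracy =
#' (TP+TN)/n, F1 = 2TP/(2TP+FP+FN), with death (1) as the positive class.
#' With no positive labels present, sensitivity (and F1) are returned as
#' `NA` with a warning rather than silently 0.
#'
#' @param labels,predicted 0/1 vectors of equal length.
#' @return A list of class `metrics_report` with `tp`, `tn`, `fp`, `fn`,
#'   `sensitivity`, `specificity`, `accuracy`, `f1`.
#' @export
classification_metrics <- function(labels, predicted) {
  if (length(labels) != length(predicted)) stopf("length mismatch")
  if (!all(labels %in% c(0, 1)) || !all(predicted %in% c(0, 1))) {
    stopf("labels and predictions must be 0/1")
  }
  tp <- sum(labels == 1 & predicted == 1)
  tn <- sum(labels == 0 & predicted == 0)
  fp <- sum(labels == 0 & predicted == 1)
  fn <- sum(labels == 1 & predicted == 0)
  sens <- if (tp + fn == 0) {
    warning("no positive labels: sensitivity undefined")
    NA_real_
  } else tp / (tp + fn)
  spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 sensitivity = sens, specificity = spec,
                 accuracy = (tp + tn) / length(labels), f1 = f1),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("TP=%d TN=%d FP=%d FN=%d | sens=%.4f spec=%.4f acc=%.4f f1=%.4f\n",
              x$tp, x$tn, x$fp, x$fn, x$sensitivity, x$specificity,
              x$accuracy, x$f1))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps every distinct predicted death probability as a threshold,
#' plotting the standard false-positive rate FP/(FP+TN) against the
#' true-positive rate TP/(TP+FN), and integrates by trapezoid. (A published
#' variant prints the FPr denominator as TP+TN; that form is not monotone
#' in the threshold and cannot produce a ROC curve, so the standard
#' denominator is used.)
#'
#' @param labels 0/1 vector with both classes present.
#' @param death_probabilities Predicted death probabilities in \[0, 1\].
#' @return A list of class `roc_curve` with `points` (threshold, fpr, tpr)
#'   and `auc`.
#' @export
roc_auc <- function(labels, death_probabilities) {
  if (length(labels) != length(death_probabilities)) stopf("length mismatch")
  assert_prob(death_probabilities, "death probabilities")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stopf("ROC needs both classes present")
  ord <- order(death_probabilities, decreasing = TRUE)
  p <- death_probabilities[ord]; y <- labels[ord]
  cum_tp <- cumsum(y == 1); cum_fp <- cumsum(y == 0)
  last <- !duplicated(p, fromLast = TRUE)   # one point per distinct threshold
  tpr <- c(0, cum_tp[last] / n_pos)
  fpr <- c(0, cum_fp[last] / n_neg)
  thr <- c(Inf, p[last])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc),
            class = "roc_curve")
}

#' Net reclassification improvement and integrated discrimination improvement
#'
#' Two-category NRI at a probability cut: records are classified high/low
#' risk by each model at `cut`; NRI = (P(up|event) - P(down|event)) +
#' (P(down|nonevent) - P(up|nonevent)), where "up" means the new model moves
#' a record above the cut that the reference left below. IDI is the change
#' in discrimination slope: (mean new - mean reference probability among
#' events) - (same among nonevents).
#'
#' @param labels 0/1 vector with both classes present.
#' @param probs_reference,probs_new Predicted death probabilities under the
#'   reference and the new model.
#' @param cut Reclassification threshold in (0, 1), default 0.5.
#' @return A list with `nri`, `idi` and the event/nonevent movement counts.
#' @export
reclassification_metrics <- function(labels, probs_reference, probs_new,
                                     cut = 0.5) {
  if (cut <= 0 || cut >= 1) stopf("cut must be in (0, 1)")
  if (length(labels) != length(probs_reference) ||
      length(labels) != length(probs_new)) stopf("length mismatch")
  ev <- labels == 1; ne <- labels == 0
  if (!any(ev) || !any(ne)) stopf("both classes must be present")
  hi_ref <- probs_reference > cut
  hi_new <- probs_new > cut
  up <- !hi_ref & hi_new
  down <- hi_ref & !hi_new
  nri <- (mean(up[ev]) - mean(down[ev])) + (mean(down[ne]) - mean(up[ne]))
  idi <- (mean(probs_new[ev]) - mean(probs_reference[ev])) -
         (mean(probs_new[ne]) - mean(probs_reference[ne]))
  list(nri = nri, idi = idi,
       events_up = sum(up[ev]), events_down = sum(down[ev]),
       nonevents_up = sum(up[ne]), nonevents_down = sum(down[ne]))
}

metrics_from_probs <- function(labels, p_death, cut = 0.5) {
  m <- classification_metrics(labels, as.integer(p_death > cut))
  m$auc <- tryCatch(roc_auc(labels, p_death)$auc, error = function(e) NA_real_)
  m
}

#' Fit and evaluate the standard baseline classifiers
#'
#' Fits a decision tree, random forest, gradient-boosted trees, k-nearest
#' neighbours, a support vector machine, and plain logistic regression via
#' their standard library implementations at fixed seeds, and evaluates each
#' on the test set. The two tree ensembles additionally report feature
#' importances for survival-factor inspection. A classifier that fails on a
#' degenerate training set is recorded as an error entry and the suite
#' continues.
#'
#' @param X_train,y_train,X_test,y_test Encoded feature matrices and 0/1
#'   outcome vectors.
#' @param seed Integer seed applied before each stochastic fit.
#' @param knn_k Neighbours for KNN (default 5).
#' @return A list of class `baseline_suite` with one entry per classifier:
#'   either a `metrics_report` (with `auc`, and `importance` for rf/gbdt) or
#'   an error message.
#' @export
baseline_suite <- function(X_train, y_train, X_test, y_test, seed = 1L,
                           knn_k = 5L) {
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  train_df <- data.frame(X_train)
  test_df <- data.frame(X_test)
  names(test_df) <- names(train_df)
  fit_one <- function(fn) tryCatch(fn(), error = function(e) {
    list(error = conditionMessage(e))
  })
  out <- list(
    dt = fit_one(function() {
      set.seed(seed)
      d <- cbind(train_df, .y = factor(y_train, levels = c(0, 1)))
      fit <- rpart::rpart(.y ~ ., data = d, method = "class")
      p <- predict(fit, test_df, type = "prob")[, "1"]
      metrics_from_probs(y_test, p)
    }),
    rf = fit_one(function() {
      set.seed(seed)
      fit <- randomForest::randomForest(X_train,
                                        factor(y_train, levels = c(0, 1)),
                                        ntree = 300)
      p <- predict(fit, X_test, type = "prob")[, "1"]
      m <- metrics_from_probs(y_test, p)
      imp <- randomForest::importance(fit)[, 1]
      m$importance <- sort(imp, decreasing = TRUE)
      m
    }),
    gbdt = fit_one(function() {
      set.seed(seed)
      dtrain <- xgboost::xgb.DMatrix(X_train, label = y_train)
      fit <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                              max_depth = 4, eta = 0.1,
                                              nthread = 1),
                                data = dtrain, nrounds = 100, verbose = 0)
      p <- predict(fit, xgboost::xgb.DMatrix(X_test))
      m <- metrics_from_probs(y_test, p)
      imp <- xgboost::xgb.importance(model = fit)
      m$importance <- stats::setNames(imp$Gain, imp$Feature)
      m
    }),
    knn = fit_one(function() {
      set.seed(seed)
      pr <- class::knn(X_train, X_test, factor(y_train, levels = c(0, 1)),
                       k = knn_k, prob = TRUE)
      win <- attr(pr, "prob")
      p <- ifelse(pr == "1", win, 1 - win)
      metrics_from_probs(y_test, p)
    }),
    svm = fit_one(function() {
      set.seed(seed)
      fit <- e1071::svm(X_train, factor(y_train, levels = c(0, 1)),
                        probability = TRUE)
      pr <- predict(fit, X_test, probability = TRUE)
      p <- attr(pr, "probabilities")[, "1"]
      metrics_from_probs(y_test, p)
    }),
    lr = fit_one(function() {
      d <- cbind(train_df, .y = y_train)
      fit <- suppressWarnings(stats::glm(.y ~ ., data = d, family = stats::binomial()))
      p <- suppressWarnings(stats::predict(fit, test_df, type = "response"))
      metrics_from_probs(y_test, p)
    })
  )
  class(out) <- "baseline_suite"
  out
}

#' Write a metrics report (or baseline suite) as JSON
#' @param x A `metrics_report` or `baseline_suite`.
#' @param path File path.
#' @export
write_metrics <- function(x, path) {
  strip <- function(m) {
    m <- unclass(m)
    if (!is.null(m$importance)) m$importance <- as.list(m$importance)
    m
  }
  payload <- if (inherits(x, "baseline_suite")) lapply(x, strip) else strip(x)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
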