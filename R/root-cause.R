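# Root-cause internal verification: per-record wrong-judgment rates over R
# repeated trainings, the TNG/FPG/TPG/FNG subgroup partition, per-feature
# effective proportions, and the death threat coefficient (Dtc).

#' Wrong-judgment rate per record
#'
#' Each record is predicted by `R` independently trained models; its WJR is
#' the fraction of runs whose prediction disagrees with the true label.
#'
#' @param true_labels 0/1 vector of length n.
#' @param prediction_matrix n x R matrix of 0/1 predictions, one column per
#'   training run.
#' @return A data frame of class `wjr_table` with columns `id`,
#'   `true_label`, `wjr` and attribute `R`.
#' @export
compute_wjr <- function(true_labels, prediction_matrix) {
  prediction_matrix <- as.matrix(prediction_matrix)
  if (ncol(prediction_matrix) == 0) stopf("at least one prediction run required")
  if (nrow(prediction_matrix) != length(true_labels)) stopf("row/label mismatch")
  wjr <- rowMeans(prediction_matrix != true_labels)
  out <- data.frame(id = seq_along(true_labels), true_label = true_labels,
                    wjr = wjr)
  attr(out, "R") <- ncol(prediction_matrix)
  class(out) <- c("wjr_table", "data.frame")
  out
}

#' Partition records into WJR subgroups
#'
#' Survivors consistently judged correctly (WJR < `lo`) form the true
#' negative group (TNG); survivors consistently judged as deaths
#' (WJR > `hi`) the false positive group (FPG); deaths judged as deaths the
#' true positive group (TPG); deaths judged as survivors the false negative
#' group (FNG). Records with `lo <= WJR <= hi` fall in the fifth group,
#' `other` (the boundary inequalities are strict).
#'
#' @param wjr_table A [compute_wjr()] result.
#' @param lo,hi WJR cut points (defaults 0.25 and 0.75, `lo < hi`).
#' @return The table with an added factor column `subgroup`.
#' @export
assign_subgroups <- function(wjr_table, lo = 0.25, hi = 0.75) {
  if (lo >= hi) stopf("lo must be smaller than hi")
  w <- wjr_table$wjr; y <- wjr_table$true_label
  g <- rep("other", nrow(wjr_table))
  g[y == 0 & w < lo] <- "TNG"
  g[y == 0 & w > hi] <- "FPG"
  g[y == 1 & w < lo] <- "TPG"
  g[y == 1 & w > hi] <- "FNG"
  wjr_table$subgroup <- factor(g, levels = c("TNG", "FPG", "TPG", "FNG", "other"))
  wjr_table
}

#' Effective proportion (or mean) of a feature per subgroup
#'
#' For binary features the share of involved (value 1) records in each
#' group; for continuous features the group mean. An empty group yields
#' `NA`, which propagates to the Dtc ratios as undefined.
#'
#' @param feature_values Numeric vector, one value per record.
#' @param group_ids Factor/character group assignment per record.
#' @return Named numeric vector of per-group Fep values.
#' @export
effective_proportion <- function(feature_values, group_ids) {
  if (length(feature_values) != length(group_ids)) stopf("length mismatch")
  groups <- if (is.factor(group_ids)) levels(group_ids) else unique(group_ids)
  vapply(groups, function(g) {
    v <- feature_values[group_ids == g]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
}

#' Death threat coefficients per feature
#'
#' Dtc(FPG-TNG) = Fep_FPG / Fep_TNG contrasts survivors the model insists
#' on calling deaths against well-classified survivors; Dtc(TPG-FNG) =
#' Fep_TPG / Fep_FNG contrasts recognized deaths against missed deaths. A
#' feature is flagged when both ratios reach `threshold` (default 1.5): the
#' higher the Dtc, the greater the feature's threat of death. A zero
#' denominator makes that ratio undefined (`NA`) with a warning and the
#' feature is not flagged.
#'
#' @param fep_by_group Matrix or data frame with one row per feature and
#'   columns `TNG`, `FPG`, `TPG`, `FNG`.
#' @param threshold Flag threshold for both ratios (default 1.5).
#' @return A data frame of class `dtc_report` with the four Feps, both
#'   ratios, and `flagged`.
#' @export
death_threat_coefficient <- function(fep_by_group, threshold = 1.5) {
  fep <- as.data.frame(fep_by_group)
  need <- c("TNG", "FPG", "TPG", "FNG")
  if (!all(need %in% names(fep))) {
    stopf("fep_by_group needs columns %s", paste(need, collapse = ", "))
  }
  ratio <- function(num, den) {
    bad <- !is.na(den) & den == 0
    if (any(bad)) warning("zero denominator: Dtc undefined for some features")
    out <- num / den
    out[bad] <- NA_real_
    out
  }
  d1 <- ratio(fep$FPG, fep$TNG)
  d2 <- ratio(fep$TPG, fep$FNG)
  eps <- 1e-9   # guard the >= comparison against float division noise
  thr <- threshold - eps
  out <- data.frame(
    feature = rownames(fep) %||% seq_len(nrow(fep)),
    fep_tng = fep$TNG, fep_fpg = fep$FPG, fep_tpg = fep$TPG,
    fep_fng = fep$FNG,
    dtc_fpg_tng = d1, dtc_tpg_fng = d2,
    flagged = !is.na(d1) & !is.na(d2) & d1 >= thr & d2 >= thr,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("dtc_report", "data.frame")
  out
}

#' Repeated-training predictions for WJR analysis
#'
#' Runs the classifier `R` times on the training data, re-seeding both the
#' majority-class under-sampling draw and the network initialization /
#' shuffling per run, and collects each run's test-set predictions. By
#' default each run executes the full semi-supervised scheme (steps i-iii);
#' `method = "supervised"` restricts each run to the step-(i) model.
#'
#' @param X_train,y_train Labeled training records (not yet balanced).
#' @param X_test Test records to predict.
#' @param X_censored Censored records used for pseudo-labeling (ignored for
#'   `method = "supervised"`).
#' @param R Number of repeated trainings (default 20).
#' @param net_cfg,loss_cfg Network and loss configuration templates; each
#'   run derives its own seed from `seed`.
#' @param method `"semisupervised"` or `"supervised"`.
#' @param seed Master seed.
#' @return n_test x R matrix of 0/1 predictions.
#' @export
wjr_replication <- function(X_train, y_train, X_test, X_censored = NULL,
                            R = 20L, net_cfg = net_config(input_dim = ncol(X_train)),
                            loss_cfg = loss_config(),
                            method = c("semisupervised", "supervised"),
                            seed = 1L) {
  method <- match.arg(method)
  if (R < 1) stopf("R must be at least 1")
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  preds <- matrix(NA_integer_, nrow(X_test), R)
  for (r in seq_len(R)) {
    run_seed <- derive_seed(seed, r)
    cfg_r <- net_cfg; cfg_r$seed <- run_seed
    keep <- undersample_majority(y_train, seed = derive_seed(run_seed, 7))
    m0 <- train_initial(X_train[keep, , drop = FALSE], y_train[keep], cfg_r)
    model <- if (method == "semisupervised" && !is.null(X_censored) &&
                 nrow(as.matrix(X_censored)) > 0) {
      pl <- pseudo_label(m0, X_censored)
      train_cost_sensitive(X_train, y_train, X_censored, pl$label,
                           net_cfg = cfg_r, loss_cfg = loss_cfg)
    } else {
      m0
    }
    preds[, r] <- predict(model, X_test, type = "class")
  }
  preds
}

#' Full root-cause analysis of a test set
#'
#' Convenience wrapper: repeated trainings, WJR, subgroup partition, Fep per
#' feature per subgroup, and the Dtc report.
#'
#' @inheritParams wjr_replication
#' @param y_test True test labels.
#' @param feature_kinds Optional character vector (`"binary"`/`"continuous"`)
#'   named by feature; only used for reporting.
#' @param lo,hi,threshold Subgroup cuts and Dtc flag threshold.
#' @return A list with `wjr` (subgrouped table), `fep` (feature x group
#'   matrix) and `dtc` (`dtc_report`).
#' @export
root_cause_analysis <- function(X_train, y_train, X_test, y_test,
                                X_censored = NULL, R = 20L,
                                net_cfg = net_config(input_dim = ncol(X_train)),
                                loss_cfg = loss_config(),
                                method = c("semisupervised", "supervised"),
                                seed = 1L, lo = 0.25, hi = 0.75,
                                threshold = 1.5, feature_kinds = NULL) {
  preds <- wjr_replication(X_train, y_train, X_test, X_censored, R,
                           net_cfg, loss_cfg, method, seed)
  tab <- assign_subgroups(compute_wjr(y_test, preds), lo, hi)
  X_test <- as.matrix(X_test)
  groups <- c("TNG", "FPG", "TPG", "FNG")
  fep <- t(vapply(colnames(X_test), function(f) {
    effective_proportion(X_test[, f], tab$subgroup)[groups]
  }, numeric(length(groups))))
  colnames(fep) <- groups
  dtc <- suppressWarnings(death_threat_coefficient(fep, threshold))
  list(wjr = tab, fep = fep, dtc = dtc)
}

#' Write a Dtc report as CSV
#' @param report A `dtc_report`.
#' @param path File path.
#' @export
write_dtc <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
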