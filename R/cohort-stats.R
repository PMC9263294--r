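# Group summary machinery: counts, percentages, mean +/- SD, and
# survival-vs-death group comparisons (Mann-Whitney U for continuous
# measures, Pearson chi-squared for indicators), formatted the way clinical
# baseline-characteristics tables print them.

#' Percentage of a count, rounded half-up to two decimals
#'
#' @param numerator,denominator Nonnegative counts, `numerator <= denominator`,
#'   `denominator > 0`.
#' @return `100 * numerator / denominator` rounded half-up to 2 decimals.
#' @examples
#' percent(1265, 1370) # 92.34
#' @export
percent <- function(numerator, denominator) {
  if (any(denominator <= 0)) stopf("denominator must be positive")
  if (any(numerator < 0) || any(numerator > denominator)) {
    stopf("numerator must lie in [0, denominator]")
  }
  round_half_up(100 * numerator / denominator, 2)
}

#' Compare a variable between two groups
#'
#' Continuous variables use the two-sided Mann-Whitney U test (normal
#' approximation with tie correction, no continuity correction); binary
#' indicators use the Pearson chi-squared test on the 2x2
#' involved-by-group table without Yates correction.
#'
#' @param values_a,values_b Numeric vectors (0/1 for `kind = "categorical"`).
#' @param kind `"continuous"` or `"categorical"`.
#' @return A list with `p_value`, `statistic`, `method`.
#' @export
compare_groups <- function(values_a, values_b,
                           kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (length(values_a) == 0 || length(values_b) == 0) {
    stopf("both groups must be nonempty")
  }
  if (kind == "continuous") {
    ht <- stats::wilcox.test(values_a, values_b, exact = FALSE,
                             correct = FALSE)
    list(p_value = unname(ht$p.value), statistic = unname(ht$statistic),
         method = "mann-whitney")
  } else {
    tab <- rbind(a = c(sum(values_a == 1), sum(values_a == 0)),
                 b = c(sum(values_b == 1), sum(values_b == 0)))
    if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
      stopf("2x2 table has an empty margin; chi-squared test undefined")
    }
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(p_value = unname(ht$p.value), statistic = unname(ht$statistic),
         method = "chi-squared")
  }
}

#' Summarize a cohort's followed records by outcome group
#'
#' Produces one row per feature: for binary indicators the involved count
#' and percentage in the total, survival, and death groups with a
#' chi-squared p-value; for continuous features the group means and SDs with
#' a Mann-Whitney p-value. With no death group present, summaries are still
#' emitted with `p_value = NA`.
#'
#' @param cohort An `sle_cohort`.
#' @param variables Feature names to summarize; default all features.
#' @return A data frame of class `cohort_summary`.
#' @export
summarize_cohort <- function(cohort, variables = NULL) {
  lab <- cohort[cohort$followed == 1, , drop = FALSE]
  if (nrow(lab) == 0) stopf("cohort has no labeled (followed) records")
  feats <- attr(cohort, "feature_names")
  if (is.null(variables)) variables <- feats
  spec <- attr(cohort, "spec")
  kinds <- if (!is.null(spec)) {
    stats::setNames(spec$features$kind, spec$features$name)
  } else {
    stats::setNames(
      ifelse(vapply(variables, function(v) all(lab[[v]] %in% c(0, 1)),
                    logical(1)), "binary", "continuous"),
      variables)
  }
  if (length(variables) == 0) {
    out <- data.frame(variable = character(0), kind = character(0),
                      total_n = integer(0), total_pct = numeric(0),
                      survival_n = integer(0), survival_pct = numeric(0),
                      death_n = integer(0), death_pct = numeric(0),
                      total_mean = numeric(0), total_sd = numeric(0),
                      survival_mean = numeric(0), survival_sd = numeric(0),
                      death_mean = numeric(0), death_sd = numeric(0),
                      p_value = numeric(0))
    class(out) <- c("cohort_summary", "data.frame")
    return(out)
  }
  surv <- lab[lab$outcome == 0, , drop = FALSE]
  death <- lab[lab$outcome == 1, , drop = FALSE]
  has_both <- nrow(surv) > 0 && nrow(death) > 0
  rows <- lapply(variables, function(v) {
    x <- lab[[v]]
    if (kinds[[v]] == "binary") {
      p <- if (has_both) {
        tryCatch(compare_groups(surv[[v]], death[[v]], "categorical")$p_value,
                 error = function(e) NA_real_)
      } else NA_real_
      data.frame(
        variable = v, kind = "binary",
        total_n = sum(x == 1), total_pct = percent(sum(x == 1), nrow(lab)),
        survival_n = sum(surv[[v]] == 1),
        survival_pct = if (nrow(surv) > 0) percent(sum(surv[[v]] == 1), nrow(surv)) else NA_real_,
        death_n = sum(death[[v]] == 1),
        death_pct = if (nrow(death) > 0) percent(sum(death[[v]] == 1), nrow(death)) else NA_real_,
        total_mean = NA_real_, total_sd = NA_real_,
        survival_mean = NA_real_, survival_sd = NA_real_,
        death_mean = NA_real_, death_sd = NA_real_,
        p_value = p, stringsAsFactors = FALSE)
    } else {
      p <- if (has_both) {
        compare_groups(surv[[v]], death[[v]], "continuous")$p_value
      } else NA_real_
      data.frame(
        variable = v, kind = "continuous",
        total_n = length(x), total_pct = NA_real_,
        survival_n = nrow(surv), survival_pct = NA_real_,
        death_n = nrow(death), death_pct = NA_real_,
        total_mean = mean(x), total_sd = stats::sd(x),
        survival_mean = mean(surv[[v]]), survival_sd = stats::sd(surv[[v]]),
        death_mean = mean(death[[v]]), death_sd = stats::sd(death[[v]]),
        p_value = p, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' Format a p-value the way baseline tables print it
#'
#' Four decimals with a hard floor representation, so p < 0.00005 prints as
#' `"0.0000"`.
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_pvalue <- function(p) {
  ifelse(is.na(p), "NA", sprintf("%.4f", p))
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Variable                     Total          Survival       Death          P value\n")
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    if (r$kind == "binary") {
      cat(sprintf("%-28s %5d(%6.2f)  %5d(%6.2f)  %5d(%6.2f)  %s\n",
                  r$variable, r$total_n, r$total_pct, r$survival_n,
                  r$survival_pct, r$death_n, r$death_pct,
                  format_pvalue(r$p_value)))
    } else {
      cat(sprintf("%-28s %6.2f±%-5.2f  %6.2f±%-5.2f  %6.2f±%-5.2f  %s\n",
                  r$variable, r$total_mean, r$total_sd, r$survival_mean,
                  r$survival_sd, r$death_mean, r$death_sd,
                  format_pvalue(r$p_value)))
    }
  }
  invisible(x)
}

#' Write a cohort summary as CSV
#' @param summary A `cohort_summary`.
#' @param path File path.
#' @export
write_summary <- function(summary, path) {
  utils::write.csv(as.data.frame(summary), path, row.names = FALSE)
  invisible(path)
}
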