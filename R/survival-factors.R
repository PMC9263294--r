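# Survival-factor analysis: L1 (LASSO) screening of the encoded features,
# forward-stepwise Cox proportional-hazards selection with entry/removal
# p-value rules, and Kaplan-Meier curves. The Cox and KM fits themselves go
# through the survival package; the screening and the stepwise selection
# loop are implemented here.

#' LASSO feature screening
#'
#' L1-penalized logistic regression of the survival outcome on the encoded
#' features; the penalty is chosen by cross-validated deviance and the
#' features with nonzero coefficients at that penalty are returned, to be
#' fed into the Cox model.
#'
#' @param X Feature matrix.
#' @param labels 0/1 outcome vector.
#' @param lambda_grid Optional decreasing penalty grid (default: glmnet's).
#' @param cv_folds Cross-validation folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return A list of class `lasso_result` with `selected`, `coefficients`
#'   (named, nonzero only), `lambda`, `cv_lambda` grid and `cv_error`.
#' @export
lasso_select <- function(X, labels, lambda_grid = NULL, cv_folds = 10L,
                         seed = 1L) {
  X <- as.matrix(X)
  if (length(unique(labels)) < 2) stopf("outcome is constant; nothing to fit")
  if (nrow(X) < cv_folds) stopf("need at least cv_folds records")
  set.seed(seed)
  cv <- glmnet::cv.glmnet(X, labels, family = "binomial",
                          lambda = lambda_grid, nfolds = cv_folds)
  co <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1, 1]
  nz <- co[co != 0]
  structure(list(selected = names(nz), coefficients = nz,
                 lambda = cv$lambda.min, cv_lambda = cv$lambda,
                 cv_error = cv$cvm),
            class = "lasso_result")
}

# Partial log-likelihood of a proportional-hazards fit on a plain design
# matrix; the matrix interface skips the formula machinery, which matters
# when the stepwise scan evaluates hundreds of candidate models. Returns
# c(null loglik, fitted loglik); NA on a failed fit.
cox_partial_loglik <- function(Xmat, y) {
  fit <- tryCatch(
    suppressWarnings(survival::coxph.fit(Xmat, y, strata = NULL,
                                         offset = NULL, init = NULL,
                                         control = survival::coxph.control(),
                                         weights = NULL, method = "efron",
                                         rownames = NULL)),
    error = function(e) NULL)
  if (is.null(fit) || any(is.na(fit$coefficients))) return(c(NA_real_, NA_real_))
  fit$loglik
}

fit_cox <- function(df, vars) {
  rhs <- if (length(vars) == 0) "1" else
    paste(sprintf("`%s`", vars), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs))
  survival::coxph(fml, data = df, ties = "efron")
}

#' Forward-stepwise Cox proportional-hazards selection
#'
#' Iteratively adds the candidate covariate with the smallest
#' likelihood-ratio p-value below `entry_p`, then removes any included
#' covariate whose likelihood-ratio p-value (against the model without it)
#' exceeds `removal_p`, for at most `max_steps` iterations. Entry/removal
#' decisions use likelihood-ratio tests; the final model's per-variable
#' hazard ratios and Wald 95% confidence intervals come from the
#' proportional-hazards fit.
#'
#' @param X Data frame or matrix of candidate covariates.
#' @param event 0/1 event indicator (1 = death).
#' @param time Positive survival/censoring times.
#' @param entry_p Largest p-value allowed to enter (default 0.05).
#' @param removal_p Smallest p-value that forces removal (default 0.10).
#' @param max_steps Maximum selection iterations (default 20).
#' @return A list of class `cox_result` with `variables`, `table`
#'   (coefficient, HR, CI, p per selected variable), `steps` (the audit
#'   log), and the final `fit`. No candidate passing entry yields an empty
#'   model, not an error.
#' @export
stepwise_cox <- function(X, event, time, entry_p = 0.05, removal_p = 0.10,
                         max_steps = 20L) {
  X <- as.data.frame(X)
  if (!any(event == 1)) stopf("at least one event required")
  if (any(time <= 0)) stopf("times must be positive")
  df <- cbind(X, .time = time, .event = event)
  Xmat <- as.matrix(X)
  y <- survival::Surv(time, event)
  candidates <- names(X)
  included <- character(0)
  log_rows <- list()
  # the null partial log-likelihood is covariate-free; read it off the
  # first candidate whose single-variable fit succeeds
  ll_null <- NA_real_
  for (v in candidates) {
    ll_null <- cox_partial_loglik(Xmat[, v, drop = FALSE], y)[1]
    if (!is.na(ll_null)) break
  }
  ll_current <- ll_null
  lr_p <- function(ll_big, ll_small, df = 1) {
    stats::pchisq(2 * (ll_big - ll_small), df = df, lower.tail = FALSE)
  }
  for (step in seq_len(max_steps)) {
    changed <- FALSE
    # forward: best candidate by LR p-value
    avail <- setdiff(candidates, included)
    if (length(avail) > 0) {
      pvals <- vapply(avail, function(v) {
        ll <- cox_partial_loglik(Xmat[, c(included, v), drop = FALSE], y)[2]
        lr_p(ll, ll_current)
      }, numeric(1))
      if (any(!is.na(pvals)) && min(pvals, na.rm = TRUE) < entry_p) {
        best <- avail[which.min(pvals)]
        included <- c(included, best)
        ll_current <- cox_partial_loglik(Xmat[, included, drop = FALSE], y)[2]
        log_rows[[length(log_rows) + 1]] <-
          data.frame(step = step, action = "enter", variable = best,
                     p_value = min(pvals, na.rm = TRUE))
        changed <- TRUE
      }
    }
    # backward: drop any included variable that no longer earns its place
    if (length(included) > 1) {
      repeat {
        drop_p <- vapply(included, function(v) {
          rest <- setdiff(included, v)
          ll <- if (length(rest) == 0) {
            ll_null
          } else {
            cox_partial_loglik(Xmat[, rest, drop = FALSE], y)[2]
          }
          lr_p(ll_current, ll)
        }, numeric(1))
        if (all(is.na(drop_p)) || max(drop_p, na.rm = TRUE) <= removal_p) break
        worst <- included[which.max(drop_p)]
        included <- setdiff(included, worst)
        ll_current <- if (length(included) == 0) ll_null else
          cox_partial_loglik(Xmat[, included, drop = FALSE], y)[2]
        log_rows[[length(log_rows) + 1]] <-
          data.frame(step = step, action = "remove", variable = worst,
                     p_value = max(drop_p, na.rm = TRUE))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  current <- if (length(included) > 0) fit_cox(df, included) else NULL
  tab <- if (length(included) == 0) {
    data.frame(variable = character(0), coef = numeric(0), hr = numeric(0),
               ci_lower = numeric(0), ci_upper = numeric(0),
               p_value = numeric(0))
  } else {
    s <- summary(current)
    data.frame(variable = included,
               coef = s$coefficients[, "coef"],
               hr = s$coefficients[, "exp(coef)"],
               ci_lower = s$conf.int[, "lower .95"],
               ci_upper = s$conf.int[, "upper .95"],
               p_value = s$coefficients[, "Pr(>|z|)"],
               row.names = NULL)
  }
  steps <- if (length(log_rows) == 0) {
    data.frame(step = integer(0), action = character(0),
               variable = character(0), p_value = numeric(0))
  } else do.call(rbind, log_rows)
  structure(list(variables = included, table = tab, steps = steps,
                 fit = if (length(included) > 0) current else NULL,
                 entry_p = entry_p, removal_p = removal_p),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  if (length(x$variables) == 0) {
    cat("<cox_result> empty model (no candidate passed entry)\n")
  } else {
    cat(sprintf("<cox_result> %d variables after %d recorded steps\n",
                length(x$variables), nrow(x$steps)))
    print(x$table, digits = 4)
  }
  invisible(x)
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimate S(t) = prod over event times <= t of
#' (1 - d_j / n_j), optionally stratified by a grouping factor; censored
#' records leave the risk set without an event.
#'
#' @param time Nonnegative times.
#' @param event_indicator 0/1 vector (1 = death).
#' @param group Optional grouping vector (one curve per level).
#' @return A data frame of class `km_curve` with columns `group`, `time`,
#'   `n_risk`, `n_event`, `survival`.
#' @export
km_estimate <- function(time, event_indicator, group = NULL) {
  if (length(time) == 0) stopf("empty group: no records to estimate")
  if (any(time < 0)) stopf("times must be nonnegative")
  if (is.null(group)) group <- rep("all", length(time))
  if (any(table(group) == 0)) stopf("empty group level")
  df <- data.frame(.time = time, .event = event_indicator, .g = group)
  fit <- survival::survfit(survival::Surv(.time, .event) ~ .g, data = df)
  sm <- summary(fit, censored = TRUE)
  g <- if (is.null(sm$strata)) rep(unique(as.character(group)), length(sm$time))
       else sub("^\\.g=", "", as.character(sm$strata))
  out <- data.frame(group = g, time = sm$time, n_risk = sm$n.risk,
                    n_event = sm$n.event, survival = sm$surv,
                    stringsAsFactors = FALSE)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Write survival-factor outputs as CSV
#' @param x A `cox_result` or `km_curve`.
#' @param path File path.
#' @export
write_cox <- function(x, path) {
  utils::write.csv(x$table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cox
#' @export
write_km <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
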