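# Logistic-regression survival risk score: coefficients fitted by maximum
# likelihood on balanced labeled data, a linear risk score z = w'x per
# patient (w0 multiplying the constant x0 = 1), and classification against
# the zero survival threshold. Because the intercept is part of the score,
# z > 0 is algebraically identical to a fitted death probability above 0.5,
# which is why the survival threshold sits at zero.

#' Fit the logistic survival-risk model
#'
#' Maximum-likelihood logistic regression of the death outcome on the
#' encoded features. The data should be balanced (majority under-sampled to
#' ~1:1) before fitting. Perfect separation is detected (non-converged or
#' exploding coefficients) and resolved by refitting with a mild ridge
#' penalty, flagged on the returned model.
#'
#' @param X Feature matrix of the balanced training records.
#' @param labels 0/1 outcome vector (1 = death).
#' @param ridge_lambda Penalty used only in the separation fallback
#'   (default 1e-3).
#' @return A list of class `risk_model` with `coefficients` (intercept
#'   first), `threshold` (0), and `separation` flag.
#' @export
fit_risk_model <- function(X, labels, ridge_lambda = 1e-3) {
  X <- as.matrix(X)
  if (length(unique(labels)) < 2) stopf("both classes must be present")
  d <- data.frame(X)
  d$.y <- labels
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = d, family = stats::binomial()),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- stats::coef(fit)
  separated <- warned || !fit$converged || any(!is.finite(co)) ||
    any(abs(co) > 15)
  if (separated) {
    # glmnet requires >= 2 columns; pad single-feature fits with a constant
    Xr <- if (ncol(X) >= 2) X else cbind(X, .pad = 0)
    rf <- glmnet::glmnet(Xr, labels, family = "binomial", alpha = 0,
                         lambda = ridge_lambda)
    co <- as.numeric(stats::coef(rf))[seq_len(ncol(X) + 1)]
    names(co) <- c("(Intercept)", colnames(X))
  } else {
    names(co) <- c("(Intercept)", colnames(X))
  }
  structure(list(coefficients = co, threshold = 0, separation = separated),
            class = "risk_model")
}

#' Linear survival-risk score
#'
#' z = w0 + w1 x1 + ... + wn xn for each patient; higher scores mean more
#' severe disease and higher death risk, lower scores the opposite.
#'
#' @param model A `risk_model`, or a bare numeric coefficient vector
#'   (intercept first).
#' @param X Feature matrix whose column count matches the model.
#' @return Numeric score per patient.
#' @export
risk_score <- function(model, X) {
  w <- if (inherits(model, "risk_model")) model$coefficients else model
  X <- as.matrix(X)
  if (ncol(X) != length(w) - 1) {
    stopf("feature count %d does not match model (%d coefficients incl. intercept)",
          ncol(X), length(w))
  }
  drop(cbind(1, X) %*% w)
}

#' Classify risk scores against the survival threshold
#'
#' Scores above `threshold` predict death (1), scores below predict
#' survival (0); a score exactly at the threshold resolves to survival,
#' completing the two strict inequalities deterministically.
#'
#' @param scores Numeric risk scores.
#' @param threshold Survival threshold (default 0).
#' @return Integer 0/1 predictions.
#' @export
classify_by_threshold <- function(scores, threshold = 0) {
  as.integer(scores > threshold)
}

#' Summarize score separation around the survival threshold
#'
#' Per-class score quartiles plus the threshold-crossing counts: survivors
#' scoring above the threshold and deaths scoring below it (the outliers in
#' a risk-score plot).
#'
#' @param scores Numeric risk scores.
#' @param labels True 0/1 outcomes (both classes present).
#' @param threshold Survival threshold (default 0).
#' @return A list with per-class quartile summaries, crossing counts and
#'   crossing fractions.
#' @export
threshold_separation_report <- function(scores, labels, threshold = 0) {
  if (!any(labels == 0) || !any(labels == 1)) {
    stopf("both classes must be present")
  }
  s0 <- scores[labels == 0]; s1 <- scores[labels == 1]
  qs <- function(v) stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1))
  list(survivor_quartiles = qs(s0),
       death_quartiles = qs(s1),
       survivors_above = sum(s0 > threshold),
       deaths_below = sum(s1 < threshold),
       survivor_crossing_fraction = mean(s0 > threshold),
       death_crossing_fraction = mean(s1 < threshold),
       threshold = threshold)
}

#' Write / read a risk model as JSON
#' @param model A `risk_model`.
#' @param path File path.
#' @export
write_risk_model <- function(model, path) {
  jsonlite::write_json(list(coefficients = as.list(model$coefficients),
                            threshold = model$threshold,
                            separation = model$separation),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coefficients = unlist(raw$coefficients),
                 threshold = raw$threshold, separation = raw$separation),
            class = "risk_model")
}
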