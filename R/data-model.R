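# Cohort container utilities: encoding, normalization, splitting,
# majority-class under-sampling. The encoded, normalized feature matrix is
# the common currency of every downstream model.

#' One-hot encode a raw table
#'
#' Every character/factor column with k levels becomes k indicator columns
#' named `<col>.<level>`; numeric columns pass through unchanged. The
#' returned encoding map freezes the column order and level sets so that the
#' transform is invertible and the encoded width stays stable across stages.
#'
#' @param raw_table A data frame mixing categorical and numeric columns.
#' @param map An encoding map from a previous call, to re-apply the same
#'   encoding to new data (an unseen level is an error naming the column).
#' @return A list with `encoded` (data frame of indicators and passthrough
#'   numerics) and `map` (per-column kind and level set).
#' @export
one_hot_encode <- function(raw_table, map = NULL) {
  if (is.null(map)) {
    map <- lapply(raw_table, function(col) {
      if (is.numeric(col)) list(kind = "numeric")
      else list(kind = "categorical", levels = sort(unique(as.character(col))))
    })
  }
  pieces <- list()
  for (nm in names(map)) {
    if (!nm %in% names(raw_table)) stopf("column '%s' missing from table", nm)
    col <- raw_table[[nm]]
    if (map[[nm]]$kind == "numeric") {
      pieces[[nm]] <- stats::setNames(data.frame(as.numeric(col)), nm)
    } else {
      lv <- map[[nm]]$levels
      vals <- as.character(col)
      unseen <- setdiff(unique(vals), lv)
      if (length(unseen) > 0) {
        stopf("column '%s' has unseen level(s): %s", nm,
              paste(unseen, collapse = ", "))
      }
      ind <- vapply(lv, function(l) as.integer(vals == l),
                    integer(length(vals)))
      ind <- matrix(ind, nrow = length(vals),
                    dimnames = list(NULL, paste(nm, lv, sep = ".")))
      pieces[[nm]] <- as.data.frame(ind)
    }
  }
  list(encoded = do.call(cbind, unname(pieces)), map = map)
}

#' Invert a one-hot encoding
#'
#' @param encoded Data frame produced by [one_hot_encode()].
#' @param map The encoding map returned alongside it.
#' @return The reconstructed raw table (categorical columns as character).
#' @export
one_hot_decode <- function(encoded, map) {
  out <- list()
  for (nm in names(map)) {
    if (map[[nm]]$kind == "numeric") {
      out[[nm]] <- encoded[[nm]]
    } else {
      lv <- map[[nm]]$levels
      cols <- paste(nm, lv, sep = ".")
      ind <- as.matrix(encoded[, cols, drop = FALSE])
      if (any(rowSums(ind) != 1)) {
        stopf("indicator block for '%s' is not one-hot", nm)
      }
      out[[nm]] <- lv[max.col(ind)]
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Min-max normalize a column
#'
#' Maps a numeric vector onto \[0, 1\] via (x - min) / (max - min). A
#' constant column cannot be scaled; it maps to all zeros with a warning.
#' Supplying a stored `range` re-applies a previous normalization (values
#' outside the stored range are clipped to \[0, 1\]).
#'
#' @param column Numeric vector.
#' @param range Optional `c(min, max)` from a previous call.
#' @param clip Clip re-applied values into \[0, 1\] (default `TRUE`).
#' @return A list with `values` and `range = c(min, max)`.
#' @export
min_max_normalize <- function(column, range = NULL, clip = TRUE) {
  if (is.null(range)) range <- c(min(column), max(column))
  lo <- range[1]; hi <- range[2]
  if (hi == lo) {
    warning("constant column: min-max normalization maps it to all zeros")
    return(list(values = rep(0, length(column)), range = range))
  }
  v <- (column - lo) / (hi - lo)
  if (clip) v <- pmin(1, pmax(0, v))
  list(values = v, range = range)
}

#' Normalize a feature matrix column-wise
#'
#' @param X Numeric matrix.
#' @param ranges Optional named list of stored ranges to re-apply.
#' @return List with `X` (normalized matrix) and `ranges`.
#' @export
normalize_features <- function(X, ranges = NULL) {
  out <- X
  new_ranges <- vector("list", ncol(X))
  names(new_ranges) <- colnames(X)
  for (j in seq_len(ncol(X))) {
    nm <- colnames(X)[j]
    r <- if (!is.null(ranges)) ranges[[nm]] else NULL
    res <- min_max_normalize(X[, j], range = r)
    out[, j] <- res$values
    new_ranges[[nm]] <- res$range
  }
  list(X = out, ranges = new_ranges)
}

time_quintile <- function(time) {
  qs <- stats::quantile(time, probs = seq(0.2, 0.8, 0.2), type = 7)
  findInterval(time, unique(qs)) + 1L
}

#' Split labeled records into train and test sets
#'
#' Stratified assignment: records are grouped by outcome crossed with
#' survival-time quintile so that both classes and the time distribution are
#' represented in both sets, and the overall train size equals
#' `round(n * train_ratio)` exactly (largest-remainder allocation across
#' strata).
#'
#' @param outcome 0/1 outcome vector of the labeled records.
#' @param time Survival/follow-up times, same length.
#' @param train_ratio Fraction assigned to training (default 0.8).
#' @param seed Integer seed.
#' @return A list of class `split_indices` with `train_idx`, `test_idx`,
#'   `seed`.
#' @export
split_cohort <- function(outcome, time, train_ratio = 0.8, seed = 1L) {
  n <- length(outcome)
  if (n < 2) stopf("need at least 2 labeled records to split")
  if (length(time) != n) stopf("outcome and time lengths differ")
  if (train_ratio <= 0 || train_ratio >= 1) stopf("train_ratio must be in (0, 1)")
  set.seed(seed)
  target_train <- round(n * train_ratio)
  strata <- interaction(outcome, time_quintile(time), drop = TRUE)
  idx_by_stratum <- split(seq_len(n), strata)
  sizes <- vapply(idx_by_stratum, length, integer(1))
  exact <- sizes * train_ratio
  base <- floor(exact)
  rem <- target_train - sum(base)
  if (rem > 0) {
    order_frac <- order(exact - base, decreasing = TRUE)
    base[order_frac[seq_len(rem)]] <- base[order_frac[seq_len(rem)]] + 1
  } else if (rem < 0) {
    order_frac <- order(exact - base)
    take <- order_frac[base[order_frac] > 0][seq_len(-rem)]
    base[take] <- base[take] - 1
  }
  train_idx <- integer(0)
  for (s in seq_along(idx_by_stratum)) {
    ids <- idx_by_stratum[[s]]
    k <- base[s]
    pick <- if (k >= length(ids)) ids else sample(ids, k)
    train_idx <- c(train_idx, pick)
  }
  train_idx <- sort(train_idx)
  structure(list(train_idx = train_idx,
                 test_idx = setdiff(seq_len(n), train_idx),
                 seed = as.integer(seed)),
            class = "split_indices")
}

#' Under-sample the majority class to a 1:1 ratio
#'
#' Keeps every minority-class record and a seeded uniform sample of the
#' majority class of equal size, so the returned index set is exactly
#' balanced.
#'
#' @param labels 0/1 vector.
#' @param seed Integer seed.
#' @return Sorted integer indices into `labels`.
#' @export
undersample_majority <- function(labels, seed = 1L) {
  n0 <- sum(labels == 0); n1 <- sum(labels == 1)
  if (n0 == 0 || n1 == 0) stopf("both classes must be present to balance")
  set.seed(seed)
  minority <- if (n1 <= n0) 1 else 0
  min_idx <- which(labels == minority)
  maj_idx <- which(labels != minority)
  keep_maj <- if (length(maj_idx) == length(min_idx)) maj_idx
              else sample(maj_idx, length(min_idx))
  sort(c(min_idx, keep_maj))
}

#' Write / read split indices as JSON
#' @param split A `split_indices` object.
#' @param path File path.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train_idx = as.integer(raw$train_idx),
                 test_idx = as.integer(raw$test_idx),
                 seed = as.integer(raw$seed[1])),
            class = "split_indices")
}
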