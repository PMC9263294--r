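# Cost-sensitive semi-supervised neural network -------------------------------
#
# A feed-forward classifier (default 117-64-64-2, softmax head) trained with
# a dynamically weighted, delayed mean-squared-error loss:
#
#   Loss = dyn_weight_MSE(y1, out1) + alpha(t) * dyn_weight_MSE(y2, out2)
#
# where the first term is over true-label records and the second over
# pseudo-labeled (formerly censored) records. dyn_weight_MSE applies
# per-batch class weights (zero_weight = Np/N to survivors, one_weight =
# Nn/N to deaths) inside a batch-mean squared error with a 1/(2*batchsize)
# factor, so the rare death class carries the larger cost. alpha(t) ramps
# linearly from 0 at epoch T1 to alpha_f at epoch T2, delaying the
# pseudo-label term until the supervised fit has stabilized.
#
# The forward/backward pass is implemented here in vectorized base R: the
# loss, its class weighting, and the training schedule are the package's
# central method and are authored in full rather than delegated.

#' Loss schedule configuration
#'
#' @param alpha_f Final pseudo-label weight (default 3).
#' @param t1,t2 Epoch indices where the pseudo-label ramp starts and ends
#'   (defaults 100 and 600); `t1 < t2`.
#' @return A list of class `loss_config`.
#' @export
loss_config <- function(alpha_f = 3, t1 = 100, t2 = 600) {
  if (alpha_f < 0) stopf("alpha_f must be nonnegative")
  if (t1 >= t2) stopf("t1 must be smaller than t2")
  structure(list(alpha_f = alpha_f, t1 = t1, t2 = t2), class = "loss_config")
}

#' Network and optimization configuration
#'
#' Defaults follow the reference architecture: 117 input neurons, two hidden
#' layers of 64, a 2-unit softmax head, learning rate 0.002, batch size 32.
#' Training runs 800 epochs by default so the pseudo-label ramp (ending at
#' epoch 600) completes. The optimizer is plain stochastic gradient descent;
#' a momentum coefficient is available but off by default.
#'
#' @param input_dim Number of input features.
#' @param hidden Integer vector of hidden-layer widths.
#' @param output_dim Number of output units (2: survival, death).
#' @param learning_rate SGD learning rate.
#' @param batch_size Minibatch size (>= 2 so batch class weights are defined).
#' @param epochs Training epochs.
#' @param momentum SGD momentum coefficient in \[0, 1).
#' @param seed Integer seed governing initialization and batch shuffling.
#' @return A list of class `net_config`.
#' @export
net_config <- function(input_dim = 117L, hidden = c(64L, 64L),
                       output_dim = 2L, learning_rate = 0.002,
                       batch_size = 32L, epochs = 800L, momentum = 0,
                       seed = 1L) {
  if (any(c(input_dim, hidden, output_dim) <= 0)) stopf("all dims must be positive")
  if (batch_size < 2) stopf("batch_size must be at least 2")
  if (learning_rate <= 0) stopf("learning_rate must be positive")
  if (momentum < 0 || momentum >= 1) stopf("momentum must be in [0, 1)")
  structure(list(input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden),
                 output_dim = as.integer(output_dim),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 momentum = momentum,
                 seed = as.integer(seed)),
            class = "net_config")
}

#' Per-batch class weights
#'
#' For a batch with `Np` deaths and `Nn` survivors out of `N` records,
#' `zero_weight = Np / N` is applied to label-0 (survivor) records and
#' `one_weight = Nn / N` to label-1 (death) records, so the minority class
#' in the batch receives the larger weight and the two weights sum to 1.
#' Computed once per batch. Single-class batches get weights (0, 1) or
#' (1, 0) exactly as the definition dictates; there is no epsilon floor, so
#' an all-survivor batch contributes zero loss (a documented sharp edge of
#' the weighting rule).
#'
#' @param batch_labels 0/1 vector.
#' @return A list of class `batch_weights` with `zero_weight`, `one_weight`,
#'   `Np`, `Nn`, `N`, and `weights` (per-record weight vector).
#' @export
class_weights <- function(batch_labels) {
  if (length(batch_labels) == 0) stopf("batch must be nonempty")
  if (!all(batch_labels %in% c(0, 1))) stopf("labels must be 0/1")
  N <- length(batch_labels)
  Np <- sum(batch_labels == 1)
  Nn <- sum(batch_labels == 0)
  zw <- Np / N
  ow <- Nn / N
  structure(list(zero_weight = zw, one_weight = ow, Np = Np, Nn = Nn, N = N,
                 weights = (1 - batch_labels) * zw + batch_labels * ow),
            class = "batch_weights")
}

#' Batch mean squared error
#'
#' `(1 / (2 * batchsize)) * sum_i sum_k (y_ik - out_ik)^2` over a batch of
#' two-column target/output matrices.
#' @param targets,outputs Equal-shape numeric matrices.
#' @return Scalar loss.
#' @export
batch_mse <- function(targets, outputs) {
  targets <- as.matrix(targets); outputs <- as.matrix(outputs)
  if (!all(dim(targets) == dim(outputs))) stopf("targets/outputs shape mismatch")
  sum((targets - outputs)^2) / (2 * nrow(targets))
}

#' Dynamically weighted batch MSE
#'
#' Each record's squared-error sum is scaled by its class weight before the
#' batch average: `(1 / (2 * batchsize)) * sum_i w_i * sum_k (y_ik - out_ik)^2`.
#' @param targets,outputs Equal-shape matrices.
#' @param weights Per-record nonnegative weights.
#' @return Scalar loss.
#' @export
dyn_weight_mse <- function(targets, outputs, weights) {
  targets <- as.matrix(targets); outputs <- as.matrix(outputs)
  if (!all(dim(targets) == dim(outputs))) stopf("targets/outputs shape mismatch")
  if (length(weights) != nrow(targets)) stopf("one weight per record required")
  if (any(weights < 0)) stopf("weights must be nonnegative")
  sum(weights * rowSums((targets - outputs)^2)) / (2 * nrow(targets))
}

#' Pseudo-label delay coefficient
#'
#' The ramp that phases the pseudo-label loss in: 0 before epoch `t1`,
#' linear from 0 to `alpha_f` between `t1` and `t2`, constant `alpha_f`
#' after; continuous at both knots.
#' @param t Epoch index (nonnegative).
#' @param cfg A [loss_config()].
#' @return Scalar coefficient.
#' @export
delay_coefficient <- function(t, cfg) {
  if (any(t < 0)) stopf("epoch index must be nonnegative")
  ifelse(t < cfg$t1, 0,
         ifelse(t <= cfg$t2, cfg$alpha_f * (t - cfg$t1) / (cfg$t2 - cfg$t1),
                cfg$alpha_f))
}

#' One-hot targets for survival outcomes
#'
#' Survival (0) maps to (1, 0), death (1) to (0, 1).
#' @param labels 0/1 vector.
#' @return n x 2 matrix.
#' @export
outcome_to_target <- function(labels) {
  cbind(survive = 1 - labels, death = labels)
}

#' Combined supervised + pseudo-label loss
#'
#' `dyn_weight_MSE(true) + alpha(t) * dyn_weight_MSE(pseudo)`, each term
#' using its own batch's class weights. An empty pseudo batch reduces the
#' loss to the supervised term.
#'
#' @param true_labels 0/1 labels of the true-label batch.
#' @param true_outputs n x 2 network outputs for the true-label batch.
#' @param pseudo_labels,pseudo_outputs Same for the pseudo-label batch
#'   (`NULL` or length 0 for none).
#' @param t Epoch index.
#' @param cfg A [loss_config()].
#' @return Scalar loss.
#' @export
combined_loss <- function(true_labels, true_outputs, pseudo_labels,
                          pseudo_outputs, t, cfg) {
  if (length(true_labels) == 0) stopf("true-label batch must be nonempty")
  lt <- dyn_weight_mse(outcome_to_target(true_labels), true_outputs,
                       class_weights(true_labels)$weights)
  if (is.null(pseudo_labels) || length(pseudo_labels) == 0) return(lt)
  lp <- dyn_weight_mse(outcome_to_target(pseudo_labels), pseudo_outputs,
                       class_weights(pseudo_labels)$weights)
  lt + delay_coefficient(t, cfg) * lp
}

# -- MLP internals -----------------------------------------------------------

mlp_init <- function(cfg) {
  dims <- c(cfg$input_dim, cfg$hidden, cfg$output_dim)
  W <- vector("list", length(dims) - 1)
  b <- vector("list", length(dims) - 1)
  for (l in seq_along(W)) {
    lim <- sqrt(6 / (dims[l] + dims[l + 1]))     # Glorot uniform
    W[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1], -lim, lim),
                     dims[l], dims[l + 1])
    b[[l]] <- rep(0, dims[l + 1])
  }
  list(W = W, b = b)
}

softmax_rows <- function(Z) {
  m <- Z[, 1]
  for (j in seq_len(ncol(Z))[-1]) m <- pmax(m, Z[, j])
  E <- exp(Z - m)
  E / rowSums(E)
}

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

mlp_forward <- function(params, X) {
  L <- length(params$W)
  A <- vector("list", L + 1)
  Z <- vector("list", L)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- add_bias(A[[l]] %*% params$W[[l]], params$b[[l]])
    A[[l + 1]] <- if (l < L) pmax(Z[[l]], 0) else softmax_rows(Z[[l]])
  }
  list(A = A, Z = Z, P = A[[L + 1]])
}

# Per-epoch shuffles, drawn in R so the seed fully determines training.
epoch_permutations <- function(n, epochs) {
  out <- matrix(0L, n, epochs)
  for (e in seq_len(epochs)) out[, e] <- sample.int(n)
  out
}

# Run the compiled SGD core over all epochs; `alpha` is the per-epoch
# pseudo-term weight (all zeros for purely supervised training).
run_sgd <- function(params, X1, lab1, X2, lab2, alpha, cfg) {
  epochs <- length(alpha)
  n2 <- nrow(X2)
  perm1 <- matrix(0L, nrow(X1), epochs)
  perm2 <- matrix(0L, n2, epochs)
  for (e in seq_len(epochs)) {
    perm1[, e] <- sample.int(nrow(X1))
    if (n2 > 0) perm2[, e] <- sample.int(n2)
  }
  res <- cssnn_sgd_core(params$W, params$b,
                        X1, outcome_to_target(lab1), as.numeric(lab1),
                        X2, outcome_to_target(lab2), as.numeric(lab2),
                        perm1, perm2, alpha,
                        cfg$batch_size, cfg$learning_rate, cfg$momentum)
  list(params = list(W = res$W, b = res$b),
       hist_true = as.numeric(res$hist_true),
       hist_pseudo = as.numeric(res$hist_pseudo))
}

new_cssnn_model <- function(params, cfg, history) {
  structure(list(params = params, config = cfg, history = history),
            class = "cssnn_model")
}

#' Train the supervised model on balanced labeled data
#'
#' Step (i) of the scheme: the network is fitted to the under-sampled
#' (approximately 1:1) labeled records with the dynamically weighted MSE
#' loss only. Per-epoch mean batch loss is recorded in the training history.
#'
#' @param X Feature matrix (rows = records, normalized to \[0, 1\]).
#' @param labels 0/1 outcome vector.
#' @param cfg A [net_config()].
#' @return A `cssnn_model`.
#' @export
train_initial <- function(X, labels, cfg = net_config(input_dim = ncol(X))) {
  X <- as.matrix(X)
  if (length(unique(labels)) < 2) stopf("training data must contain both classes")
  if (ncol(X) != cfg$input_dim) stopf("X has %d columns, config expects %d",
                                      ncol(X), cfg$input_dim)
  set.seed(cfg$seed)
  params <- mlp_init(cfg)
  empty <- matrix(numeric(0), 0, ncol(X))
  res <- run_sgd(params, X, labels, empty, numeric(0),
                 alpha = rep(0, cfg$epochs), cfg)
  new_cssnn_model(res$params, cfg,
                  data.frame(epoch = seq_len(cfg$epochs),
                             loss = res$hist_true,
                             pseudo_loss = NA_real_, alpha = NA_real_))
}

#' Predict survival/death probabilities or classes
#'
#' @param object A `cssnn_model`.
#' @param X Feature matrix with `input_dim` columns.
#' @param type `"prob"` for the n x 2 (survive, death) probability matrix,
#'   `"class"` for 0/1 labels (argmax; an exact 0.5/0.5 tie resolves to
#'   survival, the majority class, deterministically).
#' @param ... Unused.
#' @return Matrix of probabilities or integer labels.
#' @export
predict.cssnn_model <- function(object, X, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(X)
  if (ncol(X) != object$config$input_dim) {
    stopf("X has %d columns, model expects %d", ncol(X),
          object$config$input_dim)
  }
  P <- mlp_forward(object$params, X)$P
  colnames(P) <- c("survive", "death")
  if (type == "prob") P else as.integer(P[, 2] > P[, 1])
}

#' Pseudo-label censored records
#'
#' Step (ii): the trained model predicts an outcome for every censored
#' record; the argmax of the two output probabilities becomes the record's
#' pseudo label (ties resolve to survival).
#'
#' @param model A `cssnn_model`.
#' @param X Feature matrix of the censored records.
#' @param ids Record identifiers (default row numbers).
#' @return A data frame of class `pseudo_label_set` with columns `id`,
#'   `label`, `p_death`, `source`.
#' @export
pseudo_label <- function(model, X, ids = NULL) {
  X <- as.matrix(X)
  P <- predict(model, X, type = "prob")
  if (is.null(ids)) ids <- seq_len(nrow(X))
  out <- data.frame(id = ids, label = as.integer(P[, 2] > P[, 1]),
                    p_death = P[, 2], source = "pseudo",
                    stringsAsFactors = FALSE)
  class(out) <- c("pseudo_label_set", "data.frame")
  out
}

#' Retrain with cost-sensitive pseudo-label loss
#'
#' Step (iii): the model is retrained on the full labeled records plus the
#' pseudo-labeled censored records with the combined loss. Each epoch pairs
#' every true-label minibatch with a pseudo-label minibatch; both terms
#' carry their own per-batch class weights, and the pseudo term is scaled by
#' the delay coefficient `alpha(epoch)`, so pseudo labels contribute nothing
#' before epoch `t1`.
#'
#' The labeled records are deliberately *not* re-balanced by default: the
#' class penalty of the weighting rule (`zero_weight = Np/N`) only carries
#' information when batches are imbalanced — on 1:1 batches both weights
#' collapse to 0.5 — so retraining on the imbalanced labeled set is what
#' gives the cost-sensitive term its effect.
#'
#' @param X_labeled,labels Labeled records and their 0/1 outcomes.
#' @param X_pseudo,pseudo_labels Censored records and their pseudo labels.
#' @param net_cfg A [net_config()].
#' @param loss_cfg A [loss_config()].
#' @param rebalance Re-apply majority under-sampling to the labeled records
#'   before retraining (default `FALSE`; see Details).
#' @return A `cssnn_model` whose history records the supervised loss, the
#'   (unscaled) pseudo loss, and `alpha` per epoch.
#' @export
train_cost_sensitive <- function(X_labeled, labels, X_pseudo, pseudo_labels,
                                 net_cfg = net_config(input_dim = ncol(X_labeled)),
                                 loss_cfg = loss_config(),
                                 rebalance = FALSE) {
  X_labeled <- as.matrix(X_labeled); X_pseudo <- as.matrix(X_pseudo)
  if (!inherits(loss_cfg, "loss_config")) stopf("loss_cfg must be a loss_config")
  if (length(pseudo_labels) != nrow(X_pseudo)) {
    stopf("one pseudo label per censored record required")
  }
  if (rebalance) {
    keep <- undersample_majority(labels, seed = derive_seed(net_cfg$seed, 1))
    X_labeled <- X_labeled[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  if (length(unique(labels)) < 2) stopf("labeled data must contain both classes")
  set.seed(net_cfg$seed)
  params <- mlp_init(net_cfg)
  alpha <- delay_coefficient(seq_len(net_cfg$epochs), loss_cfg)
  res <- run_sgd(params, X_labeled, labels, X_pseudo, pseudo_labels,
                 alpha, net_cfg)
  new_cssnn_model(res$params, net_cfg,
                  data.frame(epoch = seq_len(net_cfg$epochs),
                             loss = res$hist_true,
                             pseudo_loss = res$hist_pseudo, alpha = alpha))
}

#' Save / load a trained model as JSON
#'
#' Checkpoints hold the architecture and flattened parameters as plain
#' numbers, so they survive any text-only transport.
#' @param model A `cssnn_model`.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  payload <- list(
    config = unclass(model$config),
    W = lapply(model$params$W, function(w) list(dim = dim(w), data = as.vector(w))),
    b = model$params$b
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(net_config, raw$config)
  params <- list(
    W = lapply(seq_along(raw$b), function(l) {
      matrix(raw$W$data[[l]], raw$W$dim[[l]][1], raw$W$dim[[l]][2])
    }),
    b = lapply(raw$b, as.numeric)
  )
  new_cssnn_model(params, cfg, history = NULL)
}

#' @export
print.cssnn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<cssnn_model> %s, lr=%g, batch=%d, epochs=%d, seed=%d\n",
              paste(c(cfg$input_dim, cfg$hidden, cfg$output_dim),
                    collapse = "-"),
              cfg$learning_rate, cfg$batch_size, cfg$epochs, cfg$seed))
  if (!is.null(x$history)) {
    cat(sprintf("  final training loss: %.6f\n",
                x$history$loss[nrow(x$history)]))
  }
  invisible(x)
}
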