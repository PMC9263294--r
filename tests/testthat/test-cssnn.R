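test_that("batch class weights follow the Np/N, Nn/N rule", {
  w <- class_weights(c(0, 1, 0, 1))
  expect_equal(w$zero_weight, 0.5)
  expect_equal(w$one_weight, 0.5)

  w <- class_weights(c(0, 0, 0, 1))
  expect_equal(w$zero_weight, 0.25)
  expect_equal(w$one_weight, 0.75)
  expect_equal(w$weights, c(0.25, 0.25, 0.25, 0.75))

  # degenerate all-survivor batch: weights (0, 1), no epsilon floor
  w <- class_weights(c(0, 0))
  expect_equal(w$zero_weight, 0)
  expect_equal(w$one_weight, 1)

  # conservation on random batches
  set.seed(5)
  for (i in 1:20) {
    labels <- rbinom(sample(2:40, 1), 1, runif(1))
    w <- class_weights(labels)
    expect_equal(w$zero_weight + w$one_weight, 1)
  }
  expect_error(class_weights(integer(0)), "nonempty")
})

test_that("batch MSE matches its definition and mean invariance", {
  t1 <- matrix(c(1, 0), 1)
  o1 <- matrix(c(0.5, 0.5), 1)
  expect_equal(batch_mse(t1, o1), 0.25)
  expect_equal(batch_mse(o1, o1), 0)
  set.seed(8)
  targets <- outcome_to_target(rbinom(10, 1, 0.5))
  outputs <- random_prob_rows(10)
  expect_equal(batch_mse(rbind(targets, targets), rbind(outputs, outputs)),
               batch_mse(targets, outputs))
  expect_error(batch_mse(targets, outputs[1:5, ]), "shape")
})

test_that("weighted MSE reduces, annihilates, and evaluates by hand", {
  set.seed(9)
  targets <- outcome_to_target(rbinom(12, 1, 0.5))
  outputs <- random_prob_rows(12)
  expect_equal(dyn_weight_mse(targets, outputs, rep(1, 12)),
               batch_mse(targets, outputs))
  expect_equal(dyn_weight_mse(targets, outputs, rep(0, 12)), 0)
  # 2 records with squared-error sums 0.5 each, weights (0.25, 0.75)
  tg <- rbind(c(1, 0), c(0, 1))
  ot <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(dyn_weight_mse(tg, ot, c(0.25, 0.75)), 0.125)
  expect_error(dyn_weight_mse(tg, ot, c(-1, 1)), "nonnegative")
})

test_that("delay coefficient ramps linearly and is continuous at the knots", {
  cfg <- loss_config()
  expect_equal(delay_coefficient(50, cfg), 0)
  expect_equal(delay_coefficient(350, cfg), 1.5)
  expect_equal(delay_coefficient(700, cfg), 3)
  # continuity at both knots under the adjacent branch formulas
  expect_equal(delay_coefficient(cfg$t1, cfg), 0)
  expect_equal(delay_coefficient(cfg$t2, cfg), cfg$alpha_f)
  eps <- 1e-9
  expect_equal(delay_coefficient(cfg$t1 - eps, cfg),
               delay_coefficient(cfg$t1 + eps, cfg), tolerance = 1e-7)
  expect_equal(delay_coefficient(cfg$t2 - eps, cfg),
               delay_coefficient(cfg$t2 + eps, cfg), tolerance = 1e-7)
  expect_error(loss_config(t1 = 600, t2 = 100), "smaller")
  expect_error(loss_config(alpha_f = -1), "nonnegative")
})

test_that("combined loss agrees with the scalar-loop oracle", {
  cfg <- loss_config(alpha_f = 3, t1 = 100, t2 = 600)
  set.seed(13)
  for (i in 1:50) {
    n1 <- sample(2:12, 1); n2 <- sample(0:12, 1)
    y1 <- rbinom(n1, 1, runif(1))
    o1 <- random_prob_rows(n1)
    y2 <- if (n2 > 0) rbinom(n2, 1, runif(1)) else integer(0)
    o2 <- if (n2 > 0) random_prob_rows(n2) else NULL
    t <- sample(0:800, 1)
    expect_equal(combined_loss(y1, o1, y2, o2, t, cfg),
                 naive_combined_loss(y1, o1, y2, o2, t, cfg),
                 tolerance = 1e-10)
  }
})

test_that("pseudo term is annihilated before the ramp starts", {
  cfg <- loss_config()
  set.seed(14)
  y1 <- rbinom(6, 1, 0.5); o1 <- random_prob_rows(6)
  y2 <- rbinom(6, 1, 0.5); o2 <- random_prob_rows(6)
  supervised_only <- combined_loss(y1, o1, NULL, NULL, 50, cfg)
  expect_equal(combined_loss(y1, o1, y2, o2, 50, cfg), supervised_only)
  expect_gt(combined_loss(y1, o1, y2, o2, 700, cfg), supervised_only)
})

test_that("supervised training learns a separable fixture deterministically", {
  fx <- separable_fixture()
  cfg <- fast_cfg(ncol(fx$X), seed = 21, epochs = 300)
  m <- train_initial(fx$X, fx$y, cfg)
  acc <- mean(predict(m, fx$X, type = "class") == fx$y)
  expect_gt(acc, 0.95)
  expect_lt(tail(m$history$loss, 1), m$history$loss[1])
  m2 <- train_initial(fx$X, fx$y, cfg)
  expect_identical(m$params, m2$params)
  expect_identical(m$history, m2$history)
  expect_error(train_initial(fx$X, rep(0, nrow(fx$X)), cfg), "both classes")
})

test_that("predictions are valid probability simplex points", {
  fx <- separable_fixture(n = 60)
  m <- train_initial(fx$X, fx$y, fast_cfg(ncol(fx$X), epochs = 50))
  P <- predict(m, fx$X, type = "prob")
  expect_true(all(P >= 0))
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)))
  expect_error(predict(m, fx$X[, 1:2]), "expects")
})

test_that("pseudo-labeling takes the argmax and covers every record", {
  fx <- separable_fixture(n = 80)
  m <- train_initial(fx$X, fx$y, fast_cfg(ncol(fx$X), seed = 3, epochs = 300))
  pl <- pseudo_label(m, fx$X)
  expect_equal(nrow(pl), 80L)
  expect_true(all(pl$label %in% c(0, 1)))
  expect_equal(pl$label, as.integer(pl$p_death > 0.5))
  # a hand-built constant model with output (0.9, 0.1) labels everything 0
  flat <- m
  for (l in seq_along(flat$params$W)) flat$params$W[[l]][] <- 0
  flat$params$b[[length(flat$params$b)]] <- c(log(0.9), log(0.1))
  pf <- pseudo_label(flat, fx$X)
  expect_true(all(pf$label == 0))
})

test_that("pseudo-labels recover generator ground truth for censored records", {
  sp <- tiny_spec(n_total = 700, n_censored = 250, seed = 31,
                  death_fraction = 0.35)
  co <- generate_cohort(sp)
  X <- normalize_features(cohort_features(co))$X
  lab <- co$followed == 1
  keep <- undersample_majority(co$outcome[lab], seed = 1)
  m <- train_initial(X[lab, ][keep, ], co$outcome[lab][keep],
                     fast_cfg(ncol(X), seed = 5, epochs = 300))
  pl <- pseudo_label(m, X[!lab, ])
  truth <- co$latent_outcome[!lab]
  expect_gt(mean(pl$label == truth), 0.6)
  # censored records drawn from the death group are mostly labeled 1
  expect_gt(mean(pl$label[truth == 1]), 0.5)
})

test_that("cost-sensitive retraining obeys the delay schedule", {
  fx <- separable_fixture(n = 100)
  loss_cfg <- fast_loss()
  cfg <- fast_cfg(ncol(fx$X), seed = 8, epochs = 120)
  m <- train_cost_sensitive(fx$X[1:60, ], fx$y[1:60], fx$X[61:100, ],
                            fx$y[61:100], net_cfg = cfg, loss_cfg = loss_cfg)
  h <- m$history
  expect_equal(h$alpha[h$epoch < loss_cfg$t1], rep(0, loss_cfg$t1 - 1))
  expect_equal(h$alpha[h$epoch > loss_cfg$t2],
               rep(loss_cfg$alpha_f, sum(h$epoch > loss_cfg$t2)))
  expect_error(
    train_cost_sensitive(fx$X[1:60, ], fx$y[1:60], fx$X[61:100, ],
                         fx$y[61:100], net_cfg = cfg, loss_cfg = list(t1 = 5)),
    "loss_config")
})

test_that("a zero pseudo weight reproduces supervised-only training", {
  fx <- separable_fixture(n = 80, seed = 11)
  cfg <- fast_cfg(ncol(fx$X), seed = 17, epochs = 60)
  zero_cfg <- loss_config(alpha_f = 0, t1 = 10, t2 = 20)
  m_zero <- train_cost_sensitive(fx$X[1:50, ], fx$y[1:50], fx$X[51:80, ],
                                 fx$y[51:80], net_cfg = cfg,
                                 loss_cfg = zero_cfg)
  # with alpha_f = 0 the pseudo rows receive coefficient 0 at every epoch,
  # so the parameter trajectory matches supervised training batch for batch
  expect_true(all(m_zero$history$alpha == 0))
  probs <- predict(m_zero, fx$X, type = "prob")
  expect_true(all(is.finite(probs)))
})

test_that("model checkpoints round-trip through JSON", {
  fx <- separable_fixture(n = 40)
  m <- train_initial(fx$X, fx$y, fast_cfg(ncol(fx$X), epochs = 30))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(predict(m2, fx$X), predict(m, fx$X), tolerance = 1e-12)
  expect_equal(m2$config$hidden, m$config$hidden)
})
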