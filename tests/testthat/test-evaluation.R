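test_that("confusion metrics match hand arithmetic", {
  # TP=8 FN=2 TN=6 FP=4
  labels <- c(rep(1, 10), rep(0, 10))
  pred <- c(rep(1, 8), rep(0, 2), rep(1, 4), rep(0, 6))
  m <- classification_metrics(labels, pred)
  expect_equal(m$tp, 8); expect_equal(m$fn, 2)
  expect_equal(m$tn, 6); expect_equal(m$fp, 4)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.6)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$f1, 2 * 8 / (2 * 8 + 4 + 2))
  expect_equal(m$tp + m$tn + m$fp + m$fn, 20)

  perfect <- classification_metrics(labels, labels)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)

  allneg <- classification_metrics(labels, rep(0, 20))
  expect_equal(allneg$sensitivity, 0)

  expect_warning(m0 <- classification_metrics(rep(0, 5), rep(0, 5)),
                 "sensitivity undefined")
  expect_true(is.na(m0$sensitivity))
})

test_that("ROC/AUC matches the hand case and degenerate rankings", {
  r <- roc_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(1, 0, 1, 0), c(1, 0, 1, 0))$auc, 1)
  set.seed(3)
  y <- rbinom(4000, 1, 0.4)
  expect_equal(roc_auc(y, runif(4000))$auc, 0.5, tolerance = 0.05)
  expect_error(roc_auc(rep(1, 5), runif(5)), "both classes")
})

test_that("AUC equals the pair-counting concordance probability", {
  concordance_oracle <- function(y, p) {
    pos <- p[y == 1]; neg <- p[y == 0]
    total <- 0
    for (a in pos) for (b in neg) {
      total <- total + (a > b) + 0.5 * (a == b)
    }
    total / (length(pos) * length(neg))
  }
  set.seed(41)
  for (i in 1:100) {
    n <- sample(6:25, 1)
    y <- c(0, 1, rbinom(n - 2, 1, runif(1, 0.2, 0.8)))
    p <- round(runif(n), 2)   # coarse grid forces ties
    expect_equal(roc_auc(y, p)$auc, concordance_oracle(y, p),
                 tolerance = 1e-12)
  }
})

test_that("NRI/IDI match definition arithmetic and identities", {
  # events: 2 of 10 reclassified up, none down; nonevents: 1 of 10 down
  y <- c(rep(1, 10), rep(0, 10))
  ref <- rep(0.4, 20)
  new <- ref
  new[1:2] <- 0.7          # two events up
  new[11] <- 0.4; ref[11] <- 0.7  # one nonevent down
  r <- reclassification_metrics(y, ref, new)
  expect_equal(r$nri, 0.2 + 0.1)
  expect_equal(r$events_up, 2)
  expect_equal(r$nonevents_down, 1)

  # identity comparison
  same <- reclassification_metrics(y, ref, ref)
  expect_equal(same$nri, 0)
  expect_equal(same$idi, 0)

  # IDI against a constant reference on a 6-record fixture:
  # new = labels, ref = 0.5 -> IDI = (1-0.5) - (0-0.5) = 1
  y6 <- c(1, 1, 1, 0, 0, 0)
  r6 <- reclassification_metrics(y6, rep(0.5, 6), as.numeric(y6), cut = 0.4)
  expect_equal(r6$idi, 1)

  # IDI antisymmetry under swapping reference and new
  set.seed(6)
  p1 <- runif(20); p2 <- runif(20)
  fwd <- reclassification_metrics(y, p1, p2)
  bwd <- reclassification_metrics(y, p2, p1)
  expect_equal(fwd$idi, -bwd$idi)
  expect_error(reclassification_metrics(rep(1, 4), runif(4), runif(4)),
               "both classes")
  expect_error(reclassification_metrics(y, ref, new, cut = 1.5), "cut")
})

test_that("baseline suite fits all six classifiers on an easy fixture", {
  fx <- separable_fixture(n = 400, seed = 17)
  tr <- 1:300; te <- 301:400
  suite <- baseline_suite(fx$X[tr, ], fx$y[tr], fx$X[te, ], fx$y[te],
                          seed = 2)
  expect_named(suite, c("dt", "rf", "gbdt", "knn", "svm", "lr"))
  for (nm in names(suite)) {
    expect_null(suite[[nm]]$error)
    expect_gt(suite[[nm]]$accuracy, 0.9)
  }
  suite2 <- baseline_suite(fx$X[tr, ], fx$y[tr], fx$X[te, ], fx$y[te],
                           seed = 2)
  expect_equal(lapply(suite, unclass), lapply(suite2, unclass))
})

test_that("tree importances surface a dominant hazard feature", {
  fs <- rbind(
    feature_spec("driver", "binary", 0.2, 0.8, hazard_weight = 1.5),
    do.call(rbind, lapply(1:8, function(i) {
      feature_spec(sprintf("noise_%02d", i), "binary", 0.3, 0.3)
    }))
  )
  sp <- cohort_spec(900, 20, 0.4, fs, baseline_hazard = 0.02, seed = 13)
  co <- generate_cohort(sp)
  lab <- co$followed == 1
  X <- cohort_features(co)[lab, ]
  y <- co$outcome[lab]
  suite <- baseline_suite(X[1:600, ], y[1:600], X[601:nrow(X), ],
                          y[601:length(y)], seed = 4)
  expect_equal(names(suite$rf$importance)[1], "driver")
  expect_equal(names(suite$gbdt$importance)[1], "driver")
})

test_that("a degenerate training set is captured per classifier", {
  X <- matrix(0.5, 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rep(0, 10)
  suite <- suppressWarnings(baseline_suite(X, y, X, y, seed = 1))
  expect_s3_class(suite, "baseline_suite")
  # at least some classifiers must refuse a single-class constant fit,
  # and the suite still returns an entry for every classifier
  expect_length(suite, 6)
})
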