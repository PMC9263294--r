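test_that("wrong-judgment rates are mismatch fractions", {
  preds <- cbind(c(1, 0, 1), c(1, 1, 1), c(0, 0, 1), c(1, 0, 0))
  tab <- compute_wjr(c(1, 0, 0), preds)
  expect_equal(tab$wjr, c(1 / 4, 1 / 4, 3 / 4))
  expect_equal(attr(tab, "R"), 4L)

  n <- 5; R <- 20
  truth <- rbinom(n, 1, 0.5)
  allright <- matrix(truth, n, R)
  expect_equal(compute_wjr(truth, allright)$wjr, rep(0, n))
  expect_equal(compute_wjr(truth, 1 - allright)$wjr, rep(1, n))
  # wrong in 5 of 20 runs -> 0.25
  one <- matrix(0, 1, R); one[1, 1:5] <- 1
  expect_equal(compute_wjr(0, one)$wjr, 0.25)
  expect_error(compute_wjr(truth, matrix(nrow = n, ncol = 0)),
               "at least one")
})

test_that("subgroup assignment follows the strict WJR cuts", {
  tab <- data.frame(
    id = 1:8,
    true_label = c(0, 0, 0, 1, 1, 1, 0, 1),
    wjr = c(0.1, 0.8, 0.5, 0.1, 0.8, 0.5, 0.25, 0.75)
  )
  class(tab) <- c("wjr_table", "data.frame")
  g <- assign_subgroups(tab)$subgroup
  expect_equal(as.character(g),
               c("TNG", "FPG", "other", "TPG", "FNG", "other",
                 "other", "other"))  # boundary values land in "other"
  expect_error(assign_subgroups(tab, lo = 0.8, hi = 0.2), "smaller")
})

test_that("subgroup partition is exhaustive and exclusive", {
  set.seed(55)
  for (i in 1:10) {
    n <- sample(20:100, 1)
    truth <- rbinom(n, 1, 0.4)
    preds <- matrix(rbinom(n * 10, 1, 0.5), n, 10)
    tab <- assign_subgroups(compute_wjr(truth, preds))
    counts <- table(tab$subgroup)
    expect_equal(sum(counts), n)
    expect_true(all(tab$wjr >= 0 & tab$wjr <= 1))
  }
})

test_that("effective proportions are group prevalences or means", {
  g <- factor(c("TNG", "TNG", "TNG", "TNG", "FPG", "FPG"),
              levels = c("TNG", "FPG", "TPG", "FNG"))
  expect_equal(unname(effective_proportion(c(1, 1, 0, 0, 1, 1), g)),
               c(0.5, 1, NA, NA))
  expect_equal(unname(effective_proportion(c(1, 3, 1, 3, 2, 2), g))[1:2],
               c(2, 2))
  expect_equal(unname(effective_proportion(rep(0, 6), g))[1], 0)
})

test_that("death threat coefficients flag by both ratios", {
  fep <- data.frame(TNG = c(0.4, 0.2, 0.5, 0),
                    FPG = c(0.6, 0.2, 0.5, 0.3),
                    TPG = c(0.6, 0.2, 0.9, 0.3),
                    FNG = c(0.4, 0.2, 0.5, 0.1),
                    row.names = c("a", "b", "c", "d"))
  expect_warning(rep_ <- death_threat_coefficient(fep), "zero denominator")
  expect_equal(rep_$dtc_fpg_tng[1], 1.5)
  expect_equal(rep_$dtc_tpg_fng[1], 1.5)
  expect_true(rep_$flagged[1])
  # all Feps equal -> both ratios 1, not flagged
  expect_equal(rep_$dtc_fpg_tng[2], 1)
  expect_false(rep_$flagged[2])
  # only one ratio elevated -> not flagged
  expect_false(rep_$flagged[3])
  # zero denominator -> undefined, not flagged
  expect_true(is.na(rep_$dtc_fpg_tng[4]))
  expect_false(rep_$flagged[4])
})

test_that("Dtc is scale invariant for continuous features", {
  g <- factor(rep(c("TNG", "FPG", "TPG", "FNG"), each = 5),
              levels = c("TNG", "FPG", "TPG", "FNG"))
  set.seed(10)
  x <- runif(20, 1, 2)
  base <- death_threat_coefficient(t(as.matrix(effective_proportion(x, g))))
  scaled <- death_threat_coefficient(t(as.matrix(effective_proportion(3.7 * x, g))))
  expect_equal(scaled$dtc_fpg_tng, base$dtc_fpg_tng)
  expect_equal(scaled$dtc_tpg_fng, base$dtc_tpg_fng)
})

test_that("an always-correct predictor yields identically zero WJR", {
  truth <- rbinom(30, 1, 0.5)
  preds <- matrix(truth, 30, 6)
  tab <- assign_subgroups(compute_wjr(truth, preds))
  expect_true(all(tab$wjr == 0))
  expect_true(all(tab$subgroup[truth == 0] == "TNG"))
  expect_true(all(tab$subgroup[truth == 1] == "TPG"))
})

test_that("repeated trainings vary by seed and resample but stay reproducible", {
  sp <- tiny_spec(n_total = 260, n_censored = 60, seed = 12,
                  death_fraction = 0.35)
  co <- generate_cohort(sp)
  X <- normalize_features(cohort_features(co))$X
  lab <- co$followed == 1
  idx <- which(lab)
  tr <- idx[1:150]; te <- idx[151:length(idx)]
  cfg <- fast_cfg(ncol(X), epochs = 60)
  preds <- wjr_replication(X[tr, ], co$outcome[tr], X[te, ], R = 3,
                           net_cfg = cfg, loss_cfg = fast_loss(),
                           method = "supervised", seed = 77)
  expect_equal(dim(preds), c(length(te), 3L))
  expect_true(all(preds %in% c(0, 1)))
  preds2 <- wjr_replication(X[tr, ], co$outcome[tr], X[te, ], R = 3,
                            net_cfg = cfg, loss_cfg = fast_loss(),
                            method = "supervised", seed = 77)
  expect_identical(preds, preds2)
  # columns differ across runs (different seeds/resamples)
  expect_false(all(preds[, 1] == preds[, 2]) && all(preds[, 2] == preds[, 3]))
})
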