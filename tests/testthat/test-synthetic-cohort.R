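test_that("default spec reproduces the reference cohort structure", {
  sp <- default_spec()
  expect_equal(sp$n_total, 2444L)
  expect_equal(sp$n_censored, 1074L)
  expect_equal(sp$death_fraction_labeled, 233 / 1370)
  expect_equal(nrow(sp$features), 117L)
  cp <- subset(sp$features, name == "cardiopulmonary")
  expect_equal(cp$prevalence_death, 0.3562, tolerance = 1e-4)
  expect_equal(cp$prevalence_survival, 0.1750, tolerance = 1e-4)
  # features with large group contrasts carry positive hazard weight
  expect_gt(subset(sp$features, name == "neuropsychiatric")$hazard_weight, 0)
  expect_gt(subset(sp$features, name == "cardiopulmonary")$hazard_weight, 0)
})

test_that("spec validation rejects inconsistent inputs", {
  expect_error(cohort_spec(100, 120, 0.2, tiny_features()), "n_censored")
  expect_error(cohort_spec(100, 20, 1.2, tiny_features()),
               "death_fraction_labeled")
  expect_error(feature_spec("bad", "binary", 1.3, 0.5), "\\[0, 1\\]")
  expect_error(feature_spec("bad", "continuous", mean_survival = 0,
                            sd_survival = -1, mean_death = 0, sd_death = 1),
               "positive SDs")
})

test_that("identical seeds give bit-identical cohorts", {
  a <- generate_cohort(tiny_spec(seed = 7))
  b <- generate_cohort(tiny_spec(seed = 7))
  expect_identical(a, b)
  c <- generate_cohort(tiny_spec(seed = 8))
  expect_false(identical(a$time, c$time))
})

test_that("cohort counts are conserved and censored outcomes hidden", {
  co <- generate_cohort(tiny_spec())
  expect_equal(sum(co$followed == 1) + sum(co$followed == 0), 400L)
  expect_true(all(is.na(co$outcome[co$followed == 0])))
  expect_true(all(co$outcome[co$followed == 1] %in% c(0, 1)))
  lab <- co$outcome[co$followed == 1]
  expect_equal(sum(lab == 0) + sum(lab == 1), sum(co$followed == 1))
})

test_that("labeled death count is a binomial draw at the spec fraction", {
  sp <- cohort_spec(2444, 1074, 0.17, tiny_features(), seed = 11)
  co <- generate_cohort(sp)
  n_lab <- sum(co$followed == 1)
  deaths <- sum(co$outcome[co$followed == 1] == 1)
  expect_equal(n_lab, 1370L)
  sd3 <- 3 * sqrt(n_lab * 0.17 * 0.83)
  expect_lt(abs(deaths - n_lab * 0.17), sd3)
})

test_that("realized group prevalences match the calibrated targets", {
  co <- generate_cohort(default_spec(seed = 19))
  lab <- co[co$followed == 1, ]
  sp <- attr(co, "spec")
  for (f in c("cardiopulmonary", "renal", "neuropsychiatric", "anti_sm")) {
    row <- subset(sp$features, name == f)
    for (g in 0:1) {
      grp <- lab[lab$outcome == g, f]
      target <- if (g == 1) row$prevalence_death else row$prevalence_survival
      sd3 <- 3 * sqrt(target * (1 - target) / length(grp))
      expect_lt(abs(mean(grp) - target), sd3)
    }
  }
})

test_that("raising a hazard weight shortens survival in that stratum", {
  mean_death_time <- function(hw, seed) {
    fs <- tiny_features()
    fs$hazard_weight[fs$name == "driver"] <- hw
    sp <- cohort_spec(800, 10, 0.4, fs, baseline_hazard = 0.02, seed = seed)
    co <- generate_cohort(sp)
    lab <- co[co$followed == 1 & co$outcome == 1 & co$driver == 1, ]
    mean(lab$time)
  }
  lo <- sapply(1:4, function(s) mean_death_time(0.2, s))
  hi <- sapply(1:4, function(s) mean_death_time(2.5, s))
  expect_true(all(hi < lo))
})

test_that("null hazard weights leave feature strata exchangeable", {
  fs <- tiny_features()
  fs$hazard_weight <- 0
  sp <- cohort_spec(600, 10, 0.3, fs, seed = 3)
  co <- generate_cohort(sp)
  lab <- co[co$followed == 1, ]
  # a pure-noise feature splits the cohort into indistinguishable strata
  sd <- survival::survdiff(survival::Surv(time, outcome) ~ noise_01,
                           data = lab)
  expect_gt(1 - stats::pchisq(sd$chisq, 1), 0.001)
})

test_that("hazard outcome law produces a proportional-hazards cohort", {
  sp <- tiny_spec(n_total = 1500, n_censored = 10, seed = 5,
                  outcome_law = "hazard")
  co <- generate_cohort(sp)
  lab <- co[co$followed == 1, ]
  fit <- survival::coxph(survival::Surv(time, outcome) ~ driver, data = lab)
  expect_equal(unname(coef(fit)), 1.5, tolerance = 0.25)
})

test_that("medication-dependent censoring tracks the medication features", {
  fs <- rbind(tiny_features(),
              feature_spec("prednisone", "binary", 0.7, 0.7),
              feature_spec("cyclophosphamide", "binary", 0.4, 0.4))
  sp <- cohort_spec(3000, 1200, 0.25, fs,
                    censoring_mode = "medication_dependent", seed = 9)
  co <- generate_cohort(sp)
  cens_rate_pred <- tapply(co$followed == 0, co$prednisone, mean)
  cens_rate_cyc <- tapply(co$followed == 0, co$cyclophosphamide, mean)
  expect_gt(cens_rate_pred["1"], cens_rate_pred["0"])
  expect_lt(cens_rate_cyc["1"], cens_rate_cyc["0"])
})

test_that("cohort CSV and spec JSON round-trip", {
  sp <- tiny_spec(seed = 2)
  co <- generate_cohort(sp)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, csv)
  back <- read_cohort(csv)
  expect_equal(back$outcome, co$outcome)
  expect_equal(back$time, co$time, tolerance = 1e-12)
  expect_equal(cohort_features(back), cohort_features(co), tolerance = 1e-12)

  js <- withr::local_tempfile(fileext = ".json")
  write_cohort_spec(sp, js)
  sp2 <- read_cohort_spec(js)
  expect_equal(sp2$n_total, sp$n_total)
  expect_equal(sp2$features$prevalence_death, sp$features$prevalence_death)
  expect_equal(sp2$death_fraction_censored, sp$death_fraction_censored)
  co2 <- generate_cohort(sp2)
  expect_equal(co2$outcome, co$outcome)
  expect_equal(co2$time, co$time)
  expect_equal(cohort_features(co2), cohort_features(co))
})
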