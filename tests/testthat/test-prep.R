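# Cohort preparation: exclusion rules and tallies, look-back feature
# construction, ON-Marg dichotomization, and the two splitting schemes.

test_that("exclusions remove the right rows with an exact tally", {
  adm <- tiny_admissions() # 2 under-65, 1 LTC, 1 missing instability
  res <- apply_exclusions(adm)
  expect_equal(res$tally$age, 2)
  expect_equal(res$tally$ltc, 1)
  expect_equal(res$tally$missing, 1)
  expect_equal(res$tally$retained, 6)
  expect_true(all(res$admissions$age >= 65))
  expect_true(all(res$admissions$from_ltc == 0))
  expect_false(anyNA(res$admissions$onmarg_instability))
})

test_that("a row violating several rules is counted once, in rule order", {
  adm <- tiny_admissions()[1:2, ]
  adm$age[1] <- 60; adm$from_ltc[1] <- 1L # age AND LTC -> counted under age
  res <- apply_exclusions(adm)
  expect_equal(res$tally$age, 1)
  expect_equal(res$tally$ltc, 0)
})

test_that("valid input passes through unchanged; empty input gives zero tally", {
  adm <- tiny_admissions()
  adm <- adm[adm$age >= 65 & adm$from_ltc == 0 & !is.na(adm$onmarg_instability), ]
  res <- apply_exclusions(adm)
  expect_equal(nrow(res$admissions), nrow(adm))
  expect_equal(res$tally$age + res$tally$ltc + res$tally$missing, 0)
  empty <- apply_exclusions(adm[0, ])
  expect_equal(empty$tally$retained, 0)
  expect_equal(nrow(empty$admissions), 0)
})

test_that("exclusion tally conserves rows on random cohorts", {
  for (s in 1:5) {
    sim <- generate_admissions(synth_config(n_patients = 200, seed = s))
    t <- apply_exclusions(sim$admissions)$tally
    expect_equal(t$age + t$ltc + t$missing + t$retained, t$input)
  }
})

make_history_fixture <- function(days_before, flags_by_row) {
  n <- length(days_before)
  adm <- tiny_admissions()[rep(2, n), ]
  adm$patient_id <- "PX"
  adm$admission_date <- as.Date("2015-06-01") - days_before
  adm$from_ltc <- 0L
  for (i in seq_len(n)) for (f in flags_by_row[[i]]) adm[[f]][i] <- 1L
  rownames(adm) <- NULL
  adm
}

test_that("look-back window is half-open and 730 days long", {
  # prior fall 800 days before index: outside the window
  adm <- make_history_fixture(c(800, 0), list("fall", character(0)))
  X <- build_lookback_features(adm)$features
  expect_equal(unname(X[2, "fall_hist"]), 0)
  # prior fall 100 days before index: inside
  adm <- make_history_fixture(c(100, 0), list("fall", character(0)))
  X <- build_lookback_features(adm)$features
  expect_equal(unname(X[2, "fall_hist"]), 1)
  # a fall on the index admission itself does not count as history
  adm <- make_history_fixture(c(0), list("fall"))
  X <- build_lookback_features(adm)$features
  expect_equal(unname(X[1, "fall_hist"]), 0)
  # exactly at the window edge (730 days) is included; the index day is not
  adm <- make_history_fixture(c(730, 0), list("fall", character(0)))
  X <- build_lookback_features(adm)$features
  expect_equal(unname(X[2, "fall_hist"]), 1)
  expect_error(build_lookback_features(adm, window_days = 0), "positive")
})

test_that("history flags union over in-window prior admissions", {
  adm <- make_history_fixture(c(400, 200, 0),
                              list("fall", "fracture", character(0)))
  X <- build_lookback_features(adm)$features
  expect_equal(unname(X[3, c("fall_hist", "fracture_hist")]), c(1, 1))
  expect_equal(unname(X[3, "rehab_hist"]), 0)
})

test_that("chronic condition flags count on the index admission", {
  adm <- make_history_fixture(c(0), list("dementia"))
  X <- build_lookback_features(adm)$features
  expect_equal(unname(X[1, "dementia"]), 1)
})

test_that("look-back features are invariant to input row order", {
  sim <- generate_admissions(synth_config(n_patients = 150, seed = 21))
  adm <- apply_exclusions(sim$admissions)$admissions
  shuffled <- adm[sample(nrow(adm)), ]
  a <- build_lookback_features(adm)
  b <- build_lookback_features(shuffled)
  key_a <- paste(a$patient_id, a$admission_date)
  key_b <- paste(b$patient_id, b$admission_date)
  expect_equal(a$features[order(key_a), ], b$features[order(key_b), ])
})

test_that("ON-Marg dichotomization separates Q5 from the rest", {
  expect_equal(dichotomize_onmarg(c(5L, 4L, 1L)), c(1L, 0L, 0L))
  expect_error(dichotomize_onmarg(6L), "1..5")
  expect_equal(dichotomize_onmarg(NA_integer_), NA_integer_)
})

test_that("patient-level split is disjoint, sized, and deterministic", {
  sim <- generate_admissions(synth_config(n_patients = 100,
                                          mean_admissions_per_patient = 3,
                                          seed = 12))
  cohort <- build_lookback_features(sim$admissions)
  sp <- split_by_patient(cohort, 0.1, seed = 5)
  test_pats <- unique(sp$test$patient_id)
  expect_length(test_pats, 10)
  expect_length(intersect(unique(sp$train$patient_id), test_pats), 0)
  # all admissions of each test patient travel together
  n_by_pat <- table(cohort$patient_id)
  expect_equal(sum(n_by_pat[test_pats]), length(sp$test$outcome))
  sp2 <- split_by_patient(cohort, 0.1, seed = 5)
  expect_identical(sp$test$patient_id, sp2$test$patient_id)
  expect_error(split_by_patient(cohort, 1.2), "\\(0, 1\\)")
})

test_that("temporal split assigns by each patient's first admission year", {
  adm <- tiny_admissions()
  adm$from_ltc <- 0L; adm$onmarg_instability <- 3L; adm$age <- 80
  adm$patient_id <- c(rep("A", 2), rep("B", 2), rep("C", 6))
  adm$admission_date <- as.Date(c("2010-05-01", "2018-07-01",  # A: train
                                  "2015-03-01", "2016-01-01",  # B: test
                                  rep("2014-12-31", 6)))       # C: train
  cohort <- build_lookback_features(adm)
  sp <- temporal_split(cohort, cutoff_year = 2014)
  expect_setequal(unique(sp$train$patient_id), c("A", "C"))
  expect_setequal(unique(sp$test$patient_id), "B")
  # A's 2018 admission stays in train with its patient
  expect_equal(sum(sp$train$patient_id == "A"), 2)
  # cohort entirely pre-cutoff -> empty test
  early <- build_lookback_features(adm[adm$admission_date < as.Date("2015-01-01"), ])
  sp2 <- temporal_split(early, 2014)
  expect_equal(length(sp2$test$outcome), 0)
})

test_that("rebalancing alters training data only, as requested", {
  sim <- generate_admissions(synth_config(n_patients = 500, seed = 13))
  cohort <- build_lookback_features(apply_exclusions(sim$admissions)$admissions)
  n1 <- sum(cohort$outcome == 1)
  down <- rebalance_training(cohort, "downsample", seed = 1)
  expect_equal(sum(down$outcome == 1), n1)
  expect_equal(sum(down$outcome == 0), n1)
  down2 <- rebalance_training(cohort, "downsample", seed = 1)
  expect_identical(down$patient_id, down2$patient_id)
  none <- rebalance_training(cohort, "none")
  expect_identical(none$features, cohort$features)
  cw <- rebalance_training(cohort, "class_weight")
  expect_identical(cw$features, cohort$features)
  expect_equal(sum(cw$weights[cw$outcome == 1]),
               sum(cw$weights[cw$outcome == 0]))
  single <- .subset_cohort_for_test(cohort, which(cohort$outcome == 0))
  expect_error(rebalance_training(single, "downsample"), "both")
})
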