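# Explainability operators: permutation importance, profiles, Shapley and
# breakdown attributions, with brute-force coalition oracles.

# small 3-feature logistic model with known coefficients
toy_model <- function(beta = c("(Intercept)" = -1, a = 1.5, b = -0.8, c = 0)) {
  lr_model_with_beta(beta)
}

toy_background <- function(n = 40, p = 3, seed = 1) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 1, 0.4), n, p)
  colnames(X) <- letters[seq_len(p)]
  X
}

test_that("permutation importance nulls out unused features", {
  cohort <- small_cohort()
  m <- small_lr()
  imp <- permutation_importance(m, cohort, n_repeats = 5, seed = 2)
  expect_lt(abs(imp$importance[imp$feature == "noise_hist"]), 0.005)
  expect_gt(imp$importance[imp$feature == "care_support_hist"], 0.01)
  imp2 <- permutation_importance(m, cohort, n_repeats = 5, seed = 2)
  expect_identical(imp, imp2)
  expect_error(permutation_importance(m, cohort, n_repeats = 1), "at least 2")
})

test_that("permuting the only informative feature destroys all signal", {
  set.seed(3)
  n <- 4000
  X <- cbind(a = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, sigmoid(-1 + 2 * X[, "a"]))
  m <- lr_model_with_beta(c("(Intercept)" = -1, a = 2))
  cohort <- structure(list(features = X, outcome = y,
                           attributes = data.frame(row = seq_len(n)),
                           patient_id = as.character(seq_len(n)),
                           admission_date = rep(Sys.Date(), n),
                           weights = NULL), class = "cohort_matrix")
  imp <- permutation_importance(m, cohort, n_repeats = 10, seed = 4)
  base <- imp$baseline_auc[1]
  expect_lt(abs(imp$importance[1] - (base - 0.5)), 0.02)
})

test_that("partial dependence matches direct averaging and flatness", {
  m <- toy_model()
  X <- toy_background()
  pdp_a <- partial_dependence(m, X, "a", c(0, 1))
  expect_equal(nrow(pdp_a), 2)
  f <- function(Z) sigmoid(-1 + 1.5 * Z[, "a"] - 0.8 * Z[, "b"])
  for (g in c(0, 1)) {
    Xg <- X; Xg[, "a"] <- g
    expect_equal(pdp_a$prediction[pdp_a$value == g], mean(f(Xg)),
                 tolerance = 1e-12)
  }
  # per-row log-odds gap between the two grid points is exactly beta_a
  p1 <- f(`[<-`(X, , "a", 1)); p0 <- f(`[<-`(X, , "a", 0))
  expect_equal(unique(round(logit(p1) - logit(p0), 10)), 1.5)
  # ignored feature -> flat profile
  pdp_c <- partial_dependence(m, X, "c", c(0, 1))
  expect_equal(diff(pdp_c$prediction), 0)
  expect_error(partial_dependence(m, X[0, , drop = FALSE], "a"), "empty")
})

test_that("ceteris paribus sweeps one instance with closed-form effects", {
  m <- toy_model()
  inst <- matrix(c(1, 0, 1), 1, dimnames = list(NULL, c("a", "b", "c")))
  cp <- ceteris_paribus(m, inst, "b", c(0, 1))
  # flipping the flag moves the log-odds by exactly its coefficient
  expect_equal(diff(logit(cp$prediction)), -0.8, tolerance = 1e-12)
  # endpoints equal direct predictions of the two modified instances
  for (g in c(0, 1)) {
    inst_g <- inst; inst_g[, "b"] <- g
    expect_equal(cp$prediction[cp$value == g], predict(m, inst_g),
                 tolerance = 1e-15)
  }
  cp_c <- ceteris_paribus(m, inst, "c", c(0, 1))
  expect_equal(diff(cp_c$prediction), 0)
})

test_that("PDP of a flag is the mean of the ceteris-paribus endpoints", {
  m <- toy_model()
  X <- toy_background(n = 25)
  pdp <- partial_dependence(m, X, "a", c(0, 1))
  cps <- vapply(seq_len(nrow(X)), function(i) {
    ceteris_paribus(m, X[i, , drop = FALSE], "a", c(0, 1))$prediction
  }, numeric(2))
  expect_equal(pdp$prediction, unname(rowMeans(cps)), tolerance = 1e-12)
})

test_that("exact Shapley equals full coalition enumeration", {
  X <- toy_background(n = 30)
  inst <- matrix(c(1, 1, 0), 1, dimnames = list(NULL, c("a", "b", "c")))
  # logistic model
  m <- toy_model()
  att <- shapley_attributions(m, inst, X, mode = "exact")
  f <- function(Z) sigmoid(-1 + 1.5 * Z[, "a"] - 0.8 * Z[, "b"])
  expect_equal(att$contributions, bf_shapley(f, inst[1, ], X),
               tolerance = 1e-10)
  # gradient-boosted model, same oracle
  cohort <- small_cohort()
  idx <- c("age", "dementia", "fall_hist")
  Xs <- cohort$features[1:200, idx]
  sub <- structure(list(features = Xs, outcome = cohort$outcome[1:200],
                        attributes = cohort$attributes[1:200, ],
                        patient_id = cohort$patient_id[1:200],
                        admission_date = cohort$admission_date[1:200],
                        weights = NULL), class = "cohort_matrix")
  if (length(unique(sub$outcome)) == 2) {
    g <- dhd_fit(sub, "gbt",
                 grid = data.frame(max_depth = 2L, eta = 0.4, nrounds = 20L))
    bg <- Xs[1:25, ]
    inst2 <- Xs[7, , drop = FALSE]
    att_g <- shapley_attributions(g, inst2, bg, mode = "exact")
    fg <- dhdrisk:::.predictor(g)
    expect_equal(att_g$contributions, bf_shapley(fg, inst2[1, ], bg),
                 tolerance = 1e-10)
    expect_equal(att_g$baseline + sum(att_g$contributions), att_g$prediction,
                 tolerance = 1e-10)
  }
})

test_that("Shapley satisfies additivity and symmetry in closed form", {
  # only feature a matters: its attribution is the full gap to baseline
  m1 <- lr_model_with_beta(c("(Intercept)" = -0.5, a = 2, b = 0, c = 0))
  X <- toy_background(n = 50)
  inst <- matrix(c(1, 0, 1), 1, dimnames = list(NULL, c("a", "b", "c")))
  att <- shapley_attributions(m1, inst, X, mode = "exact")
  expect_equal(unname(att$contributions[c("b", "c")]), c(0, 0),
               tolerance = 1e-12)
  expect_equal(unname(att$contributions["a"]), att$prediction - att$baseline,
               tolerance = 1e-12)
  # symmetric features with identical values get identical attributions
  m2 <- lr_model_with_beta(c("(Intercept)" = -1, a = 1.1, b = 1.1, c = 0))
  Xs <- X; Xs[, "b"] <- Xs[, "a"] # identical empirical roles
  inst2 <- matrix(c(1, 1, 0), 1, dimnames = list(NULL, c("a", "b", "c")))
  att2 <- shapley_attributions(m2, inst2, Xs, mode = "exact")
  expect_equal(att2$contributions[["a"]], att2$contributions[["b"]],
               tolerance = 1e-12)
})

test_that("sampled Shapley converges to the exact values", {
  m <- toy_model(c("(Intercept)" = -0.5, a = 1.2, b = -0.9, c = 0.6,
                   d = -0.4, e = 0.8))
  set.seed(5)
  X <- matrix(rbinom(20 * 5, 1, 0.5), 20, 5,
              dimnames = list(NULL, c("a", "b", "c", "d", "e")))
  inst <- matrix(c(1, 0, 1, 1, 0), 1,
                 dimnames = list(NULL, c("a", "b", "c", "d", "e")))
  exact <- shapley_attributions(m, inst, X, mode = "exact")
  samp <- shapley_attributions(m, inst, X, mode = "sampled",
                               n_samples = 10000, seed = 6)
  expect_lt(max(abs(samp$contributions - exact$contributions)), 0.01)
  # local accuracy holds exactly: each permutation telescopes
  expect_equal(samp$baseline + sum(samp$contributions), samp$prediction,
               tolerance = 1e-12)
  expect_error(
    shapley_attributions(m, inst, X, mode = "exact", id = 1)
    , NA)
  wide <- matrix(0, 1, 13, dimnames = list(NULL, paste0("f", 1:13)))
  m13 <- lr_model_with_beta(c("(Intercept)" = 0,
                              stats::setNames(rep(0.1, 13), paste0("f", 1:13))))
  expect_error(shapley_attributions(m13, wide, wide, mode = "exact"),
               "sampled")
})

test_that("breakdown telescopes exactly and is order-dependent", {
  m <- toy_model() # sigmoid link makes contributions order-dependent
  X <- toy_background(n = 40)
  inst <- matrix(c(1, 1, 1), 1, dimnames = list(NULL, c("a", "b", "c")))
  bd1 <- breakdown_attributions(m, inst, X, order = c("a", "b", "c"))
  bd2 <- breakdown_attributions(m, inst, X, order = c("b", "a", "c"))
  expect_equal(bd1$baseline + sum(bd1$contributions), bd1$prediction,
               tolerance = 1e-12)
  expect_equal(sum(bd1$contributions), sum(bd2$contributions),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(bd1$contributions["a"],
                                bd2$contributions["a"])))
  expect_error(breakdown_attributions(m, inst, X, order = c("a", "a", "b")),
               "duplicate")
  expect_error(breakdown_attributions(m, inst, X, order = c("a", "b")),
               "cover")
})

test_that("auto breakdown order sorts by single-fix absolute effect", {
  m <- toy_model(c("(Intercept)" = 0, a = 0.3, b = -2.5, c = 0))
  X <- toy_background(n = 60, seed = 7)
  inst <- matrix(c(1, 1, 1), 1, dimnames = list(NULL, c("a", "b", "c")))
  bd <- breakdown_attributions(m, inst, X, order = "auto")
  f <- dhdrisk:::.predictor(m)
  base <- mean(f(X))
  single <- vapply(c("a", "b", "c"), function(j) {
    Xj <- X; Xj[, j] <- inst[1, j]
    abs(mean(f(Xj)) - base)
  }, numeric(1))
  expect_equal(names(bd$contributions)[1], names(which.max(single)))
})

test_that("breakdown equals Shapley when only one feature matters", {
  m <- lr_model_with_beta(c("(Intercept)" = -0.5, a = 2, b = 0, c = 0))
  X <- toy_background(n = 30)
  inst <- matrix(c(1, 0, 0), 1, dimnames = list(NULL, c("a", "b", "c")))
  sh <- shapley_attributions(m, inst, X, mode = "exact")
  for (ord in list(c("a", "b", "c"), c("c", "b", "a"))) {
    bd <- breakdown_attributions(m, inst, X, order = ord)
    expect_equal(bd$contributions[names(sh$contributions)],
                 sh$contributions, tolerance = 1e-12)
  }
})
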