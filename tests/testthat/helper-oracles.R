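# Independent oracles and shared fixtures. Oracles are deliberately naive
# (O(n^2) enumeration, full coalition sweeps, power iteration) and never call
# the code paths they check.

# brute-force AUC: enumerate every positive/negative pair, ties count 1/2
bf_auc <- function(scores, outcomes) {
  pos <- scores[outcomes == 1]
  neg <- scores[outcomes == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# brute-force cross-group AUC from explicit score cells
bf_xauc <- function(pos_scores, neg_scores) bf_auc(
  c(pos_scores, neg_scores),
  c(rep(1, length(pos_scores)), rep(0, length(neg_scores))))

# brute-force Shapley over all coalitions for a prediction function f(X)
bf_shapley <- function(f, instance, background) {
  p <- length(instance)
  value <- function(S) {
    Xb <- background
    if (length(S)) Xb[, S] <- matrix(instance[S], nrow(background),
                                     length(S), byrow = TRUE)
    mean(f(Xb))
  }
  phi <- numeric(p)
  for (j in seq_len(p)) {
    others <- setdiff(seq_len(p), j)
    for (k in 0:length(others)) {
      subsets <- if (k == 0) list(integer(0)) else
        asplit(utils::combn(others, k), 2)
      w <- factorial(k) * factorial(p - k - 1) / factorial(p)
      for (S in subsets) {
        phi[j] <- phi[j] + w * (value(c(S, j)) - value(S))
      }
    }
  }
  names(phi) <- colnames(background)
  phi
}

# leading eigenpairs of a symmetric PSD matrix by power iteration with
# deflation; iterates on an even matrix power for fast, sign-safe convergence
bf_eigen <- function(A, iter = 20000, tol = 1e-26) {
  p <- nrow(A)
  vals <- numeric(p)
  vecs <- matrix(0, p, p)
  M <- A
  for (k in seq_len(p)) {
    P <- M %*% M; P <- P %*% P; P <- P %*% P # M^8
    v <- rep(1 / sqrt(p), p)
    for (i in seq_len(iter)) {
      v2 <- P %*% v
      nrm <- sqrt(sum(v2^2))
      if (nrm == 0) break # deflated to the null space
      v2 <- v2 / nrm
      if (sum((v2 - v)^2) < tol && i > 5) { v <- v2; break }
      v <- v2
    }
    lam <- as.numeric(t(v) %*% M %*% v)
    vals[k] <- lam
    vecs[, k] <- v
    M <- M - lam * (v %*% t(v))
  }
  list(values = vals, vectors = vecs)
}

# brute-force expected (Bayes) AUC over all i != j pairs of true probabilities
bf_expected_auc <- function(p) {
  num <- den <- 0
  for (i in seq_along(p)) for (j in seq_along(p)) {
    if (i == j) next
    w <- p[i] * (1 - p[j])
    den <- den + w
    num <- num + w * (if (p[i] > p[j]) 1 else if (p[i] == p[j]) 0.5 else 0)
  }
  num / den
}

# ten hand-built admissions exercising each exclusion rule
tiny_admissions <- function() {
  base <- data.frame(
    patient_id = sprintf("T%02d", 1:10),
    admission_date = as.Date("2010-06-01") + 0:9,
    age = c(64, 70, 64.9, 75, 80, 85, 90, 72, 68, 77),
    sex = rep(c("female", "male"), 5),
    region = rep(c("Eastern", "Northern"), 5),
    residency = rep(c("urban", "rural"), 5),
    income_quintile = rep(1:5, 2),
    onmarg_ethnic = rep(3L, 10),
    onmarg_dependency = rep(2L, 10),
    onmarg_instability = c(rep(5L, 9), 5L),
    onmarg_deprivation = rep(4L, 10),
    stringsAsFactors = FALSE
  )
  for (f in c("care_support", "fall", "fracture", "rehab", "palliative",
              "noise", "dementia", "mobility", "comorbidity"))
    base[[f]] <- 0L
  base$from_ltc <- c(0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L)
  base$onmarg_instability[5] <- NA_integer_
  base$dhd_90d <- rep(c(0L, 1L), 5)
  base
}

# session-level cache for expensive simulations
.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# ~1e5-admission cohort used by recovery and convergence checks
big_sim <- function() cached("big_sim", {
  generate_admissions(synth_config(n_patients = 50000, seed = 1))
})

big_cohort <- function() cached("big_cohort", {
  build_lookback_features(apply_exclusions(big_sim()$admissions)$admissions)
})

# small cohort for fast structural tests
small_sim <- function() cached("small_sim", {
  generate_admissions(synth_config(n_patients = 2500, seed = 11))
})

small_cohort <- function() cached("small_cohort", {
  build_lookback_features(apply_exclusions(small_sim()$admissions)$admissions)
})

# a fast logistic model on the small cohort
small_lr <- function() cached("small_lr", {
  dhd_fit(small_cohort(), "lr")
})

.subset_cohort_for_test <- function(cohort, idx) dhdrisk:::.subset_cohort(cohort, idx)

# hand-built dhd_model with known logistic coefficients
lr_model_with_beta <- function(beta) {
  structure(list(learner = "lr", fit = list(beta = beta),
                 hyperparameters = list(lambda = 0), cv_results = NULL,
                 feature_names = names(beta)[-1], n = 0L, seed = 0L,
                 calibrator = NULL, calibrator_attribute = NULL),
            class = "dhd_model")
}
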