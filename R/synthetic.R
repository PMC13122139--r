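# Synthetic admission cohorts with a known logistic ground truth.
#
# The generator emulates the structure of an Ontario-style administrative
# discharge cohort of older adults: repeated admissions per patient,
# ~9% prevalence of delayed hospital discharge (DHD) within 90 days,
# subgroup mixes taken from published descriptive tables, and configurable
# group-specific calibration distortions. Outcomes are drawn from a logistic
# model on the SAME look-back feature matrix that the preparation stage
# constructs, so parameter-recovery tests are well-posed.

# flags recorded per admission; "event" flags become history features via the
# look-back window, "condition" flags are current chronic states
.event_flags <- c("care_support", "fall", "fracture", "rehab", "palliative", "noise")
.condition_flags <- c("dementia", "mobility", "comorbidity")
.regions <- c("Eastern", "Central", "Metropolitan", "Southwestern", "Northern")
.onmarg_cols <- c("onmarg_ethnic", "onmarg_dependency", "onmarg_instability",
                  "onmarg_deprivation")

#' Model feature names used by the ground truth and the preparation stage
#' @return character vector of feature-column names of a cohort matrix.
#' @export
dhd_feature_names <- function() {
  c("age", "female", "rural", "income_q1",
    "ethnic_q5", "dependency_q5", "instability_q5", "deprivation_q5",
    paste0("region_", tolower(.regions[-1])),
    paste0(setdiff(.event_flags, "noise"), "_hist"), "noise_hist",
    .condition_flags)
}

#' Default ground-truth log-odds coefficients
#'
#' The largest weights sit on care-support history, dementia, rehabilitation
#' discharge history, fracture history and a linear age term; a designated
#' pure-noise feature (`noise_hist`) always carries weight 0 for
#' permutation-importance null tests. The overall scale was fixed once so
#' that the implied Bayes AUC of the default cohort is approximately 0.82.
#'
#' @return named numeric vector of log-odds weights per feature.
#' @export
default_coefficients <- function() {
  c(age = 0.048,
    female = 0.31, rural = -0.105, income_q1 = 0.16,
    ethnic_q5 = 0.0, dependency_q5 = 0.105, instability_q5 = 0.31,
    deprivation_q5 = 0.16,
    region_central = 0.21, region_metropolitan = 0.105,
    region_southwestern = 0.053, region_northern = 0.37,
    care_support_hist = 1.58, fall_hist = 0.75, fracture_hist = 0.97,
    rehab_hist = 1.14, palliative_hist = 0.53, noise_hist = 0,
    dementia = 1.50, mobility = 0.97, comorbidity = 0.53)
}

#' Configuration for the synthetic admission generator
#'
#' @param n_patients number of distinct patients (>= 1).
#' @param mean_admissions_per_patient expected admissions per patient (>= 1);
#'   admission counts are `1 + Poisson(mean - 1)`.
#' @param year_range two calendar years bounding admission dates.
#' @param target_prevalence overall DHD rate pi; the ground-truth intercept is
#'   solved so the expected prevalence over the generated covariates equals
#'   this value.
#' @param coefficient_map named log-odds weights over [dhd_feature_names()];
#'   names of the form `"a:b"` denote product interactions.
#' @param intercept optional fixed log-odds intercept; when supplied,
#'   `target_prevalence` is ignored.
#' @param subgroup_prevalences named list of marginal probabilities for
#'   `female`, `rural` and the Q5 fraction of each ON-Marg dimension
#'   (`ethnic_q5`, `dependency_q5`, `instability_q5`, `deprivation_q5`).
#' @param distortion_map named list `attribute -> group -> c(shift, scale)`
#'   applied to the outcome log-odds of rows in that group (scale > 0),
#'   e.g. `list(sex = list(female = c(0.5, 1)))`.
#' @param contamination_rates probabilities of injecting under-65 ages,
#'   LTC-origin flags, and missing ON-Marg quintiles.
#' @param frailty_loading loading of the shared patient frailty latent on the
#'   clinical-flag log-odds (induces mild positive flag correlation).
#' @param seed integer RNG seed.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_patients = 25000,
                         mean_admissions_per_patient = 2,
                         year_range = c(2004, 2022),
                         target_prevalence = 0.089,
                         coefficient_map = default_coefficients(),
                         intercept = NULL,
                         subgroup_prevalences = list(
                           female = 0.49, rural = 0.16,
                           ethnic_q5 = 0.16, dependency_q5 = 0.37,
                           instability_q5 = 0.28, deprivation_q5 = 0.21),
                         distortion_map = list(),
                         contamination_rates = c(under65 = 0.18, ltc = 0.05,
                                                 missing = 0.003),
                         frailty_loading = 0.8,
                         seed = 1L) {
  stop_if_not(is_count(n_patients), "n_patients must be a positive integer")
  stop_if_not(is.numeric(mean_admissions_per_patient) &&
                mean_admissions_per_patient >= 1,
              "mean_admissions_per_patient must be >= 1")
  stop_if_not(is_prob(target_prevalence), "target_prevalence must be in [0,1]")
  stop_if_not(length(coefficient_map) > 0, "coefficient_map must be non-empty")
  stop_if_not(all(is.finite(coefficient_map)),
              "coefficient_map must be finite")
  stop_if_not(all(vapply(subgroup_prevalences, is_prob, logical(1))),
              "subgroup_prevalences must be probabilities in [0,1]")
  stop_if_not(all(contamination_rates >= 0 & contamination_rates <= 1),
              "contamination_rates must be probabilities")
  for (attr_d in distortion_map) {
    for (d in attr_d) {
      stop_if_not(length(d) == 2 && all(is.finite(d)) && d[2] > 0,
                  "each distortion must be a finite (shift, scale) with scale > 0")
    }
  }
  structure(list(
    n_patients = as.integer(n_patients),
    mean_admissions_per_patient = mean_admissions_per_patient,
    year_range = as.integer(year_range),
    target_prevalence = target_prevalence,
    coefficient_map = coefficient_map,
    intercept = intercept,
    subgroup_prevalences = subgroup_prevalences,
    distortion_map = distortion_map,
    contamination_rates = contamination_rates,
    frailty_loading = frailty_loading,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# marginal per-admission flag rates (alpha on the logit scale before the
# frailty loading); chosen to echo a frail 65+ acute-care population
.flag_base_rates <- c(care_support = 0.13, fall = 0.12, fracture = 0.09,
                      rehab = 0.07, palliative = 0.04, noise = 0.30,
                      dementia = 0.12, mobility = 0.14, comorbidity = 0.35)

# truncated log-normal age on [65, 105] with median ~ 80
.draw_age <- function(n) {
  x <- exp(rnorm(n, log(15), 0.45))
  while (any(bad <- x > 40)) x[bad] <- exp(rnorm(sum(bad), log(15), 0.45))
  65 + x
}

#' Generate a synthetic admission table with known ground truth
#'
#' Draws a longitudinal admission table and its generating model. Patient-level
#' covariates (sex, region, residency, socioeconomic quintiles) are stable
#' across a patient's admissions; chronic condition flags accrue
#' monotonically; event flags recur per admission. The DHD outcome is
#' Bernoulli with log-odds `intercept + sum(coef * feature)` computed on the
#' look-back feature matrix (730-day window). Contaminated rows (under-65
#' ages, LTC origin, missing ON-Marg quintiles) are injected after outcomes
#' are drawn, so exclusions remove corrupted rows without touching the truth.
#'
#' @param config a [synth_config()].
#' @return list with elements `admissions` (data.frame) and `ground_truth`
#'   (class `dhd_ground_truth`: coefficient map, solved intercept,
#'   distortion map, realized prevalence, Bayes AUC, true probabilities,
#'   contamination counts).
#' @export
generate_admissions <- function(config) {
  stop_if_not(inherits(config, "synth_config"), "config must be a synth_config")
  set.seed(config$seed)
  np <- config$n_patients
  n_adm <- 1L + rpois(np, config$mean_admissions_per_patient - 1)
  n <- sum(n_adm)
  pid <- rep(sprintf("P%06d", seq_len(np)), n_adm)

  sp <- config$subgroup_prevalences
  # patient-level stable covariates
  female_p <- rbinom(np, 1, sp$female)
  rural_p <- rbinom(np, 1, sp$rural)
  region_p <- sample(.regions, np, replace = TRUE,
                     prob = c(0.18, 0.32, 0.18, 0.21, 0.11))
  income_p <- sample(1:5, np, replace = TRUE,
                     prob = c(0.21, 0.21, 0.20, 0.19, 0.19))
  q5 <- function(p) ifelse(rbinom(np, 1, p) == 1L, 5L,
                           sample(1:4, np, replace = TRUE))
  onmarg_p <- cbind(q5(sp$ethnic_q5), q5(sp$dependency_q5),
                    q5(sp$instability_q5), q5(sp$deprivation_q5))
  frailty_p <- rnorm(np)

  # admission dates: uniform within the year range, sorted per patient
  t0 <- as.Date(sprintf("%d-01-01", config$year_range[1]))
  t1 <- as.Date(sprintf("%d-12-31", config$year_range[2]))
  span <- as.integer(t1 - t0)
  date_off <- unlist(lapply(n_adm, function(k) sort(sample.int(span + 1L, k,
                                                               replace = TRUE)) - 1L),
                     use.names = FALSE)
  adm_date <- t0 + date_off
  age_first <- .draw_age(np)
  yrs_in <- (date_off - rep(date_off[cumsum(n_adm) - n_adm + 1L], n_adm)) / 365.25
  age <- rep(age_first, n_adm) + yrs_in

  lam <- config$frailty_loading
  fr <- rep(frailty_p, n_adm)
  flags <- matrix(0L, n, length(c(.event_flags, .condition_flags)),
                  dimnames = list(NULL, c(.event_flags, .condition_flags)))
  for (f in .event_flags) {
    l <- if (f == "noise") 0 else lam
    flags[, f] <- rbinom(n, 1, sigmoid(logit(.flag_base_rates[[f]]) + l * fr))
  }
  for (f in .condition_flags) {
    # chronic onset hazard per admission; once on, always on
    onset <- rbinom(n, 1, sigmoid(logit(.flag_base_rates[[f]]) + lam * fr))
    flags[, f] <- as.integer(unlist(lapply(split(onset, rep(seq_len(np), n_adm)),
                                           cummax), use.names = FALSE))
  }

  adm <- data.frame(
    patient_id = pid,
    admission_date = adm_date,
    age = age,
    sex = ifelse(rep(female_p, n_adm) == 1L, "female", "male"),
    region = rep(region_p, n_adm),
    residency = ifelse(rep(rural_p, n_adm) == 1L, "rural", "urban"),
    income_quintile = rep(income_p, n_adm),
    stringsAsFactors = FALSE
  )
  for (j in seq_along(.onmarg_cols)) adm[[.onmarg_cols[j]]] <- rep(onmarg_p[, j], n_adm)
  for (f in colnames(flags)) adm[[f]] <- flags[, f]
  adm$from_ltc <- 0L

  # ground-truth linear predictor on the look-back features
  X <- .history_features(adm)
  eta <- .linear_predictor(X, config$coefficient_map)
  intercept <- config$intercept
  if (is.null(intercept)) {
    intercept <- uniroot(function(c0) mean(sigmoid(c0 + eta)) -
                           config$target_prevalence,
                         c(-30, 30), tol = 1e-10)$root
  }
  p_true <- sigmoid(intercept + eta)
  eta_draw <- intercept + eta
  for (attr_name in names(config$distortion_map)) {
    lab <- .attribute_labels(adm, attr_name)
    for (g in names(config$distortion_map[[attr_name]])) {
      d <- config$distortion_map[[attr_name]][[g]]
      idx <- lab == g
      eta_draw[idx] <- d[1] + d[2] * eta_draw[idx]
    }
  }
  adm$dhd_90d <- rbinom(n, 1, sigmoid(eta_draw))

  # contamination after outcome draw: corrupt fields, never the truth
  cr <- config$contamination_rates
  under65 <- which(rbinom(n, 1, cr[["under65"]]) == 1L)
  adm$age[under65] <- runif(length(under65), 40, 64.99)
  ltc <- which(rbinom(n, 1, cr[["ltc"]]) == 1L)
  adm$from_ltc[ltc] <- 1L
  miss <- which(rbinom(n, 1, cr[["missing"]]) == 1L)
  if (length(miss)) {
    col <- sample(.onmarg_cols, length(miss), replace = TRUE)
    for (k in seq_along(miss)) adm[[col[k]]][miss[k]] <- NA_integer_
  }

  gt <- structure(list(
    coefficient_map = config$coefficient_map,
    intercept = intercept,
    distortion_map = config$distortion_map,
    realized_prevalence = mean(adm$dhd_90d),
    bayes_auc = .expected_auc(p_true),
    true_prob = p_true,
    contamination_counts = c(under65 = length(under65), ltc = length(ltc),
                             missing = length(miss)),
    seed = config$seed
  ), class = "dhd_ground_truth")
  list(admissions = adm, ground_truth = gt)
}

.linear_predictor <- function(X, coef_map) {
  eta <- numeric(nrow(X))
  for (nm in names(coef_map)) {
    if (coef_map[[nm]] == 0) next
    if (grepl(":", nm, fixed = TRUE)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      stop_if_not(all(parts %in% colnames(X)),
                  "unknown feature in interaction '%s'", nm)
      eta <- eta + coef_map[[nm]] * X[, parts[1]] * X[, parts[2]]
    } else {
      stop_if_not(nm %in% colnames(X), "unknown feature '%s'", nm)
      eta <- eta + coef_map[[nm]] * X[, nm]
    }
  }
  eta
}

# expected (Bayes) AUC of the true probabilities used as scores, i.e.
# P(p_i > p_j | y_i = 1, y_j = 0) with Bernoulli(p) outcomes, i != j,
# ties counting 1/2; computed exactly from the probability weights.
.expected_auc <- function(p) {
  o <- order(p)
  ps <- p[o]
  wneg <- 1 - ps
  # for each i: mass of negatives strictly below, and tied (excluding self)
  grp <- match(ps, unique(ps))
  tie_tot <- ave(wneg, grp, FUN = sum)
  # strictly-below mass: cumulative up to the start of each tie group
  start <- cumsum(wneg) - ave(wneg, grp, FUN = cumsum)
  num <- sum(ps * (start + 0.5 * (tie_tot - wneg)))
  den <- sum(ps) * sum(wneg) - sum(ps * wneg)
  num / den
}

.attribute_labels <- function(adm, attr_name) {
  switch(attr_name,
         sex = adm$sex,
         residency = adm$residency,
         instability = ifelse(is.na(adm$onmarg_instability), NA,
                              ifelse(adm$onmarg_instability == 5L, "Q5", "Q1-4")),
         stop(sprintf("unknown protected attribute '%s'", attr_name),
              call. = FALSE))
}

#' Generate a scored prediction set with known per-group distortions
#'
#' Draws risk scores `s = sigmoid(l)` with `l ~ N(mu, sigma^2)` (`sigma`
#' solved so the implied AUC equals `base_auc`) and outcomes
#' `y ~ Bernoulli(sigmoid(a_g + b_g * l))` per group `g`. With `a_g = 0`,
#' `b_g = 1` the scores are perfectly calibrated in expectation.
#'
#' @param n total number of rows.
#' @param base_auc target AUC of the undistorted scores, in (0.5, 1).
#' @param group_fractions named vector of group fractions summing to 1.
#' @param distortion_map named list `group -> c(shift, scale)`; groups not
#'   listed get `(0, 1)`.
#' @param seed integer RNG seed.
#' @param prevalence approximate event rate of the undistorted scores.
#' @return list with `predictions` (a [prediction_set()]) and `ground_truth`.
#' @export
generate_scored_set <- function(n, base_auc, group_fractions = c(all = 1),
                                distortion_map = list(), seed = 1L,
                                prevalence = 0.1) {
  stop_if_not(is.numeric(base_auc) && base_auc > 0.5 && base_auc < 1,
              "base_auc must lie in (0.5, 1)")
  stop_if_not(abs(sum(group_fractions) - 1) < 1e-8,
              "group_fractions must sum to 1")
  stop_if_not(all(n * group_fractions >= 2), "need n >= 2 per group")
  for (d in distortion_map) {
    stop_if_not(length(d) == 2 && all(is.finite(d)) && d[2] > 0,
                "each distortion must be finite (shift, scale), scale > 0")
  }
  set.seed(seed)
  mu <- logit(prevalence)
  # deterministic quantile grid: solve sigma for the target AUC
  zk <- qnorm((seq_len(2000) - 0.5) / 2000)
  auc_of <- function(s) .expected_auc(sigmoid(mu + s * zk))
  sigma <- uniroot(function(s) auc_of(s) - base_auc, c(0.01, 15),
                   tol = 1e-9)$root
  counts <- diff(round(cumsum(c(0, group_fractions * n))))
  group <- sample(rep(names(group_fractions), times = counts))
  l <- rnorm(n, mu, sigma)
  s <- sigmoid(l)
  eta <- l
  for (g in names(distortion_map)) {
    d <- distortion_map[[g]]
    eta[group == g] <- d[1] + d[2] * l[group == g]
  }
  y <- rbinom(n, 1, sigmoid(eta))
  gt <- structure(list(
    coefficient_map = NULL, intercept = mu,
    distortion_map = distortion_map,
    realized_prevalence = mean(y),
    bayes_auc = .expected_auc(s),
    sigma = sigma, seed = seed
  ), class = "dhd_ground_truth")
  list(predictions = prediction_set(s, y, list(group = group)),
       ground_truth = gt)
}

#' @export
print.dhd_ground_truth <- function(x, ...) {
  cat("Synthetic ground truth\n")
  cat(sprintf("  realized prevalence: %.4f\n", x$realized_prevalence))
  cat(sprintf("  Bayes AUC:           %.4f\n", x$bayes_auc))
  cat(sprintf("  intercept:           %.4f\n", x$intercept))
  if (length(x$distortion_map))
    cat("  distortions on:", paste(names(x$distortion_map), collapse = ", "), "\n")
  invisible(x)
}

#' Read and write admission tables
#'
#' Delimited-text interchange: comma-separated with a header row, ISO-8601
#' dates, empty fields for missing values.
#'
#' @param admissions an admission data.frame.
#' @param path file path.
#' @return `read_admissions()` returns the admission data.frame.
#' @export
write_admissions <- function(admissions, path) {
  out <- admissions
  out$admission_date <- format(out$admission_date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_admissions
#' @export
read_admissions <- function(path) {
  adm <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  adm$admission_date <- as.Date(adm$admission_date)
  adm
}

#' @rdname write_admissions
#' @param ground_truth a ground-truth object.
#' @export
write_ground_truth <- function(ground_truth, path) {
  gt <- unclass(ground_truth)
  gt$true_prob <- NULL
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
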