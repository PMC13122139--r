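# Cohort preparation: study exclusions, look-back feature construction,
# ON-Marg dichotomization, and patient-level / temporal data splits.

#' Dichotomize an ON-Marg quintile
#'
#' Compares the most marginalized quintile (Q5) against Q1-Q4.
#'
#' @param quintile integer vector with values in 1..5 (NA allowed; NA
#'   propagates and is later removed by the complete-case exclusion).
#' @return integer vector: 1 iff quintile == 5.
#' @export
dichotomize_onmarg <- function(quintile) {
  ok <- is.na(quintile) | (quintile %in% 1:5)
  stop_if_not(all(ok), "quintile values must lie in 1..5")
  as.integer(quintile == 5L)
}

# shared look-back builder: model features for every admission row, in the
# input's row order. Event flags become 730-day history indicators over PRIOR
# admissions (window half-open at the index date); chronic condition flags
# count on the index admission itself and on prior in-window admissions.
.history_features <- function(adm, window_days = 730) {
  n <- nrow(adm)
  ev <- .event_flags
  co <- .condition_flags
  hist_ev <- matrix(0L, n, length(ev), dimnames = list(NULL, ev))
  hist_co <- as.matrix(adm[co])
  ord <- order(adm$patient_id, adm$admission_date)
  d <- as.numeric(adm$admission_date)
  for (rows in split(ord, adm$patient_id[ord])) {
    if (length(rows) < 2L) next
    dd <- d[rows]
    fm_ev <- as.matrix(adm[rows, ev, drop = FALSE])
    fm_co <- as.matrix(adm[rows, co, drop = FALSE])
    for (i in 2:length(rows)) {
      prior <- which(dd < dd[i] & dd >= dd[i] - window_days)
      if (length(prior)) {
        hist_ev[rows[i], ] <- as.integer(apply(fm_ev[prior, , drop = FALSE], 2, max))
        hist_co[rows[i], ] <- pmax(hist_co[rows[i], ],
                                   apply(fm_co[prior, , drop = FALSE], 2, max))
      }
    }
  }
  X <- cbind(
    age = adm$age,
    female = as.numeric(adm$sex == "female"),
    rural = as.numeric(adm$residency == "rural"),
    income_q1 = as.numeric(adm$income_quintile == 1L),
    ethnic_q5 = dichotomize_onmarg(adm$onmarg_ethnic),
    dependency_q5 = dichotomize_onmarg(adm$onmarg_dependency),
    instability_q5 = dichotomize_onmarg(adm$onmarg_instability),
    deprivation_q5 = dichotomize_onmarg(adm$onmarg_deprivation)
  )
  for (r in .regions[-1]) {
    X <- cbind(X, as.numeric(adm$region == r))
    colnames(X)[ncol(X)] <- paste0("region_", tolower(r))
  }
  X <- cbind(X, hist_ev, hist_co)
  colnames(X) <- c(colnames(X)[seq_len(ncol(X) - length(ev) - length(co))],
                   paste0(ev, "_hist"), co)
  X[, dhd_feature_names(), drop = FALSE]
}

#' Apply the study exclusions
#'
#' Removes admissions of patients younger than 65, admissions from long-term
#' care, and rows with missing values (complete-case), in that fixed order; a
#' row violating several rules is counted once under the first.
#'
#' @param admissions admission data.frame.
#' @return list with `admissions` (retained rows) and `tally` (class
#'   `exclusion_tally`: removed counts per rule plus retained count).
#' @export
apply_exclusions <- function(admissions) {
  n <- nrow(admissions)
  if (n == 0L) {
    tally <- structure(list(age = 0L, ltc = 0L, missing = 0L, retained = 0L,
                            input = 0L), class = "exclusion_tally")
    return(list(admissions = admissions, tally = tally))
  }
  bad_age <- !is.na(admissions$age) & admissions$age < 65
  bad_ltc <- !bad_age & admissions$from_ltc == 1L
  core <- c("patient_id", "admission_date", "age", "sex", "region",
            "residency", "income_quintile", .onmarg_cols,
            .event_flags, .condition_flags, "dhd_90d")
  core <- intersect(core, names(admissions))
  any_na <- Reduce(`|`, lapply(admissions[core], is.na))
  bad_miss <- !bad_age & !bad_ltc & any_na
  keep <- !(bad_age | bad_ltc | bad_miss)
  tally <- structure(list(age = sum(bad_age), ltc = sum(bad_ltc),
                          missing = sum(bad_miss), retained = sum(keep),
                          input = n), class = "exclusion_tally")
  list(admissions = admissions[keep, , drop = FALSE], tally = tally)
}

#' @export
print.exclusion_tally <- function(x, ...) {
  cat("Exclusions:", x$input, "rows in\n")
  cat(sprintf("  under 65:       %d\n  LTC origin:     %d\n  missing/invalid: %d\n  retained:       %d\n",
              x$age, x$ltc, x$missing, x$retained))
  invisible(x)
}

#' Build the look-back cohort matrix
#'
#' Constructs, for every admission, the model feature vector: demographics,
#' dichotomized socioeconomic indicators, region dummies (Eastern is the
#' reference), 730-day history indicators for event flags over the patient's
#' prior admissions (window half-open at the index date), and current-state
#' chronic condition flags. Protected attributes (sex, residency, residential
#' instability Q5) are carried alongside for the fairness audit.
#'
#' @param admissions admission data.frame (run [apply_exclusions()] first for
#'   the study cohort).
#' @param window_days look-back window length in days (default 730).
#' @return object of class `cohort_matrix`: list with `features` (numeric
#'   matrix), `outcome` (0/1), `attributes` (data.frame of protected-group
#'   labels), `patient_id`, `admission_date`.
#' @export
build_lookback_features <- function(admissions, window_days = 730) {
  stop_if_not(is.numeric(window_days) && window_days > 0,
              "window_days must be positive")
  X <- .history_features(admissions, window_days)
  attrs <- data.frame(
    sex = admissions$sex,
    residency = admissions$residency,
    instability = ifelse(is.na(admissions$onmarg_instability), NA,
                         ifelse(admissions$onmarg_instability == 5L, "Q5", "Q1-4")),
    stringsAsFactors = FALSE
  )
  structure(list(features = X,
                 outcome = as.integer(admissions$dhd_90d),
                 attributes = attrs,
                 patient_id = admissions$patient_id,
                 admission_date = admissions$admission_date,
                 weights = NULL),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf("Cohort matrix: %d admissions, %d patients, %d features, prevalence %.3f\n",
              nrow(x$features), length(unique(x$patient_id)),
              ncol(x$features), mean(x$outcome)))
  invisible(x)
}

.subset_cohort <- function(cohort, idx) {
  structure(list(features = cohort$features[idx, , drop = FALSE],
                 outcome = cohort$outcome[idx],
                 attributes = cohort$attributes[idx, , drop = FALSE],
                 patient_id = cohort$patient_id[idx],
                 admission_date = cohort$admission_date[idx],
                 weights = cohort$weights[idx]),
            class = "cohort_matrix")
}

#' Patient-level random train/test split
#'
#' All admissions of a patient land on the same side, preventing leakage from
#' repeated visits.
#'
#' @param cohort a `cohort_matrix`.
#' @param test_fraction fraction of patients assigned to the test set.
#' @param seed integer RNG seed.
#' @return list with `train` and `test` cohort matrices.
#' @export
split_by_patient <- function(cohort, test_fraction = 0.10, seed = 1L) {
  stop_if_not(test_fraction > 0 && test_fraction < 1,
              "test_fraction must lie in (0, 1)")
  pats <- unique(cohort$patient_id)
  stop_if_not(length(pats) >= 2, "need at least 2 distinct patients")
  set.seed(seed)
  n_test <- max(1L, round(length(pats) * test_fraction))
  test_pats <- sample(pats, n_test)
  idx_test <- cohort$patient_id %in% test_pats
  list(train = .subset_cohort(cohort, which(!idx_test)),
       test = .subset_cohort(cohort, which(idx_test)))
}

#' Temporal train/test split by first-admission year
#'
#' A patient whose first recorded admission falls in or before `cutoff_year`
#' contributes all admissions to the training set; later first admissions go
#' to the temporal test set. Patient-disjoint by construction.
#'
#' @param cohort a `cohort_matrix`.
#' @param cutoff_year last first-admission year assigned to training.
#' @return list with `train` and `test` cohort matrices.
#' @export
temporal_split <- function(cohort, cutoff_year = 2014) {
  first_year <- tapply(as.integer(format(cohort$admission_date, "%Y")),
                       cohort$patient_id, min)
  train_pats <- names(first_year)[first_year <= cutoff_year]
  idx <- cohort$patient_id %in% train_pats
  list(train = .subset_cohort(cohort, which(idx)),
       test = .subset_cohort(cohort, which(!idx)))
}

#' Rebalance the training data for class imbalance
#'
#' `"class_weight"` (default elsewhere) attaches inverse-prevalence weights
#' without touching rows; `"downsample"` reduces the majority class to the
#' minority count. Applied to training data only — test data and its
#' prevalence are never altered, so calibration metrics stay meaningful.
#'
#' @param train a training `cohort_matrix`.
#' @param method one of `"none"`, `"downsample"`, `"class_weight"`.
#' @param seed integer RNG seed (downsampling).
#' @return the rebalanced training `cohort_matrix`.
#' @export
rebalance_training <- function(train, method = c("class_weight", "none",
                                                 "downsample"), seed = 1L) {
  method <- match.arg(method)
  if (method == "none") return(train)
  n1 <- sum(train$outcome == 1L); n0 <- sum(train$outcome == 0L)
  if (method == "downsample") {
    stop_if_not(n1 > 0 && n0 > 0, "downsampling needs both outcome classes")
    set.seed(seed)
    minority <- min(n0, n1)
    keep <- c(sample(which(train$outcome == 0L), minority),
              sample(which(train$outcome == 1L), minority))
    return(.subset_cohort(train, sort(keep)))
  }
  # class_weight: total weight per class equalized
  w <- ifelse(train$outcome == 1L, (n0 + n1) / (2 * n1), (n0 + n1) / (2 * n0))
  train$weights <- w
  train
}
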