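# Risk models: logistic regression and gradient-boosted trees with
# grouped (patient-level), outcome-stratified 5-fold hyperparameter tuning.

# patient-level folds: patients stratified by their patient-level outcome
# (any DHD admission) and dealt round-robin into folds after a seeded shuffle
.patient_folds <- function(patient_id, outcome, n_folds, seed) {
  pat_out <- tapply(outcome, patient_id, max)
  set.seed(seed)
  fold <- integer(length(pat_out))
  names(fold) <- names(pat_out)
  for (cls in unique(pat_out)) {
    p <- names(pat_out)[pat_out == cls]
    p <- sample(p)
    fold[p] <- rep_len(seq_len(n_folds), length(p))
  }
  fold
}

.default_gbt_grid <- function() {
  expand.grid(max_depth = c(3L, 5L), eta = c(0.1, 0.3), nrounds = 200L,
              subsample = 1, KEEP.OUT.ATTRS = FALSE)
}

.fit_gbt <- function(X, y, w, pars, seed) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y,
                                 weight = if (is.null(w)) rep(1, length(y)) else w)
  params <- list(objective = "binary:logistic", eval_metric = "auc",
                 max_depth = pars$max_depth, eta = pars$eta,
                 subsample = pars$subsample, nthread = 1, seed = seed)
  xgboost::xgb.train(params = params, data = dtrain, nrounds = pars$nrounds,
                     verbose = 0)
}

.fit_lr <- function(X, y, w, lambda = 0) {
  if (lambda > 0) {
    stop_if_not(requireNamespace("glmnet", quietly = TRUE),
                "ridge logistic regression requires the glmnet package")
    fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                          lambda = lambda,
                          weights = if (is.null(w)) rep(1, length(y)) else w,
                          standardize = TRUE)
    beta <- as.numeric(stats::coef(fit))
    names(beta) <- c("(Intercept)", colnames(X))
  } else {
    df <- data.frame(y = y, X, check.names = FALSE)
    fit <- suppressWarnings(stats::glm(
      stats::reformulate(sprintf("`%s`", colnames(X)), response = "y"),
      family = stats::binomial(), data = df, weights = w))
    beta <- stats::coef(fit)
    names(beta) <- c("(Intercept)", colnames(X))
    attr(beta, "vcov") <- stats::vcov(fit)
  }
  beta
}

#' Fit a delayed-discharge risk model with grouped cross-validated tuning
#'
#' Fits either an unpenalized (or ridge) logistic regression or a
#' gradient-boosted tree model on a cohort matrix. Hyperparameters are tuned
#' by mean out-of-fold AUC over folds that partition PATIENTS (stratified by
#' patient-level outcome), so no patient contributes to both sides of any
#' CV split; the winning setting is refit on the full training data. Ties
#' between grid points are broken toward the simpler model (fewer boosting
#' rounds, then shallower trees).
#'
#' @param train a `cohort_matrix` (see [build_lookback_features()]); any
#'   weights attached by [rebalance_training()] are used.
#' @param learner `"lr"` (logistic regression) or `"gbt"` (gradient-boosted
#'   trees).
#' @param grid data.frame of candidate hyperparameters. For `"gbt"`: columns
#'   `max_depth`, `eta`, `nrounds`, `subsample`; for `"lr"`: optional column
#'   `lambda` (ridge penalty; 0 = unpenalized). NULL or empty selects the
#'   documented defaults (GBT: depth 3/5 x eta 0.1/0.3 x 200 rounds; LR:
#'   unpenalized).
#' @param n_folds number of CV folds (default 5).
#' @param seed integer RNG seed.
#' @return object of class `dhd_model`.
#' @export
dhd_fit <- function(train, learner = c("lr", "gbt"), grid = NULL,
                    n_folds = 5, seed = 1L) {
  learner <- match.arg(learner)
  stop_if_not(inherits(train, "cohort_matrix"), "train must be a cohort_matrix")
  y <- train$outcome
  stop_if_not(length(unique(y)) == 2,
              "training outcome is single-class; cannot fit")
  X <- train$features
  w <- train$weights
  fold_of <- .patient_folds(train$patient_id, y, n_folds, seed)
  row_fold <- fold_of[train$patient_id]

  if (learner == "lr") {
    lambdas <- if (!is.null(grid) && nrow(grid) && "lambda" %in% names(grid))
      grid$lambda else 0
    cv <- NULL
    if (length(lambdas) > 1) {
      cv <- data.frame(lambda = lambdas, mean_auc = NA_real_)
      for (k in seq_along(lambdas)) {
        aucs <- vapply(seq_len(n_folds), function(f) {
          tr <- row_fold != f
          beta <- .fit_lr(X[tr, , drop = FALSE], y[tr], w[tr], lambdas[k])
          p <- sigmoid(cbind(1, X[!tr, , drop = FALSE]) %*% beta)
          auc(p, y[!tr])
        }, numeric(1))
        cv$mean_auc[k] <- mean(aucs)
      }
      # tie toward the heavier penalty (simpler model)
      ord <- order(-cv$lambda)
      best <- ord[which.max(cv$mean_auc[ord])]
      chosen <- list(lambda = lambdas[best])
    } else {
      chosen <- list(lambda = lambdas[1])
    }
    beta <- .fit_lr(X, y, w, chosen$lambda)
    fit <- list(beta = beta)
  } else {
    g <- if (is.null(grid) || nrow(grid) == 0) .default_gbt_grid() else grid
    for (col in c("subsample")) if (!col %in% names(g)) g[[col]] <- 1
    cv <- g
    cv$mean_auc <- NA_real_
    if (nrow(g) > 1) {
      for (k in seq_len(nrow(g))) {
        aucs <- vapply(seq_len(n_folds), function(f) {
          tr <- row_fold != f
          booster <- .fit_gbt(X[tr, , drop = FALSE], y[tr], w[tr], g[k, ], seed)
          p <- predict(booster, xgboost::xgb.DMatrix(X[!tr, , drop = FALSE]))
          auc(p, y[!tr])
        }, numeric(1))
        cv$mean_auc[k] <- mean(aucs)
      }
      ord <- order(g$nrounds, g$max_depth, g$eta)
      best <- ord[which.max(cv$mean_auc[ord])]
    } else best <- 1L
    chosen <- as.list(g[best, ])
    booster <- .fit_gbt(X, y, w, g[best, ], seed)
    fit <- list(raw = xgboost::xgb.save.raw(booster))
  }

  structure(list(learner = learner, fit = fit,
                 hyperparameters = chosen, cv_results = cv,
                 feature_names = colnames(X), n = nrow(X), seed = seed,
                 fold_of = fold_of, calibrator = NULL,
                 calibrator_attribute = NULL),
            class = "dhd_model")
}

.model_matrix <- function(object, newdata) {
  X <- if (inherits(newdata, "cohort_matrix")) newdata$features
       else as.matrix(newdata)
  if (nrow(X) == 0L) return(X)
  unknown <- setdiff(colnames(X), object$feature_names)
  stop_if_not(length(unknown) == 0, "unknown feature name(s): %s",
              paste(unknown, collapse = ", "))
  missing <- setdiff(object$feature_names, colnames(X))
  stop_if_not(length(missing) == 0, "missing feature(s): %s",
              paste(missing, collapse = ", "))
  X[, object$feature_names, drop = FALSE]
}

#' Predict risk probabilities
#'
#' @param object a `dhd_model`.
#' @param newdata a `cohort_matrix`, or a matrix/data.frame whose column set
#'   equals the training features (unknown or missing names are rejected).
#' @param calibrated apply the attached calibrator, if any (default TRUE).
#' @param labels protected-group labels, required when a group-stratified
#'   calibrator is attached and `newdata` is not a `cohort_matrix`.
#' @param ... unused.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict.dhd_model <- function(object, newdata, calibrated = TRUE,
                              labels = NULL, ...) {
  X <- .model_matrix(object, newdata)
  if (nrow(X) == 0L) return(numeric(0))
  p <- if (object$learner == "lr") {
    as.numeric(sigmoid(cbind(1, X) %*% object$fit$beta))
  } else {
    booster <- xgboost::xgb.load.raw(object$fit$raw)
    as.numeric(predict(booster, xgboost::xgb.DMatrix(X)))
  }
  if (calibrated && !is.null(object$calibrator)) {
    if (inherits(object$calibrator, "group_platt")) {
      if (is.null(labels)) {
        stop_if_not(inherits(newdata, "cohort_matrix"),
                    "group-stratified calibration needs labels or a cohort_matrix")
        labels <- newdata$attributes[[object$calibrator_attribute]]
      }
      p <- predict(object$calibrator, p, labels)
    } else {
      p <- predict(object$calibrator, p)
    }
  }
  p
}

#' Attach a calibrator to a fitted risk model
#'
#' @param model a `dhd_model`.
#' @param calibrator a `platt` or `group_platt` object (NULL detaches).
#' @param attribute for `group_platt`, the attribute used to route rows.
#' @return the model with the calibrator attached.
#' @export
attach_calibrator <- function(model, calibrator, attribute = NULL) {
  if (inherits(calibrator, "group_platt") && is.null(attribute))
    attribute <- calibrator$attribute
  model$calibrator <- calibrator
  model$calibrator_attribute <- attribute
  model
}

#' @export
coef.dhd_model <- function(object, ...) {
  stop_if_not(object$learner == "lr",
              "coefficients are only defined for the logistic model")
  object$fit$beta
}

#' @export
print.dhd_model <- function(x, ...) {
  cat(sprintf("DHD risk model (%s), trained on %d admissions, %d features\n",
              switch(x$learner, lr = "logistic regression",
                     gbt = "gradient-boosted trees"),
              x$n, length(x$feature_names)))
  hp <- x$hyperparameters
  if (length(hp))
    cat("  hyperparameters:",
        paste(sprintf("%s = %s", names(hp), unlist(hp)), collapse = ", "), "\n")
  if (!is.null(x$calibrator))
    cat("  calibrator:", class(x$calibrator)[1], "\n")
  invisible(x)
}

#' @export
summary.dhd_model <- function(object, ...) {
  print(object)
  if (!is.null(object$cv_results) && "mean_auc" %in% names(object$cv_results)) {
    cat("Cross-validation trace (mean out-of-fold AUC):\n")
    print(object$cv_results, row.names = FALSE)
  }
  if (object$learner == "lr") {
    cat("Coefficients (log-odds):\n")
    print(round(object$fit$beta, 4))
  }
  invisible(object)
}

#' Save / load a fitted risk model
#'
#' Serializes the model state (including any attached calibrator) with a
#' format version tag.
#'
#' @param model a `dhd_model`.
#' @param path file path.
#' @return `load_dhd_model()` returns the model.
#' @export
save_dhd_model <- function(model, path) {
  saveRDS(list(format = "dhd_model/1", model = model), path)
  invisible(path)
}

#' @rdname save_dhd_model
#' @export
load_dhd_model <- function(path) {
  obj <- readRDS(path)
  stop_if_not(identical(obj$format, "dhd_model/1"),
              "unrecognized model file format")
  obj$model
}
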