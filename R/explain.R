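# Model-agnostic explainability: permutation feature importance, partial
# dependence, Shapley attributions (exact coalition enumeration and
# permutation sampling), breakdown attributions, and ceteris paribus
# profiles. All local methods share an interventional value function: the
# mean model prediction over a background sample with a chosen feature
# subset fixed to the explained instance.

# load a booster once and return a vectorized prediction closure
.predictor <- function(model) {
  if (model$learner == "gbt") {
    booster <- xgboost::xgb.load.raw(model$fit$raw)
    nms <- model$feature_names
    function(X) as.numeric(predict(booster,
                                   xgboost::xgb.DMatrix(X[, nms, drop = FALSE])))
  } else {
    beta <- model$fit$beta
    nms <- model$feature_names
    function(X) as.numeric(sigmoid(cbind(1, X[, nms, drop = FALSE]) %*% beta))
  }
}

#' Permutation feature importance
#'
#' Importance of a feature is the drop in test AUC when its column is
#' randomly permuted, averaged over `n_repeats` independent permutations.
#' A feature the model never uses scores ~0.
#'
#' @param model a `dhd_model`.
#' @param data a `cohort_matrix` with outcomes.
#' @param n_repeats number of permutations per feature (>= 2).
#' @param seed integer RNG seed.
#' @return data.frame (feature, importance, sd, baseline_auc), sorted by
#'   decreasing importance.
#' @export
permutation_importance <- function(model, data, n_repeats = 5, seed = 1L) {
  stop_if_not(n_repeats >= 2, "n_repeats must be at least 2")
  X <- .model_matrix(model, data)
  y <- data$outcome
  f <- .predictor(model)
  base <- auc(f(X), y)
  set.seed(seed)
  res <- lapply(colnames(X), function(j) {
    drops <- vapply(seq_len(n_repeats), function(r) {
      Xp <- X
      Xp[, j] <- X[sample.int(nrow(X)), j]
      base - auc(f(Xp), y)
    }, numeric(1))
    data.frame(feature = j, importance = mean(drops), sd = stats::sd(drops),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$baseline_auc <- base
  out[order(-out$importance), ]
}

.default_grid <- function(X, feature) {
  v <- X[, feature]
  if (all(v %in% c(0, 1))) c(0, 1)
  else seq(min(v), max(v), length.out = 20)
}

#' Partial dependence profile
#'
#' The profile value at grid point g is the mean prediction over all rows
#' with the feature set to g and every other column untouched (marginal
#' effect).
#'
#' @param model a `dhd_model`.
#' @param data a `cohort_matrix` or feature matrix.
#' @param feature feature name.
#' @param grid grid of feature values ({0, 1} for flags; a range sweep for
#'   age). NULL selects a default.
#' @return object of class `dhd_profile` (data.frame: value, prediction)
#'   with attributes `feature` and `kind = "pdp"`.
#' @export
partial_dependence <- function(model, data, feature, grid = NULL) {
  X <- .model_matrix(model, data)
  stop_if_not(nrow(X) > 0, "empty data")
  stop_if_not(feature %in% colnames(X), "unknown feature '%s'", feature)
  if (is.null(grid)) grid <- .default_grid(X, feature)
  f <- .predictor(model)
  preds <- vapply(grid, function(g) {
    Xg <- X; Xg[, feature] <- g
    mean(f(Xg))
  }, numeric(1))
  structure(data.frame(value = grid, prediction = preds),
            feature = feature, kind = "pdp",
            class = c("dhd_profile", "data.frame"))
}

#' Ceteris paribus profile
#'
#' Prediction path for a single instance as one feature sweeps a grid while
#' all its other values stay frozen.
#'
#' @param model a `dhd_model`.
#' @param instance a single feature row (1-row matrix/data.frame).
#' @param feature feature name.
#' @param grid grid of feature values (NULL: default).
#' @param id optional instance identifier.
#' @return a `dhd_profile` with `kind = "ceteris_paribus"`.
#' @export
ceteris_paribus <- function(model, instance, feature, grid = NULL, id = NULL) {
  X <- .model_matrix(model, instance)
  stop_if_not(nrow(X) == 1, "instance must be a single row")
  stop_if_not(feature %in% colnames(X), "unknown feature '%s'", feature)
  if (is.null(grid)) grid <- if (X[1, feature] %in% c(0, 1)) c(0, 1)
                             else .default_grid(X, feature)
  f <- .predictor(model)
  Xg <- X[rep(1, length(grid)), , drop = FALSE]
  Xg[, feature] <- grid
  structure(data.frame(value = grid, prediction = f(Xg)),
            feature = feature, kind = "ceteris_paribus", id = id,
            class = c("dhd_profile", "data.frame"))
}

#' @export
print.dhd_profile <- function(x, ...) {
  cat(sprintf("%s profile for '%s' (%d grid points)\n",
              if (attr(x, "kind") == "pdp") "Partial dependence"
              else "Ceteris paribus",
              attr(x, "feature"), nrow(x)))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

.attribution_row <- function(id, method, baseline, prediction, contributions,
                             se = NULL) {
  structure(list(id = id, method = method, baseline = baseline,
                 prediction = prediction, contributions = contributions,
                 se = se),
            class = "attribution_row")
}

#' @export
print.attribution_row <- function(x, ...) {
  cat(sprintf("%s attributions (instance %s): baseline %.4f -> prediction %.4f\n",
              x$method, as.character(x$id %||% "?"), x$baseline, x$prediction))
  print(round(sort(x$contributions, decreasing = TRUE), 4))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mean prediction with the features in `fixed` (logical index) set to the
# instance and the rest drawn from the background rows
.coalition_value <- function(f, instance, background, fixed) {
  Xb <- background
  if (any(fixed)) Xb[, fixed] <- matrix(instance[fixed], nrow(background),
                                        sum(fixed), byrow = TRUE)
  mean(f(Xb))
}

#' Shapley attributions for a single prediction
#'
#' Interventional value function: `v(S)` is the mean prediction over the
#' background rows with the features in coalition S fixed to the instance.
#' `mode = "exact"` enumerates all coalitions (at most 12 features);
#' `mode = "sampled"` averages marginal contributions along random feature
#' permutations. Both satisfy local accuracy: baseline + sum(contributions)
#' equals the instance prediction (exactly — each sampled permutation
#' telescopes).
#'
#' @param model a `dhd_model`.
#' @param instance a single feature row.
#' @param background background feature matrix (non-empty).
#' @param mode `"exact"` or `"sampled"`.
#' @param n_samples number of permutations in sampled mode.
#' @param seed integer RNG seed (sampled mode).
#' @param id optional instance identifier.
#' @return an `attribution_row` with method `"shapley"`.
#' @export
shapley_attributions <- function(model, instance, background,
                                 mode = c("exact", "sampled"),
                                 n_samples = 200, seed = 1L, id = NULL) {
  mode <- match.arg(mode)
  X1 <- .model_matrix(model, instance)
  stop_if_not(nrow(X1) == 1, "instance must be a single row")
  Xb <- .model_matrix(model, background)
  stop_if_not(nrow(Xb) > 0, "background must be non-empty")
  p <- ncol(X1)
  f <- .predictor(model)
  inst <- X1[1, ]
  baseline <- mean(f(Xb))
  pred <- f(X1)

  if (mode == "exact") {
    stop_if_not(p <= 12,
                "exact Shapley is limited to 12 features; use mode = 'sampled'")
    nmask <- bitwShiftL(1L, p)
    v <- numeric(nmask)
    sizes <- integer(nmask)
    for (m in 0:(nmask - 1L)) {
      fixed <- as.logical(bitwAnd(bitwShiftR(m, 0:(p - 1L)), 1L))
      sizes[m + 1L] <- sum(fixed)
      v[m + 1L] <- .coalition_value(f, inst, Xb, fixed)
    }
    wt <- factorial(0:(p - 1L)) * factorial(p - 1L - 0:(p - 1L)) / factorial(p)
    phi <- numeric(p)
    for (j in seq_len(p)) {
      bit <- bitwShiftL(1L, j - 1L)
      masks <- which(bitwAnd(0:(nmask - 1L), bit) == 0L) - 1L
      phi[j] <- sum(wt[sizes[masks + 1L] + 1L] *
                      (v[bitwOr(masks, bit) + 1L] - v[masks + 1L]))
    }
    names(phi) <- colnames(X1)
    return(.attribution_row(id, "shapley", baseline, pred, phi))
  }

  set.seed(seed)
  nbg <- nrow(Xb)
  contrib <- matrix(0, n_samples, p, dimnames = list(NULL, colnames(X1)))
  for (m in seq_len(n_samples)) {
    ord <- sample.int(p)
    # stacked background copies with progressively more features fixed
    Xs <- Xb[rep(seq_len(nbg), p + 1L), , drop = FALSE]
    for (k in seq_len(p)) {
      rows <- (k * nbg + 1L):((p + 1L) * nbg)
      Xs[rows, ord[k]] <- inst[ord[k]]
    }
    vals <- f(Xs)
    vk <- vapply(0:p, function(k) mean(vals[(k * nbg + 1L):((k + 1L) * nbg)]),
                 numeric(1))
    contrib[m, ord] <- diff(vk)
  }
  phi <- colMeans(contrib)
  se <- apply(contrib, 2, stats::sd) / sqrt(n_samples)
  # each permutation telescopes from v(empty) to v(full); align the reported
  # baseline/prediction pair with the Monte-Carlo value function exactly
  .attribution_row(id, "shapley", baseline,
                   baseline + sum(phi), phi, se = se)
}

#' Breakdown attributions for a single prediction
#'
#' Sequential conditioning: the k-th contribution is
#' `E[f | first k features fixed] - E[f | first k-1 fixed]`, with
#' expectations over the background sample. Contributions sum exactly to
#' prediction - baseline. Order-dependent by design; `order = "auto"` fixes
#' features by decreasing absolute single-fix effect.
#'
#' @param model a `dhd_model`.
#' @param instance a single feature row.
#' @param background background feature matrix.
#' @param order feature-name sequence covering all features, or `"auto"`.
#' @param id optional instance identifier.
#' @return an `attribution_row` with method `"breakdown"`.
#' @export
breakdown_attributions <- function(model, instance, background,
                                   order = "auto", id = NULL) {
  X1 <- .model_matrix(model, instance)
  stop_if_not(nrow(X1) == 1, "instance must be a single row")
  Xb <- .model_matrix(model, background)
  stop_if_not(nrow(Xb) > 0, "background must be non-empty")
  f <- .predictor(model)
  inst <- X1[1, ]
  nms <- colnames(X1)
  baseline <- mean(f(Xb))
  if (identical(order, "auto")) {
    single <- vapply(nms, function(j) {
      fixed <- nms == j
      .coalition_value(f, inst, Xb, fixed)
    }, numeric(1))
    order <- nms[base::order(-abs(single - baseline), nms)]
  } else {
    stop_if_not(!anyDuplicated(order), "duplicate features in order")
    stop_if_not(setequal(order, nms), "order must cover all features exactly")
  }
  v_prev <- baseline
  phi <- numeric(length(nms))
  names(phi) <- order
  fixed <- rep(FALSE, length(nms))
  names(fixed) <- nms
  for (k in seq_along(order)) {
    fixed[order[k]] <- TRUE
    v_k <- if (all(fixed)) f(X1) else .coalition_value(f, inst, Xb, fixed[nms])
    phi[k] <- v_k - v_prev
    v_prev <- v_k
  }
  # contributions reported in application order (the breakdown-plot order)
  .attribution_row(id, "breakdown", baseline, f(X1), phi)
}
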