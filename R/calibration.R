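# Platt scaling (global and group-stratified) and calibration diagnostics:
# Brier score, expected calibration error, logistic-recalibration intercept
# and slope, and reliability-diagram bins.

#' Expected calibration error
#'
#' Count-weighted mean absolute gap between mean predicted probability and
#' observed event rate over equal-width bins on \[0, 1\].
#'
#' @param scores probabilities in \[0, 1\].
#' @param outcomes binary 0/1 vector.
#' @param n_bins number of equal-width bins (default 10).
#' @return ECE in \[0, 1\].
#' @export
ece <- function(scores, outcomes, n_bins = 10) {
  stop_if_not(length(scores) > 0, "empty input")
  b <- .bin_index(scores, n_bins)
  n <- length(scores)
  sum(vapply(split(seq_len(n), b), function(i) {
    length(i) / n * abs(mean(scores[i]) - mean(outcomes[i]))
  }, numeric(1)))
}

.bin_index <- function(scores, n_bins) {
  pmin(pmax(floor(scores * n_bins) + 1L, 1L), n_bins)
}

#' Fit a Platt scaling calibrator
#'
#' Maximum-likelihood univariate logistic regression of the outcome on the
#' log-odds of the raw score (clipped to \[1e-6, 1 - 1e-6\]). The fitted map
#' `sigmoid(intercept + slope * logit(s))` is monotone nondecreasing whenever
#' the fitted slope is nonnegative.
#'
#' @param scores raw probabilities in \[0, 1\], n >= 10.
#' @param outcomes binary 0/1 vector, both classes present.
#' @return object of class `platt` with `intercept`, `slope`, standard
#'   errors, `transform = "logit"` and fitting `n`.
#' @export
fit_platt <- function(scores, outcomes) {
  stop_if_not(length(scores) >= 10, "need at least 10 observations")
  stop_if_not(all(scores >= 0 & scores <= 1), "scores must lie in [0, 1]")
  stop_if_not(length(unique(outcomes)) == 2, "both outcome classes required")
  x <- logit(clip_prob(scores))
  stop_if_not(stats::var(x) > 0, "constant scores: no variance to calibrate on")
  fit <- stats::glm(outcomes ~ x, family = stats::binomial())
  cf <- stats::coef(fit); se <- sqrt(diag(stats::vcov(fit)))
  structure(list(intercept = unname(cf[1]), slope = unname(cf[2]),
                 se = unname(se), transform = "logit",
                 n = length(scores)),
            class = "platt")
}

#' @export
predict.platt <- function(object, scores, ...) {
  sigmoid(object$intercept + object$slope * logit(clip_prob(scores)))
}

#' @export
print.platt <- function(x, ...) {
  cat(sprintf("Platt calibrator (logit transform): intercept %.4f, slope %.4f, n = %d\n",
              x$intercept, x$slope, x$n))
  invisible(x)
}

#' Fit group-stratified Platt calibrators
#'
#' One Platt map per protected-group label plus a global fallback for labels
#' unseen at fit time. A group with a single outcome class falls back to the
#' global calibrator with a warning. Application routes each row to its
#' group's map, aligning predicted risk with observed outcomes within every
#' group (post-processing bias mitigation).
#'
#' @param predset a [prediction_set()].
#' @param attribute stratification attribute name.
#' @return object of class `group_platt`.
#' @export
fit_groupwise_platt <- function(predset, attribute) {
  stop_if_not(attribute %in% names(predset$attributes),
              "attribute '%s' not present", attribute)
  lab <- predset$attributes[[attribute]]
  keep <- !is.na(lab)
  s <- predset$scores[keep]; y <- predset$outcomes[keep]; lab <- lab[keep]
  fallback <- fit_platt(s, y)
  cals <- list()
  for (g in sort(unique(lab))) {
    i <- lab == g
    if (length(unique(y[i])) < 2 || sum(i) < 10 ||
        stats::var(logit(clip_prob(s[i]))) == 0) {
      warning(sprintf("group '%s' lacks both classes or variance; using global calibrator", g))
      cals[[g]] <- fallback
    } else {
      cals[[g]] <- fit_platt(s[i], y[i])
    }
  }
  structure(list(calibrators = cals, attribute = attribute,
                 fallback = fallback), class = "group_platt")
}

#' @export
predict.group_platt <- function(object, scores, labels, ...) {
  stop_if_not(length(scores) == length(labels),
              "scores and labels must align")
  out <- numeric(length(scores))
  unseen <- setdiff(unique(labels), names(object$calibrators))
  if (length(unseen))
    warning(sprintf("unseen group label(s) %s: using fallback calibrator",
                    paste(sQuote(unseen), collapse = ", ")))
  for (g in unique(labels)) {
    cal <- if (g %in% names(object$calibrators)) object$calibrators[[g]]
           else object$fallback
    i <- labels == g
    out[i] <- predict(cal, scores[i])
  }
  out
}

#' @export
print.group_platt <- function(x, ...) {
  cat(sprintf("Group-stratified Platt calibrator on '%s' (%d groups)\n",
              x$attribute, length(x$calibrators)))
  for (g in names(x$calibrators))
    cat(sprintf("  %-8s intercept %.4f, slope %.4f\n", g,
                x$calibrators[[g]]$intercept, x$calibrators[[g]]$slope))
  invisible(x)
}

#' Calibration diagnostics
#'
#' Brier score (mean squared error of the probabilities), expected
#' calibration error over equal-width bins, calibration intercept (offset
#' logistic model with slope fixed at 1) and calibration slope (free-slope
#' logistic recalibration), plus reliability-diagram bins.
#'
#' @param scores probabilities in \[0, 1\].
#' @param outcomes binary 0/1 vector.
#' @param n_bins ECE / reliability bin count.
#' @return object of class `calibration_report`.
#' @export
calibration_metrics <- function(scores, outcomes, n_bins = 10) {
  stop_if_not(length(scores) > 0, "empty input")
  brier <- mean((scores - outcomes)^2)
  e <- ece(scores, outcomes, n_bins)
  lp <- logit(clip_prob(scores))
  both <- length(unique(outcomes)) == 2
  slope <- intercept <- NA_real_
  if (both && stats::var(lp) > 0) {
    slope <- unname(stats::coef(stats::glm(outcomes ~ lp,
                                           family = stats::binomial()))[2])
    intercept <- unname(stats::coef(stats::glm(outcomes ~ 1 + offset(lp),
                                               family = stats::binomial()))[1])
  }
  b <- .bin_index(scores, n_bins)
  bins <- do.call(rbind, lapply(split(seq_along(scores), b), function(i) {
    data.frame(bin = b[i[1]], mean_score = mean(scores[i]),
               event_rate = mean(outcomes[i]), n = length(i))
  }))
  rownames(bins) <- NULL
  structure(list(brier = brier, ece = e,
                 calibration_intercept = intercept,
                 calibration_slope = slope,
                 bins = bins, n = length(scores), n_bins = n_bins),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, digits = 4, ...) {
  cat("Calibration report\n")
  cat(sprintf("  Brier score:            %.*f\n", digits, x$brier))
  cat(sprintf("  ECE (%d bins):          %.*f\n", x$n_bins, digits, x$ece))
  cat(sprintf("  Calibration intercept:  %.*f\n", digits, x$calibration_intercept))
  cat(sprintf("  Calibration slope:      %.*f\n", digits, x$calibration_slope))
  invisible(x)
}

#' Plot a reliability diagram
#'
#' @param x a `calibration_report`.
#' @param ... passed to [plot()].
#' @export
plot.calibration_report <- function(x, ...) {
  plot(x$bins$mean_score, x$bins$event_rate, xlim = c(0, 1), ylim = c(0, 1),
       xlab = "Mean predicted probability", ylab = "Observed event rate",
       pch = 19, ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  graphics::lines(x$bins$mean_score, x$bins$event_rate)
  invisible(x)
}

#' Serialize a calibration report
#'
#' Writes the scalar metrics as JSON and the reliability bins as
#' comma-separated text.
#'
#' @param report a `calibration_report`.
#' @param json_path,bins_path output paths (NULL to skip either).
#' @export
write_calibration_report <- function(report, json_path = NULL,
                                     bins_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(report[c("brier", "ece", "calibration_intercept",
                                  "calibration_slope", "n", "n_bins")],
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(bins_path)) utils::write.csv(report$bins, bins_path,
                                            row.names = FALSE)
  invisible(report)
}
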