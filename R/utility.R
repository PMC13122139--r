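# Decision-curve analysis: net benefit of a model against the treat-all and
# treat-none strategies over a grid of threshold probabilities.

#' Net benefit at a threshold probability
#'
#' `NB = TP/n - (FP/n) * t / (1 - t)` where a positive classification means
#' score >= t (ties act positive). The standardized variant divides by the
#' event prevalence pi, giving a maximum of 1.0.
#'
#' @param predset a [prediction_set()].
#' @param threshold threshold probability t in (0, 1).
#' @param standardized divide by prevalence (default FALSE).
#' @return net benefit (real).
#' @export
net_benefit <- function(predset, threshold, standardized = FALSE) {
  stop_if_not(is.numeric(threshold) && threshold > 0 && threshold < 1,
              "threshold must lie in (0, 1)")
  y <- predset$outcomes
  pos <- predset$scores >= threshold
  n <- length(y)
  nb <- sum(pos & y == 1L) / n -
    sum(pos & y == 0L) / n * threshold / (1 - threshold)
  if (standardized) nb / mean(y) else nb
}

#' Treat-all net benefit (analytic)
#'
#' Under treat-all, the true-positive rate equals the event prevalence pi and
#' the false-positive rate equals 1 - pi, so
#' `NB = pi - (1 - pi) * t / (1 - t)`; it equals pi as t -> 0 and crosses
#' zero exactly at t = pi.
#'
#' @param prevalence event rate pi.
#' @param threshold threshold probability t in (0, 1).
#' @param standardized divide by prevalence.
#' @return net benefit (real).
#' @export
nb_treat_all <- function(prevalence, threshold, standardized = FALSE) {
  stop_if_not(all(threshold > 0 & threshold < 1),
              "threshold must lie in (0, 1)")
  nb <- prevalence - (1 - prevalence) * threshold / (1 - threshold)
  if (standardized) nb / prevalence else nb
}

#' Decision curve over a threshold grid
#'
#' Computes model net benefit at each threshold alongside the analytic
#' treat-all curve and the treat-none reference (identically 0). Both raw and
#' prevalence-standardized net benefit are emitted.
#'
#' @param predset a [prediction_set()].
#' @param thresholds threshold grid inside (0, 1); default 0.01-0.60 by 0.01.
#' @return object of class `decision_curve` (a data.frame with columns
#'   threshold, nb_model, nb_all, nb_none, snb_model, snb_all) with the
#'   prevalence as an attribute.
#' @export
decision_curve <- function(predset, thresholds = seq(0.01, 0.60, by = 0.01)) {
  stop_if_not(length(thresholds) > 0 && all(thresholds > 0 & thresholds < 1),
              "thresholds must be a non-empty grid inside (0, 1)")
  pi_hat <- mean(predset$outcomes)
  nb_model <- vapply(thresholds, function(t) net_benefit(predset, t),
                     numeric(1))
  nb_all <- nb_treat_all(pi_hat, thresholds)
  out <- data.frame(threshold = thresholds, nb_model = nb_model,
                    nb_all = nb_all, nb_none = 0,
                    snb_model = nb_model / pi_hat, snb_all = nb_all / pi_hat)
  # structural guarantees of the NB definition, asserted on every curve
  stop_if_not(all(out$nb_model <= pi_hat + 1e-12),
              "model net benefit exceeded the prevalence bound")
  stop_if_not(all(out$snb_model <= 1 + 1e-12),
              "standardized net benefit exceeded 1.0")
  structure(out, prevalence = pi_hat,
            class = c("decision_curve", "data.frame"))
}

#' @export
print.decision_curve <- function(x, ...) {
  cat(sprintf("Decision curve: %d thresholds in [%.2f, %.2f], prevalence %.4f\n",
              nrow(x), min(x$threshold), max(x$threshold),
              attr(x, "prevalence")))
  invisible(x)
}

#' Plot a decision curve
#'
#' @param x a `decision_curve`.
#' @param standardized plot standardized net benefit (default FALSE).
#' @param ... passed to [plot()].
#' @export
plot.decision_curve <- function(x, standardized = FALSE, ...) {
  cols <- if (standardized) c("snb_model", "snb_all") else c("nb_model", "nb_all")
  ylim <- range(c(x[[cols[1]]], x[[cols[2]]], 0))
  plot(x$threshold, x[[cols[1]]], type = "l", ylim = ylim,
       xlab = "Threshold probability",
       ylab = if (standardized) "Standardized net benefit" else "Net benefit",
       ...)
  graphics::lines(x$threshold, x[[cols[2]]], lty = 2, col = "grey40")
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", c("model", "treat all", "treat none"),
                   lty = c(1, 2, 3), col = c("black", "grey40", "black"),
                   bty = "n")
  invisible(x)
}

#' Write a decision curve as delimited text
#'
#' @param curve a `decision_curve`.
#' @param path output path (CSV).
#' @export
write_decision_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
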