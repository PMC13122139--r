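# Threshold-free fairness audit: within-group AUC, cross-group xAUC, and
# ECE, expressed as equity-seeking / regular parity ratios with 10%/20%
# fairness bands.

#' Construct a prediction set
#'
#' Aligned risk scores, binary outcomes, and per-row protected-attribute
#' labels.
#'
#' @param scores numeric probabilities in \[0, 1\].
#' @param outcomes binary 0/1 vector of the same length.
#' @param attributes named list (or data.frame) of per-row group labels.
#' @return object of class `prediction_set`.
#' @export
prediction_set <- function(scores, outcomes, attributes = list()) {
  stop_if_not(length(scores) == length(outcomes),
              "scores and outcomes must have equal length")
  stop_if_not(all(scores >= 0 & scores <= 1, na.rm = TRUE),
              "scores must lie in [0, 1]")
  stop_if_not(all(outcomes %in% c(0L, 1L)), "outcomes must be 0/1")
  attributes <- as.data.frame(attributes, stringsAsFactors = FALSE)
  if (nrow(attributes)) {
    stop_if_not(nrow(attributes) == length(scores),
                "attributes must align with scores")
  }
  structure(list(scores = as.numeric(scores), outcomes = as.integer(outcomes),
                 attributes = attributes),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("Prediction set: n = %d, prevalence %.3f, attributes: %s\n",
              length(x$scores), mean(x$outcomes),
              if (ncol(x$attributes)) paste(names(x$attributes), collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney form: P(score_pos > score_neg) + 1/2 P(tie), computed from
#' average ranks; matches brute-force pair enumeration exactly.
#'
#' @param scores numeric vector.
#' @param outcomes binary 0/1 vector.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, outcomes) {
  stop_if_not(length(scores) == length(outcomes), "length mismatch")
  n1 <- sum(outcomes == 1L); n0 <- sum(outcomes == 0L)
  stop_if_not(n1 > 0 && n0 > 0, "both outcome classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[outcomes == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# default equity-seeking label per protected attribute
.default_equity <- c(sex = "female", residency = "rural", instability = "Q5")

.equity_label <- function(predset, attribute, equity_label = NULL) {
  if (!is.null(equity_label)) return(equity_label)
  if (attribute %in% names(.default_equity)) return(.default_equity[[attribute]])
  stop(sprintf("no default equity-seeking label for attribute '%s'; supply equity_label",
               attribute), call. = FALSE)
}

#' Cross-group AUC (xAUC)
#'
#' Probability that a random positive case from one protected group is ranked
#' above a random negative case from the other group (ties count 1/2).
#'
#' @param predset a [prediction_set()].
#' @param attribute name of the protected attribute.
#' @param direction `"equity_pos_vs_regular_neg"` (forward) or
#'   `"regular_pos_vs_equity_neg"` (backward).
#' @param equity_label label of the equity-seeking group (defaults: female,
#'   rural, Q5).
#' @return xAUC in \[0, 1\].
#' @export
xauc <- function(predset, attribute,
                 direction = c("equity_pos_vs_regular_neg",
                               "regular_pos_vs_equity_neg"),
                 equity_label = NULL) {
  direction <- match.arg(direction)
  stop_if_not(attribute %in% names(predset$attributes),
              "attribute '%s' not present in prediction set", attribute)
  lab <- predset$attributes[[attribute]]
  keep <- !is.na(lab)
  s <- predset$scores[keep]; y <- predset$outcomes[keep]; lab <- lab[keep]
  eq <- .equity_label(predset, attribute, equity_label)
  is_eq <- lab == eq
  if (direction == "equity_pos_vs_regular_neg") {
    pos <- s[is_eq & y == 1L]; neg <- s[!is_eq & y == 0L]
    cells <- c("equity positives", "regular negatives")
  } else {
    pos <- s[!is_eq & y == 1L]; neg <- s[is_eq & y == 0L]
    cells <- c("regular positives", "equity negatives")
  }
  if (length(pos) == 0L) stop(sprintf("empty cell: %s", cells[1]), call. = FALSE)
  if (length(neg) == 0L) stop(sprintf("empty cell: %s", cells[2]), call. = FALSE)
  auc(c(pos, neg), c(rep(1L, length(pos)), rep(0L, length(neg))))
}

.band <- function(ratio) {
  if (is.na(ratio)) return(NA_character_)
  d <- abs(ratio - 1)
  if (d <= 0.1) "within 10%" else if (d <= 0.2) "within 20%" else "outside"
}

#' Threshold-free fairness report
#'
#' For each protected attribute, computes within-group AUC, cross-group xAUC
#' and ECE for the equity-seeking and regular groups, their parity ratios
#' (equity / regular; forward / backward for xAUC), and a fairness-band label
#' per ratio (`|ratio - 1|` against 0.1 and 0.2). An ECE of zero in the
#' denominator yields an undefined (NA) ratio with a flag.
#'
#' @param predset a [prediction_set()].
#' @param attributes attribute names to audit (default: all present).
#' @param n_bins ECE bin count.
#' @param equity_labels optional named vector attribute -> equity label.
#' @return object of class `fairness_report` (a data.frame, one row per
#'   attribute).
#' @export
fairness_report <- function(predset, attributes = names(predset$attributes),
                            n_bins = 10, equity_labels = NULL) {
  rows <- lapply(attributes, function(a) {
    lab <- predset$attributes[[a]]
    keep <- !is.na(lab)
    s <- predset$scores[keep]; y <- predset$outcomes[keep]; labk <- lab[keep]
    eq <- .equity_label(predset, a, equity_labels[[a]])
    is_eq <- labk == eq
    stop_if_not(any(is_eq) && any(!is_eq),
                "attribute '%s' needs both groups present", a)
    auc_eq <- auc(s[is_eq], y[is_eq])
    auc_reg <- auc(s[!is_eq], y[!is_eq])
    x_f <- xauc(predset, a, "equity_pos_vs_regular_neg", equity_label = eq)
    x_b <- xauc(predset, a, "regular_pos_vs_equity_neg", equity_label = eq)
    e_eq <- ece(s[is_eq], y[is_eq], n_bins)
    e_reg <- ece(s[!is_eq], y[!is_eq], n_bins)
    ece_par <- if (e_reg == 0) NA_real_ else e_eq / e_reg
    data.frame(attribute = a, equity_group = eq,
               auc_equity = auc_eq, auc_regular = auc_reg,
               auc_parity = auc_eq / auc_reg,
               xauc_forward = x_f, xauc_backward = x_b,
               xauc_parity = x_f / x_b,
               ece_equity = e_eq, ece_regular = e_reg,
               ece_parity = ece_par,
               auc_band = .band(auc_eq / auc_reg),
               xauc_band = .band(x_f / x_b),
               ece_band = .band(ece_par),
               ece_parity_undefined = e_reg == 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fairness_report", "data.frame")
  attr(out, "direction_convention") <-
    "xauc_parity = forward/backward; forward ranks equity-group positives against regular-group negatives"
  out
}

#' @export
print.fairness_report <- function(x, digits = 3, ...) {
  cat("Fairness audit (equity-seeking / regular parity ratios)\n")
  df <- as.data.frame(x)
  print(format(df[c("attribute", "auc_parity", "xauc_parity", "ece_parity",
                    "auc_band", "xauc_band", "ece_band")],
               digits = digits), row.names = FALSE)
  invisible(x)
}

#' Write a fairness report as JSON and a flat delimited table
#'
#' @param report a `fairness_report`.
#' @param json_path,table_path output paths (NULL to skip either).
#' @return invisibly, the flat long-format data.frame (attribute, metric,
#'   value).
#' @export
write_fairness_report <- function(report, json_path = NULL, table_path = NULL) {
  df <- as.data.frame(report)
  long <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    metrics <- c("auc_equity", "auc_regular", "auc_parity", "xauc_forward",
                 "xauc_backward", "xauc_parity", "ece_equity", "ece_regular",
                 "ece_parity")
    data.frame(attribute = df$attribute[i], metric = metrics,
               value = unlist(df[i, metrics]), stringsAsFactors = FALSE)
  }))
  if (!is.null(json_path))
    jsonlite::write_json(df, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  if (!is.null(table_path))
    utils::write.csv(long, table_path, row.names = FALSE)
  invisible(long)
}
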