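# Aggregation of local attributions over high-risk patients into per-feature
# (contribution, rank, prevalence) summaries, followed by z-scoring, PCA on
# the 3x3 correlation matrix, sign-quadrant assignment and category
# composition.

#' Default a-priori feature categories
#'
#' Three conceptual groups used to interpret the explanation-PCA quadrants:
#' sociodemographic-geographic, multimorbidity-health, mobility-disability.
#'
#' @return named character vector feature -> category.
#' @export
default_feature_categories <- function() {
  sdg <- c("age", "female", "rural", "income_q1", "ethnic_q5",
           "dependency_q5", "instability_q5", "deprivation_q5",
           "region_central", "region_metropolitan", "region_southwestern",
           "region_northern")
  mob <- c("care_support_hist", "fall_hist", "fracture_hist", "rehab_hist",
           "mobility")
  mmh <- c("dementia", "comorbidity", "palliative_hist", "noise_hist")
  c(stats::setNames(rep("sociodemographic-geographic", length(sdg)), sdg),
    stats::setNames(rep("mobility-disability", length(mob)), mob),
    stats::setNames(rep("multimorbidity-health", length(mmh)), mmh))
}

#' Read a feature-category map from delimited text
#'
#' Two-column CSV with header `feature,category`.
#'
#' @param path file path.
#' @return named character vector feature -> category.
#' @export
read_feature_categories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_if_not(all(c("feature", "category") %in% names(df)),
              "category file needs 'feature' and 'category' columns")
  stats::setNames(df$category, df$feature)
}

#' Summarize local attributions over high-risk patients
#'
#' Restricts to instances with predicted probability above `risk_threshold`
#' and computes, per feature: the mean (signed) contribution, the mean rank
#' (rank 1 = largest absolute contribution; ties broken by feature name),
#' and the prevalence — the percentage of high-risk patients for whom the
#' feature appears in the top `top_k` by absolute contribution.
#'
#' @param attributions list of `attribution_row` objects.
#' @param scores predicted probabilities aligned with `attributions`.
#' @param risk_threshold high-risk cut (default 0.5, strict).
#' @param top_k top-contributor count for prevalence (default 10).
#' @param category_map named vector feature -> category (default
#'   [default_feature_categories()]).
#' @return object of class `feature_summary` (data.frame: feature,
#'   mean_contribution, mean_rank, prevalence, category).
#' @export
summarize_attributions <- function(attributions, scores,
                                   risk_threshold = 0.5, top_k = 10,
                                   category_map = default_feature_categories()) {
  stop_if_not(length(attributions) == length(scores),
              "attributions and scores must align")
  hi <- which(scores > risk_threshold)
  stop_if_not(length(hi) > 0,
              "no high-risk instances above the risk threshold; nothing to summarize")
  feats <- names(attributions[[hi[1]]]$contributions)
  contrib <- t(vapply(attributions[hi],
                      function(a) a$contributions[feats], numeric(length(feats))))
  # rank by decreasing |contribution|, lexicographic tie-break
  ranks <- t(apply(contrib, 1, function(row) {
    ord <- order(-abs(row), feats)
    r <- integer(length(row)); r[ord] <- seq_along(row); r
  }))
  out <- data.frame(
    feature = feats,
    mean_contribution = colMeans(contrib),
    mean_rank = colMeans(ranks),
    prevalence = 100 * colMeans(ranks <= top_k),
    category = unname(category_map[feats]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_high_risk") <- length(hi)
  attr(out, "risk_threshold") <- risk_threshold
  attr(out, "top_k") <- top_k
  class(out) <- c("feature_summary", "data.frame")
  out
}

#' PCA of the explanation summary with sign quadrants
#'
#' Z-scores the three summary metrics, eigendecomposes their 3x3 correlation
#' matrix, keeps the top two components (sign fixed so the contribution
#' loading is nonnegative), assigns each feature to a quadrant by the signs
#' of its PC1/PC2 scores (Q1 = (+,+), Q2 = (-,+), Q3 = (-,-), Q4 = (+,-)),
#' and tabulates the category composition of each quadrant.
#'
#' @param summary a `feature_summary` with at least 3 features.
#' @return object of class `pca_result`: standardized matrix, loadings,
#'   per-feature PC scores and quadrants, variance-explained fractions, and
#'   the quadrant-by-category composition table.
#' @export
pca_quadrants <- function(summary) {
  stop_if_not(nrow(summary) >= 3, "need at least 3 features")
  metrics <- c("mean_contribution", "mean_rank", "prevalence")
  M <- as.matrix(summary[metrics])
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0))
    stop(sprintf("constant metric column: %s",
                 paste(metrics[sds == 0], collapse = ", ")), call. = FALSE)
  Z <- scale(M)
  R <- stats::cor(M)
  eg <- eigen(R, symmetric = TRUE)
  loadings <- eg$vectors
  # sign convention: contribution loading >= 0 on each component
  for (k in 1:3) if (loadings[1, k] < 0) loadings[, k] <- -loadings[, k]
  rownames(loadings) <- c("contribution", "rank", "percentage")
  colnames(loadings) <- paste0("PC", 1:3)
  var_frac <- eg$values / sum(eg$values)
  scores <- Z %*% loadings[, 1:2]
  colnames(scores) <- c("PC1", "PC2")
  rownames(scores) <- summary$feature
  quadrant <- ifelse(scores[, 1] >= 0,
                     ifelse(scores[, 2] >= 0, "Q1", "Q4"),
                     ifelse(scores[, 2] >= 0, "Q2", "Q3"))
  comp <- if (!all(is.na(summary$category))) {
    tab <- table(quadrant = quadrant, category = summary$category)
    prop.table(tab, margin = 1)
  } else NULL
  structure(list(standardized = Z, loadings = loadings,
                 scores = scores, variance_explained = var_frac,
                 quadrant = quadrant, composition = comp,
                 features = summary$feature),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, digits = 3, ...) {
  cat("Explanation-summary PCA\n")
  ve <- 100 * x$variance_explained
  cat(sprintf("  variance explained: PC1 %.1f%%, PC2 %.1f%% (top two: %.1f%%)\n",
              ve[1], ve[2], ve[1] + ve[2]))
  cat(sprintf("  PC1 = %+.2f x contribution %+.2f x rank %+.2f x percentage\n",
              x$loadings[1, 1], x$loadings[2, 1], x$loadings[3, 1]))
  cat(sprintf("  PC2 = %+.2f x contribution %+.2f x rank %+.2f x percentage\n",
              x$loadings[1, 2], x$loadings[2, 2], x$loadings[3, 2]))
  cat("  quadrant counts:\n")
  print(table(x$quadrant))
  invisible(x)
}

#' Serialize the explanation summary and PCA result
#'
#' @param summary a `feature_summary`.
#' @param pca a `pca_result` (optional).
#' @param table_path CSV path for the per-feature table.
#' @param json_path JSON path for loadings/variance/quadrants.
#' @export
write_explanation_summary <- function(summary, pca = NULL, table_path = NULL,
                                      json_path = NULL) {
  df <- as.data.frame(summary)
  if (!is.null(pca)) {
    df$PC1 <- pca$scores[df$feature, "PC1"]
    df$PC2 <- pca$scores[df$feature, "PC2"]
    df$quadrant <- pca$quadrant[df$feature]
  }
  if (!is.null(table_path)) utils::write.csv(df, table_path, row.names = FALSE)
  if (!is.null(json_path) && !is.null(pca)) {
    jsonlite::write_json(list(
      loadings = as.data.frame(pca$loadings),
      variance_explained = pca$variance_explained,
      quadrants = as.list(pca$quadrant)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(df)
}
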