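# Disease-status classification: a random forest (out-of-bag vote scores,
# impurity importances) and ROC/AUC with a DeLong confidence interval.

#' Fit a random forest and collect out-of-bag scores
#'
#' Fits a forest of `n_trees` classification trees; each sample's score is
#' the fraction of case-class votes among the trees in which the sample was
#' out-of-bag, so the scores are honest (no resubstitution).  Trees are
#' grown on balanced per-class subsamples (0.632 times the smaller class,
#' drawn without replacement): with plain bootstrap bags the out-of-bag
#' sample systematically faces bags slightly depleted of its own class,
#' which biases null out-of-bag AUC below 0.5; balanced subsampling removes
#' that skew.  Feature importances are mean decreases in Gini impurity.
#' Deterministic under a fixed seed.
#'
#' @param matrix Samples x features numeric matrix.
#' @param labels Two-level group label per sample; at least 5 per class.
#' @param n_trees Number of trees (default 1000).
#' @param rng_seed Integer seed.
#' @param positive_group Level scored as the case class (default `"PE"`
#'   when present, else the second level).
#' @return A list with `scores` (named, in `[0, 1]`), `importance`
#'   (data.frame `feature_id`, `importance`, decreasing), `labels`,
#'   `positive_group` and the fitted `forest`.
#' @export
fit_and_score <- function(matrix, labels, n_trees = 1000, rng_seed = 1,
                          positive_group = NULL) {
  m <- unclass(matrix)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("labels contain a single class")
  if (nlevels(labels) > 2) stop("exactly two classes required")
  if (any(table(labels) < 5)) stop("at least 5 samples per class required")
  if (all(apply(m, 2, function(x) length(unique(x)) == 1L)))
    stop("all features are constant; nothing to classify on")
  if (is.null(positive_group))
    positive_group <- if ("PE" %in% levels(labels)) "PE" else
      levels(labels)[2]
  set.seed(rng_seed)
  n_sub <- max(3L, floor(0.632 * min(table(labels))))
  rf <- randomForest::randomForest(x = m, y = labels, ntree = n_trees,
                                   strata = labels, replace = FALSE,
                                   sampsize = rep(n_sub, nlevels(labels)))
  scores <- rf$votes[, positive_group]
  names(scores) <- rownames(m)
  imp <- randomForest::importance(rf)
  importance <- data.frame(feature_id = rownames(imp),
                           importance = unname(imp[, "MeanDecreaseGini"]))
  importance <- importance[order(-importance$importance,
                                 importance$feature_id), ]
  rownames(importance) <- NULL
  list(scores = scores, importance = importance, labels = labels,
       positive_group = positive_group, forest = rf)
}

#' ROC curve, AUC and DeLong confidence interval
#'
#' AUC by the trapezoidal rule over all thresholds (equal to the normalized
#' Mann-Whitney U statistic, with half-credit for tied scores); the 95%
#' confidence interval uses the DeLong variance estimate, both via pROC.
#'
#' @param scores Numeric classification scores (higher = more case-like).
#' @param labels Two-level group label per sample.
#' @param positive_group Case level (default `"PE"` when present, else the
#'   second level).
#' @return An object of class `classifier_report`: `auc`, `ci_low`,
#'   `ci_high`, `scores`, `labels`, and `roc_points` (data.frame
#'   `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels, positive_group = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("both classes must be present")
  if (any(table(labels) == 0)) stop("both classes must be present")
  if (is.null(positive_group))
    positive_group <- if ("PE" %in% levels(labels)) "PE" else
      levels(labels)[2]
  neg <- setdiff(levels(labels), positive_group)
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = c(neg, positive_group), direction = "<",
                 quiet = TRUE)
  # a perfect AUC makes the DeLong variance degenerate (CI collapses to
  # 1-1); pROC warns about it, the returned interval already says it all
  ci <- withCallingHandlers(
    pROC::ci.auc(r, method = "delong"),
    warning = function(w) {
      if (grepl("AUC == 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  structure(list(auc = as.numeric(pROC::auc(r)),
                 ci_low = as.numeric(ci[1]), ci_high = as.numeric(ci[3]),
                 scores = scores, labels = labels,
                 positive_group = positive_group,
                 roc_points = data.frame(threshold = r$thresholds,
                                         fpr = 1 - r$specificities,
                                         tpr = r$sensitivities)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI %.3f-%.3f), positive class = %s\n",
              x$auc, x$ci_low, x$ci_high, x$positive_group))
  invisible(x)
}

#' Fit, score and report a microbiome classifier
#'
#' Convenience wrapper: [fit_and_score()] then [roc_auc()] on the
#' out-of-bag scores, plus a ranked top-feature table annotated with the
#' enrichment direction (sign of the case-vs-control mean difference).
#'
#' @inheritParams fit_and_score
#' @param top_n Number of top features to report (default 30).
#' @return A `classifier_report` with an extra `top_features` data.frame
#'   (`feature_id`, `importance`, `direction`).
#' @export
classifier_report <- function(matrix, labels, n_trees = 1000, rng_seed = 1,
                              top_n = 30, positive_group = NULL) {
  fit <- fit_and_score(matrix, labels, n_trees = n_trees,
                       rng_seed = rng_seed, positive_group = positive_group)
  rep <- roc_auc(fit$scores, fit$labels, positive_group = fit$positive_group)
  m <- unclass(matrix)
  ci <- fit$labels == fit$positive_group
  top <- head(fit$importance, top_n)
  delta <- colMeans(m[ci, top$feature_id, drop = FALSE]) -
    colMeans(m[!ci, top$feature_id, drop = FALSE])
  ctrl <- setdiff(levels(fit$labels), fit$positive_group)
  top$direction <- ifelse(delta >= 0,
                          paste0(fit$positive_group, "-enriched"),
                          paste0(ctrl, "-enriched"))
  rep$top_features <- top
  rep$importance <- fit$importance
  rep
}
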