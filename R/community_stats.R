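# Community statistics: Bray-Curtis dissimilarity, principal coordinate
# analysis, one-factor PERMANOVA, the Mantel test, and per-feature
# differential-abundance calling (Wilcoxon rank-sum + Benjamini-Hochberg).
# Distance-based machinery is delegated to vegan; this module owns the
# contracts, seeding and result containers.

#' Bray-Curtis dissimilarity between samples
#'
#' `d(i, j) = sum(|x - y|) / sum(x + y)` over features; symmetric, zero
#' diagonal, in `[0, 1]` for non-negative profiles.
#'
#' @param matrix Samples x features matrix with non-negative entries.
#' @return A `dist` object (use `as.matrix()` for the square form).
#' @export
bray_curtis <- function(matrix) {
  m <- unclass(matrix)
  if (any(m < 0)) stop("Bray-Curtis requires non-negative rows")
  if (sum(rowSums(m) == 0) >= 2)
    stop("two or more all-zero rows: Bray-Curtis undefined between them")
  vegan::vegdist(m, method = "bray")
}

#' Principal coordinate analysis (classical MDS)
#'
#' Eigendecomposition of the double-centered Gower matrix via
#' [stats::cmdscale()].  Axes are ordered by decreasing eigenvalue.
#' Negative eigenvalues (from non-Euclidean distances such as Bray-Curtis)
#' are reported; the percent-variance denominator uses, by choice, either
#' the positive eigenvalues only (default) or the sum of absolute values.
#'
#' @param d A `dist` object or symmetric zero-diagonal matrix.
#' @param n_axes Number of returned axes (default 2).
#' @param positive_only Use only positive eigenvalues in the
#'   percent-variance denominator (default `TRUE`).
#' @return A list with `coordinates` (samples x n_axes), `eigenvalues`
#'   (all, decreasing) and `pct_variance` (per returned axis, in percent).
#' @export
pcoa <- function(d, n_axes = 2, positive_only = TRUE) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d), tol = 1e-12))
      stop("distance matrix must be symmetric")
    if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be 0")
    d <- as.dist(d)
  }
  n <- attr(d, "Size")
  # cmdscale warns when fewer than k eigenvalues are positive (degenerate
  # inputs); the eigenvalues are returned anyway, so the warning is noise
  fit <- withCallingHandlers(
    cmdscale(d, k = min(n_axes, n - 1), eig = TRUE),
    warning = function(w) {
      if (grepl("eigenvalues", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  eig <- sort(fit$eig, decreasing = TRUE)
  denom <- if (positive_only) sum(eig[eig > 0]) else sum(abs(eig))
  coords <- fit$points
  if (ncol(coords) < n_axes)  # degenerate input: pad with zero axes
    coords <- cbind(coords, matrix(0, n, n_axes - ncol(coords)))
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  pct <- if (denom > 0) 100 * pmax(eig[seq_len(n_axes)], 0) / denom else
    rep(0, n_axes)
  list(coordinates = coords, eigenvalues = eig, pct_variance = pct)
}

#' One-factor PERMANOVA (adonis)
#'
#' Permutational partitioning of distance-matrix variance by a grouping
#' factor, computed with [vegan::adonis2()]; the permutation p-value is
#' `(1 + #permuted F >= observed F) / (1 + n_perm)`.
#'
#' @param d A `dist` object or square distance matrix.
#' @param labels Group label per sample; at least two groups with at least
#'   two samples each.
#' @param n_perm Number of label permutations (default 1000).
#' @param rng_seed Optional integer seed for the permutations.
#' @return An object of class `permanova_result`: `pseudo_F`, `r2`
#'   (explained-variation fraction), `p_perm`, `n_perm`.
#' @export
permanova <- function(d, labels, n_perm = 1000, rng_seed = NULL) {
  if (is.matrix(d)) d <- as.dist(d)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("PERMANOVA needs at least two groups")
  if (any(table(labels) < 2))
    stop("every group needs at least two samples")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  dat <- data.frame(group = labels)
  fit <- vegan::adonis2(d ~ group, data = dat, permutations = n_perm)
  structure(list(pseudo_F = fit$F[1], r2 = fit$R2[1],
                 p_perm = fit$`Pr(>F)`[1], n_perm = n_perm),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.4f (%.1f%%), p = %.4g (%d permutations)\n",
              x$pseudo_F, x$r2, 100 * x$r2, x$p_perm, x$n_perm))
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal distances with a permutation
#' p-value obtained by permuting one matrix's rows and columns
#' ([vegan::mantel()]).
#'
#' @param dist_a,dist_b `dist` objects or square matrices over the same
#'   samples in the same order.
#' @param n_perm Number of permutations (default 1000).
#' @param rng_seed Optional integer seed.
#' @return A list with `r`, `p_perm`, `n_perm`.
#' @export
mantel_test <- function(dist_a, dist_b, n_perm = 1000, rng_seed = NULL) {
  if (is.matrix(dist_a)) dist_a <- as.dist(dist_a)
  if (is.matrix(dist_b)) dist_b <- as.dist(dist_b)
  if (attr(dist_a, "Size") != attr(dist_b, "Size"))
    stop("distance matrices must cover the same samples")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  fit <- vegan::mantel(dist_a, dist_b, method = "pearson",
                       permutations = n_perm)
  list(r = unname(fit$statistic), p_perm = fit$signif, n_perm = n_perm)
}

#' Differential-abundance calling between two groups
#'
#' Per feature: a two-sided Wilcoxon rank-sum test on the abundances
#' (exact for groups of at most 25 without ties, normal approximation with
#' continuity and tie correction otherwise), Benjamini-Hochberg q-values
#' over the tested set, group means, and a log2 fold change of the group
#' means with pseudocount epsilon = half the smallest positive value in
#' the matrix.  Direction is assigned at the configured threshold on p (or
#' q when `use_q`): positive fold change means enrichment in
#' `positive_group`.
#'
#' @param matrix Samples x features abundance matrix.
#' @param labels Two-level group label per sample.
#' @param alpha Significance threshold (default 0.05).
#' @param use_q Call significance on BH q instead of raw p
#'   (default `FALSE`).
#' @param positive_group Level treated as the case group in fold changes
#'   and direction labels (default `"PE"` when present, else the second
#'   level).
#' @return data.frame of class `differential_result`: `feature_id`,
#'   `mean_<case>`, `mean_<control>`, `log2fc`, `p`, `q`, `direction`
#'   (`<case>-enriched` / `<control>-enriched` / `ns`), `constant`.
#' @export
differential_features <- function(matrix, labels, alpha = 0.05,
                                  use_q = FALSE, positive_group = NULL) {
  m <- unclass(matrix)
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("exactly two groups required")
  if (is.null(positive_group))
    positive_group <- if ("PE" %in% levels(labels)) "PE" else
      levels(labels)[2]
  case <- positive_group
  ctrl <- setdiff(levels(labels), case)
  ci <- labels == case
  pos <- m[m > 0]
  eps <- if (length(pos) > 0) min(pos) / 2 else .Machine$double.eps
  exact <- sum(ci) <= 25 && sum(!ci) <= 25

  res <- lapply(seq_len(ncol(m)), function(j) {
    x <- m[ci, j]
    y <- m[!ci, j]
    constant <- length(unique(c(x, y))) == 1L
    p <- if (constant) 1 else
      suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
    data.frame(feature_id = colnames(m)[j],
               mean_case = mean(x), mean_ctrl = mean(y),
               log2fc = log2((mean(x) + eps) / (mean(y) + eps)),
               p = p, constant = constant)
  })
  res <- do.call(rbind, res)
  res$q <- p.adjust(res$p, method = "BH")
  sig <- if (use_q) res$q < alpha else res$p < alpha
  res$direction <- ifelse(!sig, "ns",
                          ifelse(res$log2fc > 0,
                                 paste0(case, "-enriched"),
                                 paste0(ctrl, "-enriched")))
  names(res)[names(res) == "mean_case"] <- paste0("mean_", case)
  names(res)[names(res) == "mean_ctrl"] <- paste0("mean_", ctrl)
  res <- res[, c("feature_id", paste0("mean_", case), paste0("mean_", ctrl),
                 "log2fc", "p", "q", "direction", "constant")]
  class(res) <- c("differential_result", "data.frame")
  attr(res, "positive_group") <- case
  res
}
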