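# Rank-based between-cluster tests: Shapiro-Wilk normality gate,
# Wilcoxon-Mann-Whitney for two clusters, Kruskal-Wallis for three or more,
# and the per-index comparison report.

test_result <- function(statistic, p_value, method, n, alpha = 0.05) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 method = method, n = n, alpha = alpha,
                 decision = if (is.na(p_value)) NA_character_
                            else if (p_value < alpha) "rejected"
                            else "failed_to_reject"),
            class = "ssm_test")
}

#' @export
print.ssm_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g -> %s\n",
              x$method, x$statistic, x$p_value, x$decision))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' W statistic and p-value via the Royston approximation, for
#' `3 <= n <= 5000`.
#'
#' @param x Numeric vector.
#' @param alpha Significance level for the reported decision (default 0.05).
#' @return An `ssm_test` with fields `statistic`, `p_value`, `method`, `n`,
#'   `decision`.
#' @export
shapiro_wilk <- function(x, alpha = 0.05) {
  if (length(x) < 3 || length(x) > 5000)
    ssm_stop("Shapiro-Wilk needs 3 <= n <= 5000", "parameter_error")
  if (length(unique(x)) == 1)
    ssm_stop("constant input: normality test undefined", "degenerate_error")
  f <- stats::shapiro.test(x)
  test_result(f$statistic, f$p.value, "shapiro_wilk", length(x), alpha)
}

#' Wilcoxon-Mann-Whitney two-sample test
#'
#' Two-sided rank-sum test. In `"auto"` mode the exact null distribution is
#' used when `n_x + n_y <= 20` and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param mode `"auto"` (default), `"exact"` or `"normal_approx"`.
#' @param alpha Significance level for the decision.
#' @return An `ssm_test`; `statistic` is the Mann-Whitney U of `x`.
#' @export
wilcoxon_mann_whitney <- function(x, y, mode = c("auto", "exact", "normal_approx"),
                                  alpha = 0.05) {
  mode <- match.arg(mode)
  if (length(x) < 1 || length(y) < 1)
    ssm_stop("both groups must be non-empty", "parameter_error")
  ties <- any(duplicated(c(x, y)))
  exact <- switch(mode,
                  exact = TRUE,
                  normal_approx = FALSE,
                  auto = (length(x) + length(y) <= 20) && !ties)
  f <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  test_result(f$statistic, f$p.value, "wmw",
              c(n_x = length(x), n_y = length(y)), alpha)
}

#' Kruskal-Wallis test for two or more groups
#'
#' H statistic with tie correction; p-value from the chi-square distribution
#' with `length(groups) - 1` degrees of freedom.
#'
#' @param groups List of numeric vectors (>= 2 groups, total n >= 3).
#' @param alpha Significance level for the decision.
#' @return An `ssm_test`.
#' @export
kruskal_wallis <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2)
    ssm_stop("need at least 2 groups", "parameter_error")
  if (any(lengths(groups) < 1) || sum(lengths(groups)) < 3)
    ssm_stop("each group non-empty and total n >= 3", "parameter_error")
  f <- stats::kruskal.test(groups)
  test_result(f$statistic, f$p.value, "kruskal_wallis", lengths(groups), alpha)
}

#' Per-index between-cluster comparison report
#'
#' For each index, tests whether the chosen descriptor differs between the
#' clusters of `solution`: Wilcoxon-Mann-Whitney when `k = 2`, Kruskal-Wallis
#' otherwise. Raw p-values are reported by default (Holm adjustment
#' available). A test is skipped (flagged) when some cluster's values are
#' all identical.
#'
#' @param fm Feature matrix from [build_feature_matrix()].
#' @param solution An `ssm_clustering` whose labels align with `fm` rows.
#' @param descriptor Descriptor column to test (default `"mean"`).
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (default) or `"holm"`.
#' @return A data.frame with columns `index`, `statistic`, `p_value`,
#'   `method`, `outcome` (`"Rejected"` / `"Failed to reject"` /
#'   `"Skipped"`), `flagged`.
#' @export
compare_clusters <- function(fm, solution, descriptor = "mean",
                             alpha = 0.05, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  labels <- solution$labels
  if (length(labels) != nrow(fm))
    ssm_stop("labels do not align with the feature matrix", "schema_error")
  if (max(labels) < 2 || any(tabulate(labels, max(labels)) == 0))
    ssm_stop("need >= 2 non-empty clusters", "parameter_error")
  grouping <- attr(fm, "grouping")
  indices <- unique(grouping)
  rows <- lapply(indices, function(ix) {
    col <- paste0(ix, "_", descriptor)
    if (!col %in% names(fm))
      ssm_stop(paste0("missing feature column ", col), "schema_error")
    v <- fm[[col]]
    groups <- split(v, labels)
    flagged <- any(vapply(groups, function(g) length(unique(g)) == 1, TRUE))
    if (flagged)
      return(data.frame(index = ix, statistic = NA_real_, p_value = NA_real_,
                        method = NA_character_, flagged = TRUE))
    t <- if (max(labels) == 2)
      wilcoxon_mann_whitney(groups[[1]], groups[[2]], alpha = alpha)
    else kruskal_wallis(groups, alpha = alpha)
    data.frame(index = ix, statistic = t$statistic, p_value = t$p_value,
               method = t$method, flagged = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "holm")
    out$p_value <- stats::p.adjust(out$p_value, "holm")
  out$outcome <- ifelse(out$flagged, "Skipped",
                        ifelse(out$p_value < alpha, "Rejected",
                               "Failed to reject"))
  out[, c("index", "statistic", "p_value", "method", "outcome", "flagged")]
}
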