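# Rank-test wrappers against enumeration oracles, hand-computed statistics,
# asymptotic agreement, and the per-index cluster report.

test_that("exact WMW equals full enumeration for all small group sizes", {
  expect_equal(wilcoxon_mann_whitney(c(1, 2), c(3, 4), mode = "exact")$p_value,
               1 / 3, tolerance = 1e-12)
  set.seed(6)
  for (i in 1:25) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    x <- round(rnorm(nx), 3); y <- round(rnorm(ny) + 0.5, 3)
    if (any(duplicated(c(x, y)))) next
    got <- wilcoxon_mann_whitney(x, y, mode = "exact")$p_value
    expect_equal(got, wmw_enumerate(x, y), tolerance = 1e-9)
  }
})

test_that("identical samples give p = 1 and empty groups error", {
  x <- c(1, 2, 3)
  expect_equal(wilcoxon_mann_whitney(x, x)$p_value, 1)
  expect_error(wilcoxon_mann_whitney(numeric(0), x), class = "parameter_error")
})

test_that("auto mode switches to the normal approximation on ties or n > 20", {
  with_ties <- wilcoxon_mann_whitney(c(1, 2, 2), c(2, 3, 4))
  expect_true(is.finite(with_ties$p_value))
  set.seed(2)
  big <- wilcoxon_mann_whitney(rnorm(15), rnorm(15))
  expect_true(big$p_value >= 0 && big$p_value <= 1)
})

test_that("Kruskal-Wallis matches the hand-ranked statistic", {
  t <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(t$statistic, 4.5714, tolerance = 1e-4)
  # identical rank patterns give H = 0 after tie correction
  t0 <- kruskal_wallis(list(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  expect_error(kruskal_wallis(list(c(1, 2))), class = "parameter_error")
})

test_that("KW with 2 groups tracks the WMW normal approximation", {
  diffs <- vapply(1:100, function(s) {
    set.seed(s)
    x <- rnorm(50); y <- rnorm(50, 0.2)
    abs(kruskal_wallis(list(x, y))$p_value -
          wilcoxon_mann_whitney(x, y, mode = "normal_approx")$p_value)
  }, 0)
  expect_true(all(diffs < 0.02))
})

test_that("Shapiro-Wilk gates normality and rejects strong skew", {
  set.seed(4)
  expect_gt(shapiro_wilk(rnorm(50))$p_value, 0)
  rej <- mean(vapply(1:50, function(s) {
    set.seed(s)
    shapiro_wilk(rexp(50))$p_value < 0.05
  }, TRUE))
  expect_gt(rej, 0.9)
  expect_error(shapiro_wilk(rep(1, 10)), class = "degenerate_error")
  expect_error(shapiro_wilk(c(1, 2)), class = "parameter_error")
})

planted_fm <- function(shift_index, shift, labels, seed,
                       indices = c("ACI", "ADI", "AEI", "H", "DSC")) {
  set.seed(seed)
  cols <- as.vector(outer(c("mean", "median", "mode", "sd", "iqr",
                            "skewness", "kurtosis"), indices,
                          function(d, i) paste0(i, "_", d)))
  X <- matrix(rnorm(length(labels) * length(cols)), length(labels))
  colnames(X) <- cols
  X[, paste0(shift_index, "_mean")] <-
    X[, paste0(shift_index, "_mean")] + shift * (labels - 1)
  fm <- data.frame(site_id = sprintf("S%02d", seq_along(labels)), X,
                   check.names = FALSE)
  attr(fm, "grouping") <- stats::setNames(rep(indices, each = 7), cols)
  fm
}

test_that("a planted shift in one index is the one rejected", {
  labels <- rep(1:2, each = 8)
  sol <- structure(list(labels = labels, k = 2L, algorithm = "plant"),
                   class = "ssm_clustering")
  hits <- vapply(1:10, function(s) {
    fm <- planted_fm("ADI", 4, labels, seed = s)
    tab <- compare_clusters(fm, sol)
    tab$outcome[tab$index == "ADI"] == "Rejected" &&
      all(tab$outcome[tab$index != "ADI"] == "Failed to reject")
  }, TRUE)
  expect_gte(sum(hits), 9)
})

test_that("identical groups all fail to reject and k = 3 dispatches to KW", {
  labels <- rep(1:2, each = 8)
  sol <- structure(list(labels = labels, k = 2L, algorithm = "null"),
                   class = "ssm_clustering")
  fm <- planted_fm("ADI", 0, labels, seed = 99)
  tab <- compare_clusters(fm, sol)
  expect_true(all(tab$outcome == "Failed to reject"))
  expect_true(all(tab$method == "wmw"))
  labels3 <- rep(1:3, c(6, 5, 5))
  sol3 <- structure(list(labels = labels3, k = 3L, algorithm = "null"),
                    class = "ssm_clustering")
  fm3 <- planted_fm("ADI", 0, labels3, seed = 100)
  tab3 <- compare_clusters(fm3, sol3)
  expect_true(all(tab3$method == "kruskal_wallis"))
})

test_that("a cluster with constant values is flagged and skipped", {
  labels <- rep(1:2, each = 4)
  sol <- structure(list(labels = labels, k = 2L, algorithm = "x"),
                   class = "ssm_clustering")
  fm <- planted_fm("ACI", 0, labels, seed = 3)
  fm$ACI_mean[labels == 1] <- 7
  tab <- compare_clusters(fm, sol)
  expect_identical(tab$outcome[tab$index == "ACI"], "Skipped")
  expect_true(tab$flagged[tab$index == "ACI"])
  expect_false(any(tab$flagged[tab$index != "ACI"]))
})
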