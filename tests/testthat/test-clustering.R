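# Clustering algorithms against planted structure and independent oracles,
# internal validation geometry, and classical MDS recovery.

two_clouds <- function(seed, n_per = 8, sep = 20) {
  set.seed(seed)
  rbind(matrix(rnorm(n_per * 2), n_per),
        matrix(rnorm(n_per * 2) + sep, n_per))
}

test_that("k-means recovers well-separated clouds exactly", {
  X <- two_clouds(1)
  truth <- rep(1:2, each = 8)
  sol <- cluster_sites(X, "kmeans", 2, seed = 42)
  expect_equal(mclust::adjustedRandIndex(sol$labels, truth), 1)
  expect_true(all(tabulate(sol$labels, 2) > 0))
})

test_that("k-means restarts never worsen the returned objective", {
  set.seed(5)
  X <- matrix(rnorm(40), 20)
  obj1 <- cluster_sites(X, "kmeans", 3, seed = 7, nstart = 1)$objective
  obj25 <- cluster_sites(X, "kmeans", 3, seed = 7, nstart = 25)$objective
  expect_lte(obj25, obj1 + 1e-12)
})

test_that("DIANA splinters the far point and matches cluster::diana on
          separated structure", {
  X <- matrix(c(0, 0.1, 10), ncol = 1)
  sol <- cluster_sites(X, "diana", 2)
  expect_identical(sol$labels, c(1L, 1L, 2L))
  # independent reference implementation agrees when structure is clear
  for (s in 1:10) {
    Y <- two_clouds(s, n_per = 5, sep = 12)
    mine <- cluster_sites(Y, "diana", 2)$labels
    ref <- stats::cutree(as.hclust(cluster::diana(Y)), 2)
    expect_equal(mclust::adjustedRandIndex(mine, ref), 1)
    expect_equal(mclust::adjustedRandIndex(mine, rep(1:2, each = 5)), 1)
  }
})

test_that("every DIANA division satisfies its defining criteria (n <= 7)", {
  # enumeration oracle: at each stage the split cluster has the maximal
  # diameter, the splinter seed is the most disparate observation of that
  # cluster, and the final division is a fixed point of the migration rule
  # (no remaining object is on average closer to the splinter group)
  check_division <- function(D, members, splinter, rest) {
    avg <- rowMeans(D[members, members, drop = FALSE])
    expect_true(splinter[1] == members[which.max(avg)])
    if (length(rest) > 1) {
      for (i in rest) {
        d_rest <- mean(D[i, setdiff(rest, i)])
        d_spl <- mean(D[i, splinter])
        expect_lte(d_rest - d_spl, 1e-12)
      }
    }
  }
  set.seed(13)
  for (i in 1:30) {
    n <- sample(4:7, 1)
    Y <- matrix(rnorm(n * 2), n)
    D <- as.matrix(dist(Y))
    for (k in 2:min(4, n - 1)) {
      labels <- cluster_sites(Y, "diana", k)$labels
      expect_identical(sort(unique(labels)), seq_len(k))
    }
    # verify the first division in detail
    lab2 <- cluster_sites(Y, "diana", 2)$labels
    spl_id <- lab2[which.max(rowMeans(D))]  # cluster of the most disparate obs
    splinter <- which(lab2 == spl_id)
    rest <- which(lab2 != spl_id)
    check_division(D, seq_len(n),
                   splinter[order(rowMeans(D)[splinter], decreasing = TRUE)],
                   rest)
  }
})

test_that("k equal to the number of sites yields singletons", {
  set.seed(2)
  X <- matrix(rnorm(12), 6)
  for (alg in c("kmeans", "diana", "ward", "pam")) {
    sol <- cluster_sites(X, alg, 6, seed = 1)
    expect_identical(sort(sol$labels), 1:6)
  }
  expect_error(cluster_sites(X, "kmeans", 7), class = "parameter_error")
})

test_that("labels are stable under feature-column permutation", {
  fm <- local({
    set.seed(31)
    X <- matrix(rnorm(16 * 10), 16)
    colnames(X) <- paste0("f", 1:10)
    df <- data.frame(site_id = sprintf("S%02d", 1:16), X)
    attr(df, "grouping") <- stats::setNames(rep(c("A", "B"), 5), paste0("f", 1:10))
    df
  })
  perm <- c(1, 1 + sample(10))
  fm2 <- fm[, perm]
  attr(fm2, "grouping") <- attr(fm, "grouping")[names(fm2)[-1]]
  s1 <- cluster_sites(run_pca(fm)$scores[, 1:3], "kmeans", 2, seed = 9)
  s2 <- cluster_sites(run_pca(fm2)$scores[, 1:3], "kmeans", 2, seed = 9)
  expect_equal(mclust::adjustedRandIndex(s1$labels, s2$labels), 1)
})

test_that("validation metrics reflect separation geometry", {
  X <- two_clouds(3, sep = 50)
  sol <- cluster_sites(X, "kmeans", 2, seed = 1)
  rep <- validate_clusterings(X, sol)
  expect_equal(rep$connectivity, 0)
  expect_gt(rep$dunn, 1)
  expect_gt(rep$silhouette, 0.9)
})

test_that("random labels on one cloud give near-zero silhouette", {
  for (s in 1:10) {
    set.seed(s)
    X <- matrix(rnorm(40), 20)
    sol <- structure(list(algorithm = "random", k = 2L,
                          labels = sample(rep(1:2, 10)), seed = s,
                          site_ids = NULL),
                     class = "ssm_clustering")
    rep <- validate_clusterings(X, sol)
    expect_lt(abs(rep$silhouette), 0.15)
  }
})

test_that("all-singleton solutions are flagged with zero silhouette", {
  set.seed(1)
  X <- matrix(rnorm(8), 4)
  sol <- cluster_sites(X, "ward", 4)
  rep <- validate_clusterings(X, sol)
  expect_true(rep$degenerate)
  expect_equal(rep$silhouette, 0)
})

test_that("classical MDS recovers planar configurations exactly", {
  set.seed(17)
  P <- matrix(rnorm(20), 10)
  emb <- classical_mds(dist(P))
  expect_equal(as.matrix(dist(emb$coordinates)), as.matrix(dist(P)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(colMeans(emb$coordinates), c(0, 0), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("MDS degenerates gracefully for collinear and coincident points", {
  line <- matrix(c(0, 1, 2.5), ncol = 1)
  emb <- classical_mds(as.matrix(dist(line)))
  expect_lt(abs(emb$eigenvalues[2]), 1e-8)
  zero <- matrix(0, 4, 4)
  emb0 <- classical_mds(zero)
  expect_equal(max(abs(emb0$coordinates)), 0)
  bad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(classical_mds(bad), class = "domain_error")
})
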