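# Site clustering (k-means with k-means++ seeding, DIANA, Ward, PAM),
# internal validation (silhouette, Dunn, connectivity) and classical MDS.
# All methods operate on the Euclidean geometry of the PCA scores; labels
# are renumbered by first occurrence (lowest site index) so runs are
# bit-reproducible.

relabel_by_first_occurrence <- function(labels) {
  as.integer(factor(labels, levels = unique(labels)))
}

# k-means++ seeding: first centre uniform, later centres sampled with
# probability proportional to squared distance to the nearest chosen centre.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  chosen <- sample.int(n, 1)
  for (j in seq_len(k - 1)) {
    d2 <- apply(X, 1, function(r)
      min(colSums((t(X[chosen, , drop = FALSE]) - r)^2)))
    d2[chosen] <- 0
    if (sum(d2) == 0) {
      cand <- setdiff(seq_len(n), chosen)
      chosen <- c(chosen, cand[1])
    } else {
      chosen <- c(chosen, sample.int(n, 1, prob = d2 / sum(d2)))
    }
  }
  X[chosen, , drop = FALSE]
}

diana_diameter <- function(D, members) {
  if (length(members) < 2) return(0)
  max(D[members, members])
}

# One DIANA splinter split of `members` (Macnaughton-Smith): seed the
# splinter with the observation of largest average dissimilarity, then move
# points whose average distance to the splinter is smaller than to the rest.
diana_split <- function(D, members) {
  avg <- rowMeans(D[members, members, drop = FALSE])
  splinter <- members[which.max(avg)]
  rest <- setdiff(members, splinter)
  repeat {
    if (length(rest) < 2) break
    d_rest <- vapply(rest, function(i)
      mean(D[i, setdiff(rest, i)]), 0)
    d_spl <- vapply(rest, function(i)
      mean(D[i, splinter]), 0)
    gain <- d_rest - d_spl
    if (max(gain) <= 0) break
    mv <- rest[which.max(gain)]
    splinter <- c(splinter, mv)
    rest <- setdiff(rest, mv)
  }
  list(splinter = splinter, rest = rest)
}

diana_labels <- function(D, k) {
  n <- nrow(D)
  clusters <- list(seq_len(n))
  while (length(clusters) < k) {
    diams <- vapply(clusters, function(m) diana_diameter(D, m), 0)
    target <- which.max(diams)  # ties -> lowest-index cluster
    sp <- diana_split(D, clusters[[target]])
    clusters <- c(clusters[-target], list(sp$rest), list(sp$splinter))
  }
  labels <- integer(n)
  for (i in seq_along(clusters)) labels[clusters[[i]]] <- i
  relabel_by_first_occurrence(labels)
}

#' Cluster sites on PCA scores
#'
#' Partitions the rows of `scores` into `k` groups under Euclidean distance.
#' `"kmeans"` uses k-means++ seeding with `nstart` restarts (fixed seed) and
#' Lloyd iterations, keeping the lowest within-cluster sum of squares;
#' `"diana"` is divisive analysis clustering (splinter the cluster with the
#' largest diameter until `k` clusters); `"ward"` cuts a Ward-linkage
#' agglomerative tree; `"pam"` is partitioning around medoids.
#'
#' @param scores Numeric matrix, sites x dimensions.
#' @param algorithm One of `"kmeans"`, `"diana"`, `"ward"`, `"pam"`.
#' @param k Number of clusters, `2 <= k <= nrow(scores)`.
#' @param seed Integer seed for the stochastic k-means initialisation.
#' @param nstart Number of k-means++ restarts (default 25).
#' @param site_ids Optional site labels attached to the solution.
#' @return An `ssm_clustering` list: `algorithm`, `k`, `labels` (1..k, every
#'   cluster non-empty), `seed`, `centers` or `medoids` where applicable,
#'   and `objective` (total within-cluster sum of squares for k-means).
#' @export
cluster_sites <- function(scores, algorithm = c("kmeans", "diana", "ward", "pam"),
                          k, seed = 1, nstart = 25, site_ids = NULL) {
  algorithm <- match.arg(algorithm)
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (k > n) ssm_stop("k exceeds the number of sites", "parameter_error")
  if (k < 1) ssm_stop("k must be >= 1", "parameter_error")
  centers <- NULL
  medoids <- NULL
  objective <- NA_real_
  if (k == n) {
    return(structure(list(algorithm = algorithm, k = as.integer(k),
                          labels = seq_len(n), seed = seed,
                          centers = scores, medoids = NULL, objective = 0,
                          site_ids = site_ids %||% rownames(scores)),
                     class = "ssm_clustering"))
  }
  if (algorithm == "kmeans") {
    fit <- with_seed(seed, {
      best <- NULL
      for (r in seq_len(nstart)) {
        init <- kmeanspp_centers(scores, k)
        km <- suppressWarnings(
          stats::kmeans(scores, centers = init, iter.max = 100,
                        algorithm = "Lloyd"))
        if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
      }
      best
    })
    labels <- relabel_by_first_occurrence(fit$cluster)
    centers <- fit$centers
    objective <- fit$tot.withinss
  } else if (algorithm == "diana") {
    labels <- diana_labels(as.matrix(stats::dist(scores)), k)
  } else if (algorithm == "ward") {
    hc <- stats::hclust(stats::dist(scores), method = "ward.D2")
    labels <- relabel_by_first_occurrence(stats::cutree(hc, k))
  } else {
    fit <- cluster::pam(scores, k, metric = "euclidean")
    labels <- relabel_by_first_occurrence(fit$clustering)
    medoids <- fit$medoids
  }
  structure(list(algorithm = algorithm, k = as.integer(k),
                 labels = labels, seed = seed,
                 centers = centers, medoids = medoids,
                 objective = objective,
                 site_ids = site_ids %||% rownames(scores)),
            class = "ssm_clustering")
}

#' @export
print.ssm_clustering <- function(x, ...) {
  cat(sprintf("<ssm_clustering> %s, k = %d; sizes: %s\n", x$algorithm, x$k,
              paste(tabulate(x$labels, x$k), collapse = "/")))
  invisible(x)
}

dunn_index <- function(D, labels) {
  k <- max(labels)
  inter <- Inf
  intra <- 0
  for (a in seq_len(k)) {
    ia <- which(labels == a)
    if (length(ia) > 1) intra <- max(intra, max(D[ia, ia]))
    for (b in seq_len(k)) if (b > a) {
      inter <- min(inter, min(D[ia, which(labels == b)]))
    }
  }
  if (intra == 0) return(Inf)
  inter / intra
}

connectivity_index <- function(D, labels, L = 5) {
  n <- nrow(D)
  total <- 0
  for (i in seq_len(n)) {
    nb <- order(D[i, -i])  # indices into the reduced vector
    others <- seq_len(n)[-i]
    for (j in seq_len(min(L, n - 1))) {
      if (labels[others[nb[j]]] != labels[i]) total <- total + 1 / j
    }
  }
  total
}

#' Internal validation of clustering solutions
#'
#' For each solution reports the mean silhouette width, the Dunn index
#' (minimum inter-cluster distance over maximum intra-cluster diameter) and
#' the connectivity (sum of `1/j` over each point's `j`-th nearest
#' neighbours that fall outside its cluster, `j = 1..L`; 0 is best).
#'
#' @param scores Numeric matrix the solutions were fitted on.
#' @param solutions A list of `ssm_clustering` objects (a single object is
#'   accepted).
#' @param L Number of nearest neighbours for connectivity (default 5).
#' @return A data.frame with columns `algorithm`, `k`, `silhouette`,
#'   `dunn`, `connectivity`, `degenerate` (TRUE when silhouette is
#'   undefined, e.g. all-singleton solutions, and reported as 0).
#' @export
validate_clusterings <- function(scores, solutions, L = 5) {
  if (inherits(solutions, "ssm_clustering")) solutions <- list(solutions)
  D <- as.matrix(stats::dist(as.matrix(scores)))
  rows <- lapply(solutions, function(sol) {
    lab <- sol$labels
    degenerate <- max(lab) == nrow(D) || max(lab) < 2
    sil <- if (degenerate) 0 else
      mean(cluster::silhouette(lab, dmatrix = D)[, "sil_width"])
    data.frame(algorithm = sol$algorithm, k = sol$k,
               silhouette = sil,
               dunn = dunn_index(D, lab),
               connectivity = connectivity_index(D, lab, L),
               degenerate = degenerate)
  })
  do.call(rbind, rows)
}

#' Classical (metric) multidimensional scaling
#'
#' Double-centres `-D^2 / 2`, eigendecomposes, and returns the leading
#' coordinates scaled by the square root of their eigenvalues — exact
#' recovery (up to rotation/reflection) for distances of true planar
#' configurations.
#'
#' @param distances Symmetric, non-negative matrix with zero diagonal
#'   (a `dist` object is accepted).
#' @param dims Number of embedding dimensions (default 2).
#' @return A list with `coordinates` (sites x dims, column means ~ 0) and
#'   `eigenvalues` of the doubly-centred matrix.
#' @export
classical_mds <- function(distances, dims = 2) {
  D <- as.matrix(distances)
  if (!isSymmetric(unname(D), tol = 1e-8) || any(D < 0) ||
      any(abs(diag(D)) > 1e-12))
    ssm_stop("distances must be symmetric, non-negative, zero-diagonal",
             "domain_error")
  fit <- suppressWarnings(stats::cmdscale(D, k = dims, eig = TRUE))
  coords <- fit$points
  if (is.null(coords) || ncol(coords) < dims) {
    pad <- matrix(0, nrow(D), dims - ncol(coords))
    coords <- cbind(coords, pad)
  }
  rownames(coords) <- rownames(D)
  list(coordinates = coords, eigenvalues = fit$eig)
}
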