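#!/usr/bin/env Rscript
# Dimensionality reduction and clustering: PCA on the standardised feature
# matrix, retention by the 78% cumulative-variance rule, per-index
# contribution table, k-means and DIANA solutions at k = 2, 3, 4 with
# internal validation, and a classical MDS embedding for display.
# Reads results/feature_matrix.csv; writes PCA/cluster tables to results/.

library(soundscapemap)

fm <- read_feature_matrix("results/feature_matrix.csv")
pca <- run_pca(fm)
d <- select_dimensions(pca, cum_var_target = 78)
cat(sprintf("explained variance: %s %%\n",
            paste(sprintf("%.1f", pca$explained_pct[1:5]), collapse = " ")))
cat(sprintf("retained d = %d dimensions (%.1f%% cumulative)\n",
            d, pca$cumulative_pct[d]))
utils::write.csv(
  data.frame(dimension = seq_along(pca$eigenvalues),
             eigenvalue = pca$eigenvalues,
             explained_pct = pca$explained_pct,
             cumulative_pct = pca$cumulative_pct),
  "results/pca_summary.csv", row.names = FALSE)

contrib <- variable_contributions(pca, dims = seq_len(max(3, d)))
print(round(contrib, 1))
utils::write.csv(data.frame(index = rownames(contrib), contrib),
                 "results/pca_contributions.csv", row.names = FALSE)

scores <- pca$scores[, seq_len(d), drop = FALSE]
rownames(scores) <- fm$site_id
solutions <- list()
for (alg in c("kmeans", "diana")) for (k in 2:4)
  solutions[[paste0(alg, "_k", k)]] <-
    cluster_sites(scores, alg, k, seed = 1, site_ids = fm$site_id)
labels <- data.frame(site_id = fm$site_id,
                     lapply(solutions, `[[`, "labels"), check.names = FALSE)
utils::write.csv(labels, "results/cluster_labels.csv", row.names = FALSE)

val <- validate_clusterings(scores, solutions)
print(val, digits = 3)
utils::write.csv(val, "results/cluster_validation.csv", row.names = FALSE)

mds <- classical_mds(dist(scores))
utils::write.csv(data.frame(site_id = fm$site_id, mds$coordinates),
                 "results/mds_coordinates.csv", row.names = FALSE)
cat("cluster sizes (kmeans k=2):",
    paste(tabulate(solutions$kmeans_k2$labels, 2), collapse = "/"), "\n")
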