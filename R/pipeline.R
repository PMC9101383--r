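# End-to-end orchestration: audio (synthetic or WAV files) -> per-second
# index series -> descriptor feature matrix -> PCA with dimension retention
# -> clustering at k = 2, 3, 4 -> internal validation, between-cluster rank
# tests, classical MDS, class maps -> CSV/GeoJSON artifacts plus a run
# manifest with seeds and a config hash.

config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

#' Run the full soundscape-mapping pipeline
#'
#' Executes every analysis stage on a synthetic study (or caller-supplied
#' clips) and writes the artifact bundle to `out_dir`: per-site index series
#' CSVs, the feature matrix, a PCA summary, cluster solutions with internal
#' validation, the per-index between-cluster test report, MDS coordinates,
#' equal-interval class maps (GeoJSON + CSV) and a JSON run manifest.
#'
#' @param study A [study_config()] (rendered internally) or the result of
#'   [generate_study()]; alternatively supply `clips` and `geo` directly.
#' @param out_dir Output directory (created if needed).
#' @param clips Optional named list of [audio_clip()]s (overrides `study`).
#' @param geo Optional site table `site_id`, `x`, `y` (with `clips`).
#' @param cfg An [index_config()]; defaults to the 5-index urban-park set
#'   ACI, ADI, AEI, H, DSC.
#' @param params A [spectrogram_params()] (defaults to 1024-point Hann at
#'   the clips' rate).
#' @param cum_var_target Cumulative-variance retention target (percent).
#' @param ks Cluster counts to fit (default `2:4`).
#' @param algorithms Clustering algorithms to run (default k-means and
#'   DIANA).
#' @param descriptor Descriptor tested between clusters (default "mean").
#' @param seed Seed for the stochastic stages (k-means restarts).
#' @return Invisibly, a list with every intermediate result: `series`,
#'   `features`, `pca`, `d`, `solutions`, `validation`, `tests`, `mds`,
#'   `map_classes`, `manifest`.
#' @export
run_pipeline <- function(study = study_config(), out_dir = tempfile("ssm_run_"),
                         clips = NULL, geo = NULL,
                         cfg = index_config(c("ACI", "ADI", "AEI", "H", "DSC")),
                         params = NULL,
                         cum_var_target = 78, ks = 2:4,
                         algorithms = c("kmeans", "diana"),
                         descriptor = "mean", seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL
  if (is.null(clips)) {
    bundle <- if (inherits(study, "study_config")) generate_study(study)
              else study
    clips <- bundle$clips
    geo <- bundle$geo
    truth <- bundle$truth
  }
  if (is.null(geo)) ssm_stop("site geometry required", "schema_error")
  rate <- clips[[1]]$rate
  if (is.null(params)) params <- spectrogram_params(rate)

  message(sprintf("indices: %d sites, index set {%s}", length(clips),
                  paste(cfg$index_set, collapse = ", ")))
  series <- lapply(clips, compute_indices, params = params, cfg = cfg)
  dir.create(file.path(out_dir, "series"), showWarnings = FALSE)
  for (s in series)
    write_index_series(s, file.path(out_dir, "series",
                                    paste0(s$site_id[1], ".csv")))
  n_deg <- sum(vapply(series, function(s) sum(s$degenerate), 0L))
  if (n_deg > 0) message(sprintf("flagged %d degenerate window-index values",
                                 n_deg))

  fm <- build_feature_matrix(series, cfg$index_set)
  write_feature_matrix(fm, file.path(out_dir, "feature_matrix.csv"))

  pca <- run_pca(fm)
  d <- select_dimensions(pca, cum_var_target = cum_var_target)
  message(sprintf("PCA: retaining %d dimensions (%.1f%% cumulative variance)",
                  d, pca$cumulative_pct[d]))
  utils::write.csv(
    data.frame(dimension = seq_along(pca$eigenvalues),
               eigenvalue = pca$eigenvalues,
               explained_pct = pca$explained_pct,
               cumulative_pct = pca$cumulative_pct),
    file.path(out_dir, "pca_summary.csv"), row.names = FALSE)
  contrib <- variable_contributions(pca, dims = seq_len(max(2, d)))
  utils::write.csv(data.frame(index = rownames(contrib), contrib),
                   file.path(out_dir, "pca_contributions.csv"),
                   row.names = FALSE)

  scores <- pca$scores[, seq_len(d), drop = FALSE]
  rownames(scores) <- fm$site_id
  solutions <- list()
  for (alg in algorithms) for (k in ks) {
    sol <- cluster_sites(scores, alg, k, seed = seed, site_ids = fm$site_id)
    solutions[[paste0(alg, "_k", k)]] <- sol
  }
  lab_tab <- data.frame(site_id = fm$site_id,
                        lapply(solutions, `[[`, "labels"),
                        check.names = FALSE)
  utils::write.csv(lab_tab, file.path(out_dir, "cluster_labels.csv"),
                   row.names = FALSE)
  validation <- validate_clusterings(scores, solutions)
  utils::write.csv(validation, file.path(out_dir, "cluster_validation.csv"),
                   row.names = FALSE)

  ref <- solutions[[paste0(algorithms[1], "_k2")]] %||% solutions[[1]]
  tests <- compare_clusters(fm, ref, descriptor = descriptor)
  utils::write.csv(tests, file.path(out_dir, "cluster_tests.csv"),
                   row.names = FALSE)

  mds <- classical_mds(stats::dist(scores))
  utils::write.csv(data.frame(site_id = fm$site_id, mds$coordinates),
                   file.path(out_dir, "mds_coordinates.csv"),
                   row.names = FALSE)

  mean_cols <- paste0(cfg$index_set, "_mean")
  map_classes <- data.frame(site_id = fm$site_id, stringsAsFactors = FALSE)
  for (col in mean_cols)
    map_classes[[paste0(col, "_class")]] <-
      classify_equal_intervals(fm[[col]])
  map_classes$cluster_k2 <- ref$labels
  export_map(geo, map_classes, file.path(out_dir, "site_map"))

  manifest <- list(package_version = "0.1.0",
                   seed = seed,
                   index_set = cfg$index_set,
                   n_sites = length(clips),
                   rate = rate,
                   window_len = params$window_len,
                   cum_var_target = cum_var_target,
                   retained_dimensions = d,
                   algorithms = algorithms, ks = ks,
                   config_hash = config_hash(list(cfg, params, cum_var_target,
                                                  ks, algorithms, descriptor,
                                                  seed)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(series = series, features = fm, pca = pca, d = d,
                 solutions = solutions, validation = validation,
                 tests = tests, mds = mds, map_classes = map_classes,
                 truth = truth, out_dir = out_dir, manifest = manifest))
}
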