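# Spatial outputs and survey cross-tabulations: equal-interval class maps,
# NDVI and 60 m region-of-interest statistics, aural-label proportions per
# cluster, and GeoJSON/CSV export of per-site attributes. Coordinates are a
# local planar grid in meters.

#' Classify values into equally spaced classes
#'
#' Class edges are `min + i * (max - min) / n`, half-open `[lo, hi)` with the
#' maximum assigned to the top class; a constant input puts every site in
#' class 1.
#'
#' @param values Numeric vector (at least one finite value).
#' @param n_classes Number of classes (default 4).
#' @return Integer class ids in `1..n_classes`.
#' @export
classify_equal_intervals <- function(values, n_classes = 4) {
  if (!any(is.finite(values)))
    ssm_stop("no finite values to classify", "domain_error")
  lo <- min(values); hi <- max(values)
  if (hi == lo) return(rep(1L, length(values)))
  w <- (hi - lo) / n_classes
  pmin(as.integer(floor((values - lo) / w)) + 1L, as.integer(n_classes))
}

#' Normalized Difference Vegetation Index
#'
#' Elementwise `(NIR - R) / (NIR + R)`; pixels where `NIR + R = 0` yield 0
#' and are counted in the attribute `degenerate_pixels`.
#'
#' @param nir,r Reflectance arrays of equal shape (dimensionless, >= 0).
#' @return Array in `[-1, 1]` of the same shape.
#' @export
ndvi <- function(nir, r) {
  if (!identical(dim(nir) %||% length(nir), dim(r) %||% length(r)))
    ssm_stop("NIR and R shapes differ", "schema_error")
  s <- nir + r
  out <- (nir - r) / s
  deg <- s == 0
  out[deg] <- 0
  structure(out, degenerate_pixels = sum(deg))
}

#' Classify NDVI into water / soil / vegetation
#'
#' Values below 0 are water, up to 0.4 soil, above 0.4 vegetation.
#'
#' @param v NDVI values.
#' @return Character vector of classes.
#' @export
classify_ndvi <- function(v) {
  ifelse(v < 0, "water", ifelse(v <= 0.4, "soil", "vegetation"))
}

#' Mean NDVI over a square region of interest per site
#'
#' Averages the pixels whose centres fall inside a `side_m` x `side_m`
#' square centred on each site (60 m by default). The raster is indexed
#' `[row, col]` with pixel centre of `[i, j]` at
#' `origin + ((j - 0.5), (i - 0.5)) * pixel_size`.
#'
#' @param ndvi_map NDVI matrix.
#' @param geo Data frame with `site_id`, `x`, `y` (meters).
#' @param side_m ROI side length in meters (default 60).
#' @param pixel_size Pixel size in meters.
#' @param origin Raster origin `c(x0, y0)` (default `c(0, 0)`).
#' @return Data frame `site_id`, `mean_ndvi`, `n_pixels`,
#'   `coverage_fraction` (covered pixel area over the ROI area).
#' @export
roi_mean_ndvi <- function(ndvi_map, geo, side_m = 60, pixel_size,
                          origin = c(0, 0)) {
  nr <- nrow(ndvi_map); nc <- ncol(ndvi_map)
  px <- origin[1] + (seq_len(nc) - 0.5) * pixel_size
  py <- origin[2] + (seq_len(nr) - 0.5) * pixel_size
  half <- side_m / 2
  rows <- lapply(seq_len(nrow(geo)), function(i) {
    jx <- which(px >= geo$x[i] - half & px <= geo$x[i] + half)
    iy <- which(py >= geo$y[i] - half & py <= geo$y[i] + half)
    if (length(jx) == 0 || length(iy) == 0)
      ssm_stop(sprintf("ROI of site %s does not intersect the raster",
                       geo$site_id[i]), "coverage_error")
    vals <- ndvi_map[iy, jx, drop = FALSE]
    data.frame(site_id = geo$site_id[i],
               mean_ndvi = mean(vals),
               n_pixels = length(vals),
               coverage_fraction = length(vals) * pixel_size^2 / side_m^2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bin perceived singing activity percentages
#'
#' Maps an activity percentage to the survey bins `[0-10]`, `(10-35]`,
#' `(35-65]`, `(65-85]`, `(85-100]`.
#'
#' @param pct Numeric percentages in `[0, 100]`.
#' @return Factor with the five bin labels.
#' @export
bin_singing_activity <- function(pct) {
  if (any(pct < 0 | pct > 100))
    ssm_stop("activity percentage outside [0, 100]", "domain_error")
  cut(pct, breaks = c(0, 10, 35, 65, 85, 100), include.lowest = TRUE,
      labels = c("[0-10]", "(10-35]", "(35-65]", "(65-85]", "(85-100]"))
}

#' Cross-tabulate aural labels by cluster
#'
#' For one label category, computes per cluster the proportion of labelled
#' minutes carrying each category value; every non-empty column sums to 1.
#'
#' @param labels Data frame of per-minute aural labels with a `site_id`
#'   column and one column per category.
#' @param solution An `ssm_clustering` with `site_ids`.
#' @param category Name of the label column to tabulate.
#' @return Matrix, rows = category values, columns = `cluster_1..k`
#'   (proportions). Clusters with no labelled minutes give a zero column and
#'   are listed in attribute `unlabelled_clusters`.
#' @export
aural_cross_tab <- function(labels, solution, category) {
  if (!category %in% names(labels))
    ssm_stop(paste0("no label category ", category), "schema_error")
  site_cluster <- stats::setNames(solution$labels, solution$site_ids)
  if (!all(labels$site_id %in% names(site_cluster)))
    ssm_stop("labelled site without a cluster", "schema_error")
  cl <- site_cluster[labels$site_id]
  vals <- sort(unique(as.character(labels[[category]])))
  k <- max(solution$labels)
  out <- matrix(0, length(vals), k,
                dimnames = list(vals, paste0("cluster_", seq_len(k))))
  unlabelled <- integer(0)
  for (g in seq_len(k)) {
    v <- as.character(labels[[category]][cl == g])
    if (length(v) == 0) { unlabelled <- c(unlabelled, g); next }
    tab <- table(factor(v, levels = vals))
    out[, g] <- as.numeric(tab) / length(v)
  }
  structure(out, unlabelled_clusters = unlabelled)
}

#' Export per-site attributes as GeoJSON and CSV
#'
#' Writes point features (one per site, ordered by `site_id`) with the given
#' attributes as properties, plus a flat CSV of the same table. Coordinates
#' are the local planar grid in meters; the GeoJSON carries a CRS note
#' saying so.
#'
#' @param geo Data frame `site_id`, `x`, `y`.
#' @param attributes Data frame keyed by `site_id` with per-site values.
#' @param path Output path without extension; `.geojson` and `.csv` are
#'   appended.
#' @return Character vector of the two paths, invisibly.
#' @export
export_map <- function(geo, attributes, path) {
  missing <- setdiff(geo$site_id, attributes$site_id)
  if (length(missing) > 0)
    ssm_stop(paste0("missing attributes for site(s): ",
                    paste(missing, collapse = ", ")), "schema_error")
  ord <- order(geo$site_id)
  geo <- geo[ord, ]
  tab <- merge(geo, attributes, by = "site_id", sort = TRUE)
  features <- lapply(seq_len(nrow(tab)), function(i) {
    props <- as.list(tab[i, setdiff(names(tab), c("x", "y")), drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(tab$x[i], tab$y[i])),
         properties = props)
  })
  gj <- list(type = "FeatureCollection",
             crs_note = "local planar grid, meters (not geographic)",
             features = features)
  geojson_path <- paste0(path, ".geojson")
  csv_path <- paste0(path, ".csv")
  jsonlite::write_json(gj, geojson_path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(tab, csv_path, row.names = FALSE)
  invisible(c(geojson_path, csv_path))
}
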