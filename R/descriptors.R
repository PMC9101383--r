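# The seven statistical descriptors of an index time series, and the
# site x (index, descriptor) feature matrix they assemble into.

DESCRIPTOR_NAMES <- c("mean", "median", "mode", "sd", "iqr",
                      "skewness", "kurtosis")

# Mode of a real-valued series. If the series contains repeated exact values
# the most frequent value wins (lowest on ties); otherwise the midpoint of
# the maximal-count histogram bin under the Freedman-Diaconis width (ties ->
# lowest bin).
series_mode <- function(x) {
  tab <- table(x)
  if (max(tab) > 1) return(as.numeric(names(tab)[which.max(tab)]))
  n <- length(x)
  h <- 2 * stats::IQR(x) / n^(1 / 3)
  if (h <= 0) h <- diff(range(x)) / ceiling(sqrt(n))
  if (h <= 0) return(x[1])
  lo <- min(x)
  nb <- max(1L, ceiling((max(x) - lo) / h))
  bin <- pmin(floor((x - lo) / h) + 1L, nb)
  lo + (which.max(tabulate(bin, nb)) - 0.5) * h
}

#' Summarise an index time series with seven descriptors
#'
#' Computes mean, median, mode, sample standard deviation, interquartile
#' range (linear-interpolation quantiles), moment skewness `g1` and excess
#' kurtosis `g2`. A constant series returns `sd = iqr = 0` and
#' `skewness = kurtosis = 0` by convention.
#'
#' @param values Numeric vector, length >= 2.
#' @return Named numeric vector with elements `mean`, `median`, `mode`,
#'   `sd`, `iqr`, `skewness`, `kurtosis`.
#' @export
summarize_series <- function(values) {
  if (length(values) < 2)
    ssm_stop("need at least 2 values to summarise", "insufficient_data_error")
  if (!all(is.finite(values)))
    ssm_stop("values must be finite", "domain_error")
  constant <- length(unique(values)) == 1
  c(mean = mean(values),
    median = stats::median(values),
    mode = series_mode(values),
    sd = if (constant) 0 else stats::sd(values),
    iqr = stats::IQR(values, type = 7),
    skewness = if (constant) 0 else e1071::skewness(values, type = 1),
    kurtosis = if (constant) 0 else e1071::kurtosis(values, type = 1))
}

#' Assemble the site x feature matrix
#'
#' One row per site, one column per (index, descriptor) pair, index-major
#' then descriptor order, named `INDEX_descriptor`. With the full 7-index
#' set this gives 49 columns; with the 5-index urban-park subset, 35.
#'
#' @param series_list List of long-form index series
#'   (from [compute_indices()]), one per site.
#' @param index_set Character vector of indices expected for every site;
#'   defaults to the indices present in the first series.
#' @return A data.frame with first column `site_id` (rows ordered by it)
#'   followed by the numeric feature columns; attribute `grouping` maps each
#'   feature column to its index.
#' @export
build_feature_matrix <- function(series_list, index_set = NULL) {
  stopifnot(length(series_list) >= 1)
  if (is.null(index_set)) index_set <- unique(series_list[[1]]$index)
  rows <- lapply(series_list, function(s) {
    site <- unique(s$site_id)
    stopifnot(length(site) == 1)
    feats <- lapply(index_set, function(ix) {
      v <- s$value[s$index == ix]
      if (length(v) < 2)
        ssm_stop(sprintf("site %s is missing index %s", site, ix),
                 "schema_error")
      d <- summarize_series(v)
      stats::setNames(d, paste0(ix, "_", names(d)))
    })
    c(site_id = site, unlist(feats))
  })
  site_ids <- vapply(rows, `[[`, "", "site_id")
  ord <- order(site_ids)
  X <- do.call(rbind, lapply(rows[ord], function(r)
    as.numeric(r[-1])))
  colnames(X) <- names(rows[[1]])[-1]
  fm <- data.frame(site_id = site_ids[ord], X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  attr(fm, "grouping") <- stats::setNames(
    rep(index_set, each = length(DESCRIPTOR_NAMES)), colnames(X))
  fm
}

#' Write / read a feature matrix as CSV (bit-faithful round trip)
#'
#' @param fm A feature matrix from [build_feature_matrix()].
#' @param path CSV path.
#' @return `path` invisibly (writer); the feature matrix (reader).
#' @export
write_feature_matrix <- function(fm, path) {
  df <- fm
  df[-1] <- lapply(df[-1], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  fm <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  idx <- unique(sub("_[a-z]+$", "", names(fm)[-1]))
  attr(fm, "grouping") <- stats::setNames(
    rep(idx, each = length(DESCRIPTOR_NAMES)), names(fm)[-1])
  fm
}
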