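# Per-second index time series for one site/session, in tidy long form:
# site_id, t_start_s, index, value, degenerate.

compute_block_indices <- function(block, cfg) {
  out <- lapply(cfg$index_set, function(ix) {
    v <- switch(ix,
                ACI  = aci(block),
                ADI  = adi(band_occupancy(block, cfg)),
                AEI  = aei(band_occupancy(block, cfg)),
                H    = entropy_h(block),
                BI   = bi(block, cfg),
                NDSI = ndsi(block, cfg),
                DSC  = dsc(block, cfg))
    data.frame(index = ix, value = as.numeric(v),
               degenerate = isTRUE(attr(v, "degenerate")))
  })
  do.call(rbind, out)
}

#' Compute all configured indices on 1-second windows of a clip
#'
#' Computes the spectrogram, restricts it to the analysis band, tiles it into
#' integration blocks, and evaluates every index in `cfg$index_set` on each
#' block.
#'
#' @param clip An [audio_clip()] of at least one integration period.
#' @param params A [spectrogram_params()].
#' @param cfg An [index_config()].
#' @param integration Integration time per window in seconds (default 1).
#' @return A data.frame (long form) with columns `site_id`, `t_start_s`,
#'   `index`, `value`, `degenerate`; one row per window and index.
#' @export
compute_indices <- function(clip, params = spectrogram_params(clip$rate),
                            cfg = index_config(), integration = 1.0) {
  spec <- compute_spectrogram(clip, params)
  spec <- mask_band(spec, cfg$flim)
  blocks <- tile_windows(spec, integration)
  res <- lapply(seq_along(blocks), function(b) {
    df <- compute_block_indices(blocks[[b]], cfg)
    df$t_start_s <- blocks[[b]]$times[1]
    df
  })
  out <- do.call(rbind, res)
  out$site_id <- clip$site_id
  out[, c("site_id", "t_start_s", "index", "value", "degenerate")]
}

#' Write / read an index series as tidy CSV
#'
#' @param series A data.frame from [compute_indices()].
#' @param path CSV path.
#' @return `path` invisibly (writer); the data.frame (reader).
#' @export
write_index_series <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_index_series
#' @export
read_index_series <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
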