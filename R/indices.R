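# The seven eco-acoustic indices, each computed on one integration block of a
# linear-magnitude spectrogram. Degenerate (all-silent) inputs yield flagged
# zeros rather than errors so long field recordings never abort; the flag is
# attached as attribute "degenerate".

flag_value <- function(value, degenerate = FALSE) {
  structure(value, degenerate = degenerate)
}

#' Index configuration
#'
#' Bundles the band and threshold settings of the indices. Defaults follow
#' the adapted urban-park configuration: NDSI anthrophony below 1 kHz,
#' biophony and BI band 1–8 kHz, ADI/AEI bands of 1 kHz width up to 24 kHz
#' with a −50 dB occupancy threshold relative to the block maximum.
#'
#' @param index_set Character subset of
#'   `c("ACI","ADI","AEI","H","BI","NDSI","DSC")`; order is kept.
#' @param flim Analysis band applied to the spectrogram before any index
#'   (Hz); default 100 Hz – 24 kHz.
#' @param adi_band_width,adi_max_freq Band width and ceiling (Hz) for the
#'   occupancy bands shared by ADI and AEI.
#' @param adi_db_threshold Occupancy threshold in dB relative to the block's
#'   maximum magnitude (default −50).
#' @param bi_band Biophony band `[f_lo, f_hi]` in Hz for BI (default
#'   `c(1000, 8000)`).
#' @param ndsi_anthro,ndsi_bio Anthrophony and biophony bands (Hz) for NDSI;
#'   must not overlap.
#' @param dsc_aggregation `"mean_of_frame_centroids"` (default) averages
#'   per-frame spectral centroids; `"centroid_of_mean_spectrum"` takes the
#'   centroid of the time-averaged spectrum.
#' @return A list of class `index_config`.
#' @export
index_config <- function(index_set = c("ACI", "ADI", "AEI", "H", "BI", "NDSI", "DSC"),
                         flim = c(100, 24000),
                         adi_band_width = 1000, adi_max_freq = 24000,
                         adi_db_threshold = -50,
                         bi_band = c(1000, 8000),
                         ndsi_anthro = c(100, 1000), ndsi_bio = c(1000, 8000),
                         dsc_aggregation = c("mean_of_frame_centroids",
                                             "centroid_of_mean_spectrum")) {
  dsc_aggregation <- match.arg(dsc_aggregation)
  all_idx <- c("ACI", "ADI", "AEI", "H", "BI", "NDSI", "DSC")
  index_set <- match.arg(index_set, all_idx, several.ok = TRUE)
  if (ndsi_anthro[2] > ndsi_bio[1])
    ssm_stop("NDSI anthrophony and biophony bands overlap", "configuration_error")
  if (bi_band[1] >= bi_band[2])
    ssm_stop("BI band is empty", "configuration_error")
  structure(list(index_set = index_set, flim = flim,
                 adi_band_width = adi_band_width, adi_max_freq = adi_max_freq,
                 adi_db_threshold = adi_db_threshold,
                 bi_band = bi_band, ndsi_anthro = ndsi_anthro,
                 ndsi_bio = ndsi_bio, dsc_aggregation = dsc_aggregation),
            class = "index_config")
}

#' Acoustic Complexity Index
#'
#' Sums, over frequency bins, the absolute frame-to-frame magnitude change
#' normalised by the bin's total magnitude:
#' `ACI = sum_f [ sum_t |A(f,t+1) - A(f,t)| / sum_t A(f,t) ]`.
#' Bins with zero total magnitude contribute 0. Sensitive to modulated
#' (biotic) sound, insensitive to level scaling and to stationary noise.
#'
#' @param block A `spectrogram` with at least 2 frames.
#' @return Non-negative scalar with attribute `degenerate`.
#' @export
aci <- function(block) {
  A <- block$A
  if (ncol(A) < 2)
    ssm_stop("ACI needs at least 2 frames", "insufficient_frames_error")
  denom <- rowSums(A)
  num <- rowSums(abs(A[, -1, drop = FALSE] - A[, -ncol(A), drop = FALSE]))
  ok <- denom > 0
  flag_value(sum(num[ok] / denom[ok]), !any(ok))
}

# Assign each spectrogram row to an occupancy band of width band_width
# starting at 0 Hz, up to max_freq (last band may be truncated). Returns an
# integer band id per row (NA outside the analysis span).
band_ids <- function(freqs, band_width, max_freq) {
  id <- findInterval(freqs, seq(0, max_freq, by = band_width),
                     rightmost.closed = FALSE, left.open = TRUE)
  id[freqs == 0] <- 1L
  id[freqs > max_freq] <- NA_integer_
  id
}

#' Per-band occupancy proportions (substrate of ADI and AEI)
#'
#' Splits the masked spectrogram into bands of `cfg$adi_band_width` Hz up to
#' `cfg$adi_max_freq` and returns, per band, the fraction of cells whose
#' level `20*log10(A / max(A))` exceeds `cfg$adi_db_threshold`.
#'
#' @param block A `spectrogram`.
#' @param cfg An [index_config()].
#' @return Named numeric vector of proportions (not normalised), attribute
#'   `degenerate` set for an all-zero block.
#' @export
band_occupancy <- function(block, cfg = index_config()) {
  ids <- band_ids(block$freqs, cfg$adi_band_width, cfg$adi_max_freq)
  keep <- !is.na(ids)
  if (!any(keep))
    ssm_stop("no occupancy band inside the masked range", "configuration_error")
  ids <- ids[keep]
  A <- block$A[keep, , drop = FALSE]
  amax <- max(A)
  bands <- sort(unique(ids))
  if (amax == 0)
    return(flag_value(stats::setNames(numeric(length(bands)),
                                      paste0("band", bands)), TRUE))
  above <- 20 * log10(A / amax) > cfg$adi_db_threshold
  p <- vapply(bands, function(b) mean(above[ids == b, , drop = FALSE]), 0)
  flag_value(stats::setNames(p, paste0("band", bands)), FALSE)
}

#' Acoustic Diversity Index
#'
#' Shannon entropy (nats) of the normalised band occupancy vector:
#' `q_b = p_b / sum(p)`, `ADI = -sum q_b log q_b` with `0 log 0 = 0`.
#' All-zero occupancy gives 0 (flagged).
#'
#' @param p Occupancy proportions from [band_occupancy()].
#' @return Scalar in `[0, log(n)]` nats.
#' @export
adi <- function(p) {
  if (length(p) < 1) ssm_stop("empty proportion vector", "domain_error")
  if (any(p < 0)) ssm_stop("negative proportions", "domain_error")
  s <- sum(p)
  if (s == 0) return(flag_value(0, TRUE))
  q <- p / s
  q <- q[q > 0]
  flag_value(-sum(q * log(q)), FALSE)
}

#' Acoustic Evenness Index
#'
#' Gini coefficient of the band occupancy vector:
#' `G = sum_ij |p_i - p_j| / (2 n^2 mean(p))`; 0 for perfectly even
#' occupancy, `(n-1)/n` when a single band is occupied. All-zero occupancy
#' gives 0 (flagged).
#'
#' @inheritParams adi
#' @return Scalar in `[0, 1]`.
#' @export
aei <- function(p) {
  if (length(p) < 1) ssm_stop("empty proportion vector", "domain_error")
  if (any(p < 0)) ssm_stop("negative proportions", "domain_error")
  n <- length(p)
  mu <- mean(p)
  if (mu == 0) return(flag_value(0, TRUE))
  flag_value(sum(abs(outer(p, p, "-"))) / (2 * n^2 * mu), FALSE)
}

#' Acoustic Entropy Index H
#'
#' Product of the normalised temporal entropy of the frame envelope (RMS
#' magnitude per frame) and the normalised spectral entropy of the mean
#' spectrum, both in `[0, 1]` (log base 2 normalised by the number of frames
#' and bins respectively).
#'
#' @param block A `spectrogram` with >= 2 frames and >= 2 bins.
#' @return Scalar in `[0, 1]`.
#' @export
entropy_h <- function(block) {
  A <- block$A
  if (ncol(A) < 2 || nrow(A) < 2)
    ssm_stop("H needs >= 2 frames and >= 2 bins", "insufficient_input_error")
  norm_entropy <- function(w) {
    s <- sum(w)
    if (s == 0) return(NA_real_)
    q <- w / s
    q <- q[q > 0]
    -sum(q * log2(q)) / log2(length(w))
  }
  e_t <- sqrt(colMeans(A^2))
  s_f <- rowMeans(A)
  ht <- norm_entropy(e_t)
  hf <- norm_entropy(s_f)
  if (is.na(ht) || is.na(hf)) return(flag_value(0, TRUE))
  flag_value(ht * hf, FALSE)
}

#' Bioacoustic Index
#'
#' Area under the mean dB spectrum within the biophony band, referenced to
#' the band minimum: the mean magnitude spectrum is converted to dB relative
#' to its maximum, restricted to `cfg$bi_band`, the band minimum subtracted,
#' and the result summed times the bin width in kHz (dB·kHz).
#'
#' @param block A `spectrogram`.
#' @param cfg An [index_config()].
#' @return Non-negative scalar (dB·kHz).
#' @export
bi <- function(block, cfg = index_config()) {
  in_band <- block$freqs >= cfg$bi_band[1] & block$freqs <= cfg$bi_band[2]
  if (sum(in_band) < 2)
    ssm_stop("BI band contains fewer than 2 bins", "configuration_error")
  s <- rowMeans(block$A)
  if (max(s) == 0) return(flag_value(0, TRUE))
  sdb <- 20 * log10(pmax(s, max(s) * 1e-8) / max(s))  # floor silent bins at -160 dB
  sb <- sdb[in_band]
  flag_value(sum(sb - min(sb)) * block$params$fr / 1000, FALSE)
}

#' Normalized Difference Soundscape Index
#'
#' `(B - A) / (B + A)` where `B` and `A` are the summed squared magnitudes
#' in the biophony and anthrophony bands; +1 for pure biophony, −1 for pure
#' technophony, 0 (flagged) if both bands are silent.
#'
#' @param block A `spectrogram`.
#' @param cfg An [index_config()].
#' @return Scalar in `[-1, 1]`.
#' @export
ndsi <- function(block, cfg = index_config()) {
  an <- block$freqs >= cfg$ndsi_anthro[1] & block$freqs <= cfg$ndsi_anthro[2]
  bi_rows <- block$freqs > cfg$ndsi_bio[1] & block$freqs <= cfg$ndsi_bio[2]
  if (!any(an) || !any(bi_rows))
    ssm_stop("empty NDSI band after masking", "configuration_error")
  a <- sum(block$A[an, , drop = FALSE]^2)
  b <- sum(block$A[bi_rows, , drop = FALSE]^2)
  if (a + b == 0) return(flag_value(0, TRUE))
  flag_value((b - a) / (b + a), FALSE)
}

#' Dynamic Spectral Centroid
#'
#' Amplitude-weighted mean frequency ("centre of mass") of the spectrum,
#' reported in kHz. By default the centroid is computed per frame and
#' averaged over frames with non-zero magnitude; alternatively the centroid
#' of the time-averaged spectrum.
#'
#' @param block A `spectrogram`.
#' @param cfg An [index_config()].
#' @return Non-negative scalar (kHz); 0 with `degenerate` flag for silence.
#' @export
dsc <- function(block, cfg = index_config()) {
  A <- block$A
  f <- block$freqs
  if (cfg$dsc_aggregation == "centroid_of_mean_spectrum") {
    s <- rowMeans(A)
    if (sum(s) == 0) return(flag_value(0, TRUE))
    return(flag_value(sum(s * f) / sum(s) / 1000, FALSE))
  }
  denom <- colSums(A)
  ok <- denom > 0
  if (!any(ok)) return(flag_value(0, TRUE))
  cent <- colSums(A * f)[ok] / denom[ok]
  flag_value(mean(cent) / 1000, FALSE)
}
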