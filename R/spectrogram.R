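# Fixed-resolution STFT magnitude spectrograms and 1-second tiling.
#
# The analysis operates at a fixed frequency resolution FR = rate/window_len
# (46.875 Hz for 48 kHz audio and 1024-point windows) and, because windows do
# not overlap, a time resolution TR = 1/FR. All downstream indices consume the
# linear-magnitude matrix produced here.

#' Spectrogram analysis parameters
#'
#' @param rate Sampling rate of the audio in Hz.
#' @param window_len Analysis window length in samples (default 1024).
#' @param hop Hop between consecutive windows in samples; defaults to
#'   `window_len`, i.e. no overlap, which makes the time resolution the exact
#'   reciprocal of the frequency resolution.
#' @param window_fn Taper: `"hann"` (default) or `"rectangular"`.
#' @return A list with the inputs plus `fr` (frequency resolution, Hz) and
#'   `tr` (time resolution, s), class `spectrogram_params`.
#' @export
spectrogram_params <- function(rate, window_len = 1024, hop = window_len,
                               window_fn = c("hann", "rectangular")) {
  window_fn <- match.arg(window_fn)
  if (window_len < 2) ssm_stop("window_len must be >= 2", "parameter_error")
  if (hop < 1) ssm_stop("hop must be >= 1", "parameter_error")
  structure(list(rate = rate, window_len = as.integer(window_len),
                 hop = as.integer(hop), window_fn = window_fn,
                 fr = rate / window_len, tr = window_len / rate),
            class = "spectrogram_params")
}

window_taper <- function(fn, n) {
  switch(fn,
         hann = 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1)),
         rectangular = rep(1, n))
}

#' Compute a linear-magnitude spectrogram
#'
#' Slices the clip into windows of `params$window_len` samples advancing by
#' `params$hop`, tapers each, and takes the magnitude of its discrete Fourier
#' transform. Trailing samples that do not fill a window are dropped.
#'
#' @param clip An [audio_clip()].
#' @param params A [spectrogram_params()]; defaults to 1024-point,
#'   non-overlapping Hann windows at the clip's rate.
#' @return A `spectrogram`: list with matrix `A` (rows = frequency bins
#'   `0..window_len/2`, cols = frames), `freqs` (Hz, bin k at `k * fr`),
#'   `times` (s, frame starts), and `params`.
#' @export
compute_spectrogram <- function(clip, params = spectrogram_params(clip$rate)) {
  stopifnot(inherits(clip, "audio_clip"))
  n <- length(clip$samples)
  wl <- params$window_len
  hop <- params$hop
  if (n < wl)
    ssm_stop("clip shorter than one analysis window", "insufficient_input_error")
  n_frames <- (n - wl) %/% hop + 1L
  frames <- if (hop == wl) {
    # contiguous non-overlapping windows: reshape directly
    matrix(clip$samples[seq_len(n_frames * wl)], nrow = wl)
  } else {
    idx <- rep(seq_len(wl), n_frames) +
      rep.int((seq_len(n_frames) - 1L) * hop, rep.int(wl, n_frames))
    matrix(clip$samples[idx], nrow = wl)
  }
  frames <- frames * window_taper(params$window_fn, wl)
  nb <- wl %/% 2 + 1L
  A <- Mod(stats::mvfft(frames))[seq_len(nb), , drop = FALSE]
  structure(list(A = A,
                 freqs = (seq_len(nb) - 1) * params$fr,
                 times = (seq_len(n_frames) - 1) * hop / clip$rate,
                 params = params),
            class = "spectrogram")
}

#' Restrict a spectrogram to a frequency interval
#'
#' Keeps only the rows whose bin centre lies in `[flim[1], flim[2]]`; the
#' default reproduces the analysis band of 100 Hz to 24 kHz applied before
#' index computation.
#'
#' @param spec A `spectrogram`.
#' @param flim Length-2 numeric, band edges in Hz.
#' @return The masked `spectrogram`.
#' @export
mask_band <- function(spec, flim = c(100, 24000)) {
  keep <- spec$freqs >= flim[1] & spec$freqs <= flim[2]
  if (!any(keep)) ssm_stop("mask removes every frequency bin", "parameter_error")
  spec$A <- spec$A[keep, , drop = FALSE]
  spec$freqs <- spec$freqs[keep]
  spec
}

#' Tile a spectrogram into fixed-duration integration blocks
#'
#' Splits the frame axis into contiguous non-overlapping blocks of
#' `floor(integration / tr)` frames (1-second blocks by default); a final
#' partial block is dropped.
#'
#' @param spec A `spectrogram`.
#' @param integration Block duration in seconds (default 1).
#' @return A list of `spectrogram` blocks. The number of dropped trailing
#'   frames is attached as attribute `dropped_frames`.
#' @export
tile_windows <- function(spec, integration = 1.0) {
  tr <- spec$params$hop / spec$params$rate
  if (integration < tr)
    ssm_stop("integration shorter than one frame", "parameter_error")
  J <- as.integer(floor(integration / tr))
  if (J < 2)
    ssm_stop("integration must span at least 2 frames", "integration_too_short_error")
  n_frames <- ncol(spec$A)
  n_blocks <- n_frames %/% J
  if (n_blocks < 1)
    ssm_stop("spectrogram shorter than one integration block",
             "insufficient_input_error")
  blocks <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    cols <- ((b - 1L) * J + 1L):(b * J)
    blk <- spec
    blk$A <- spec$A[, cols, drop = FALSE]
    blk$times <- spec$times[cols]
    blocks[[b]] <- blk
  }
  structure(blocks, dropped_frames = n_frames - n_blocks * J)
}

#' Dump a spectrogram matrix to CSV (debugging aid)
#'
#' @param spec A `spectrogram`.
#' @param path Output CSV path; rows = frequency bins with a `freq_hz` column.
#' @return `path`, invisibly.
#' @export
write_spectrogram_csv <- function(spec, path) {
  df <- data.frame(freq_hz = spec$freqs, spec$A, check.names = FALSE)
  names(df)[-1] <- sprintf("t%.6f", spec$times)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
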