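# Recorder-fleet quality control with white-noise exposures: an ACI
# tolerance screen around the fleet centre, the selected fleet's mean
# frequency response, and orientation correlation of response spectra.
# QC spectra use a 512-point transform, independent of the 1024-point
# analysis setting.

#' White-noise ACI of one recorder exposure
#'
#' Computes the acoustic complexity index of a white-noise calibration clip
#' over the whole clip as a single block, at 512-point resolution.
#'
#' @param clip An [audio_clip()] of the exposure.
#' @param window_len FFT length (default 512).
#' @return List with `aci_white` (scalar) and `spectrum` (mean magnitude per
#'   bin).
#' @export
recorder_response <- function(clip, window_len = 512) {
  spec <- compute_spectrogram(
    clip, spectrogram_params(clip$rate, window_len = window_len))
  list(aci_white = as.numeric(aci(spec)),
       spectrum = rowMeans(spec$A),
       freqs = spec$freqs)
}

#' Screen a recorder fleet by white-noise ACI
#'
#' Flags recorders whose white-noise ACI deviates from the fleet centre
#' (mean by default; median available because one gross outlier moves a
#' mean-centred band) by more than `tolerance` (relative). Single pass, no
#' re-centering.
#'
#' @param responses Data frame with columns `recorder_id` and `aci_white`.
#' @param tolerance Maximum relative deviation (default 0.03, the 3% rule).
#' @param center `"mean"` (default) or `"median"`.
#' @return A `qc_report` list: `center_value`, `tolerance`, `table` (one row
#'   per recorder with `relative_deviation` and `selected`, sorted by
#'   deviation), `selected`, `rejected`.
#' @export
white_noise_aci_screen <- function(responses, tolerance = 0.03,
                                   center = c("mean", "median")) {
  center <- match.arg(center)
  if (nrow(responses) < 2)
    ssm_stop("need at least 2 recorder responses", "parameter_error")
  ctr <- if (center == "mean") mean(responses$aci_white)
         else stats::median(responses$aci_white)
  rel <- abs(responses$aci_white - ctr) / ctr
  tab <- data.frame(recorder_id = responses$recorder_id,
                    aci_white = responses$aci_white,
                    relative_deviation = rel,
                    selected = rel <= tolerance,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$relative_deviation), ]
  rownames(tab) <- NULL
  structure(list(center = center, center_value = ctr, tolerance = tolerance,
                 table = tab,
                 selected = tab$recorder_id[tab$selected],
                 rejected = tab$recorder_id[!tab$selected]),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d/%d recorders within %.0f%% of %s ACI = %.4g\n",
              length(x$selected), nrow(x$table), 100 * x$tolerance,
              x$center, x$center_value))
  invisible(x)
}

#' Fleet mean spectrum with per-bin spread
#'
#' @param spectra Matrix, recorders x frequency bins (equal geometry).
#' @return List with `mean` and `sd` per bin (sample SD across recorders).
#' @export
mean_spectrum_band <- function(spectra) {
  spectra <- as.matrix(spectra)
  if (nrow(spectra) < 2)
    ssm_stop("need at least 2 recorders", "parameter_error")
  list(mean = colMeans(spectra), sd = apply(spectra, 2, stats::sd))
}

#' Orientation correlation of a response with the source spectrum
#'
#' Pearson correlation of the two magnitude spectra after conversion to dB
#' (relative to each spectrum's maximum).
#'
#' @param response_spectrum,source_spectrum Non-negative magnitude spectra of
#'   equal length >= 3.
#' @return Pearson r in `[-1, 1]`.
#' @export
orientation_correlation <- function(response_spectrum, source_spectrum) {
  if (length(response_spectrum) != length(source_spectrum) ||
      length(response_spectrum) < 3)
    ssm_stop("spectra must have equal length >= 3", "parameter_error")
  to_db <- function(s) {
    if (max(s) <= 0 || length(unique(s)) == 1)
      ssm_stop("constant or silent spectrum", "degenerate_error")
    20 * log10(pmax(s, max(s) * 1e-8) / max(s))
  }
  a <- to_db(response_spectrum)
  b <- to_db(source_spectrum)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    ssm_stop("constant spectrum in dB", "degenerate_error")
  stats::cor(a, b)
}

# Planted anomaly models. A pure gain or smooth EQ change cannot move the
# white-noise ACI (the index is scale-free per bin), so the planted defects
# are modulation/interference faults: intermittent dropouts and deep gain
# oscillation raise ACI, strong harmonic-comb interference lowers it.
apply_anomaly <- function(x, rate, type) {
  n <- length(x)
  switch(type,
    dropout = {
      n_mute <- 40
      starts <- sort(sample.int(n - rate %/% 8, n_mute))
      for (s in starts) x[s:(s + rate %/% 8)] <- 0
      x
    },
    hum = {
      # electrical interference: strong harmonic comb dominating ~24 bins,
      # whose near-constant magnitudes depress the summed per-bin variation
      t <- seq_len(n) / rate
      f0 <- 187.5
      comb <- rowSums(sapply(1:24, function(h) sin(2 * pi * h * f0 * t)))
      x + comb * stats::sd(x) * 1.5
    },
    am = {
      # motorboating preamp: deep slow gain oscillation raises frame-to-frame
      # magnitude variation in every bin
      t <- seq_len(n) / rate
      x * (1 + sin(2 * pi * 4 * t))
    },
    x)
}

#' Simulate a white-noise QC fleet with planted anomalies
#'
#' Generates `n_recorders` white-noise calibration exposures; the first
#' `n_recorders - n_anomalous` units are clean (flat response, small random
#' gain), the rest carry cyclically assigned dropout / harmonic-hum /
#' gain-oscillation defects that displace their white-noise ACI.
#'
#' @param n_recorders Fleet size (default 46).
#' @param n_anomalous Number of defective units (default 24).
#' @param duration Exposure length in seconds (default 10).
#' @param rate Sampling rate in Hz (default 48000).
#' @param level_dbfs Exposure level (default −20 dBFS).
#' @param seed Integer seed.
#' @return List with `responses` (data.frame `recorder_id`, `aci_white`,
#'   `anomaly`), `spectra` (matrix recorders x bins) and `clean_ids`.
#' @export
simulate_recorder_fleet <- function(n_recorders = 46, n_anomalous = 24,
                                    duration = 10, rate = 48000,
                                    level_dbfs = -20, seed = 1) {
  stopifnot(n_anomalous < n_recorders)
  types <- rep(c("dropout", "hum", "am"), length.out = n_anomalous)
  anomaly <- c(rep("none", n_recorders - n_anomalous), types)
  with_seed(seed, {
    rows <- vector("list", n_recorders)
    spectra <- NULL
    for (i in seq_len(n_recorders)) {
      x <- stats::rnorm(duration * rate)
      x <- x / rms(x) * dbfs_to_amp(level_dbfs) * stats::runif(1, 0.8, 1.25)
      x <- apply_anomaly(x, rate, anomaly[i])
      resp <- recorder_response(audio_clip(x, rate, sprintf("R%02d", i)))
      rows[[i]] <- data.frame(recorder_id = sprintf("R%02d", i),
                              aci_white = resp$aci_white,
                              anomaly = anomaly[i],
                              stringsAsFactors = FALSE)
      if (is.null(spectra))
        spectra <- matrix(NA_real_, n_recorders, length(resp$spectrum))
      spectra[i, ] <- resp$spectrum
    }
    responses <- do.call(rbind, rows)
    list(responses = responses, spectra = spectra,
         clean_ids = responses$recorder_id[responses$anomaly == "none"])
  })
}

#' Write a QC report table as CSV
#'
#' @param report A `qc_report`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  utils::write.csv(report$table, path, row.names = FALSE)
  invisible(path)
}
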