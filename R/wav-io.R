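# Minimal RIFF/PCM WAV reader and writer. Supports the formats consumer
# recorders actually produce: 8/16/24/32-bit integer PCM and 32-bit IEEE
# float, mono or multi-channel (channel 0 is used with a warning).

#' Construct an audio clip
#'
#' An `audio_clip` holds a mono waveform in full-scale units together with
#' its sampling rate and a site label. All acoustic stages of the package
#' start from this container.
#'
#' @param samples Numeric vector of samples, nominally in `[-1, 1]`.
#' @param rate Sampling rate in Hz (> 0).
#' @param site_id Text label for the recording site.
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(samples, rate, site_id = "site") {
  if (!is.numeric(samples) || length(samples) < 1)
    ssm_stop("samples must be a non-empty numeric vector", "empty_input_error")
  if (!all(is.finite(samples)))
    ssm_stop("samples must all be finite", "domain_error")
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0)
    ssm_stop("rate must be a single positive number", "domain_error")
  structure(list(samples = as.numeric(samples), rate = rate,
                 site_id = as.character(site_id)),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> site %s: %d samples @ %g Hz (%.2f s)\n",
              x$site_id, length(x$samples), x$rate,
              length(x$samples) / x$rate))
  invisible(x)
}

#' Read a PCM WAV file
#'
#' Reads a RIFF/WAVE file into an [audio_clip()]. Integer PCM samples are
#' scaled to `[-1, 1]` by the signed range of the bit depth (so a 16-bit
#' full-scale positive sample becomes 32767/32768). Multi-channel files are
#' reduced to channel 0 with a warning.
#'
#' @param path Path to the WAV file.
#' @param site_id Site label; defaults to the file name without extension.
#' @return An [audio_clip()].
#' @export
read_wav <- function(path, site_id = NULL) {
  if (!file.exists(path))
    ssm_stop(paste0("file not found: ", path), "format_error")
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    ssm_stop("not a RIFF file", "format_error")
  readBin(con, "integer", 1, 4, endian = "little")  # overall size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    ssm_stop("not a WAVE file", "format_error")

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        format    = readBin(fmt_raw[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        channels  = readBin(fmt_raw[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        rate      = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits      = readBin(fmt_raw[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + size %% 2)  # skip unknown chunk (word-aligned)
      next
    }
    if (size %% 2 == 1) readBin(con, "raw", 1)
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    ssm_stop("missing fmt/data chunk", "format_error")
  if (!fmt$format %in% c(1L, 3L))
    ssm_stop("only uncompressed PCM or float WAV supported", "format_error")
  if (length(data_raw) == 0)
    ssm_stop("zero-length data chunk", "empty_input_error")

  bytes <- fmt$bits %/% 8
  n_total <- length(data_raw) %/% bytes
  x <- switch(
    as.character(fmt$bits),
    "8"  = (as.numeric(readBin(data_raw, "integer", n_total, 1,
                               signed = FALSE)) - 128) / 128,
    "16" = as.numeric(readBin(data_raw, "integer", n_total, 2,
                              signed = TRUE, endian = "little")) / 32768,
    "24" = {
      m <- matrix(as.integer(data_raw[seq_len(n_total * 3)]), nrow = 3)
      v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
      v[v >= 2^23] <- v[v >= 2^23] - 2^24
      v / 2^23
    },
    "32" = if (fmt$format == 3L) {
      readBin(data_raw, "numeric", n_total, 4, endian = "little")
    } else {
      as.numeric(readBin(data_raw, "integer", n_total, 4,
                         endian = "little")) / 2^31
    },
    ssm_stop(paste0("unsupported bit depth: ", fmt$bits), "format_error")
  )
  if (fmt$channels > 1) {
    ssm_warn(sprintf("%d channels found; using channel 0 only", fmt$channels),
             "multichannel_warning")
    x <- x[seq(1, length(x), by = fmt$channels)]
  }
  if (length(x) == 0) ssm_stop("no samples decoded", "empty_input_error")
  audio_clip(x, fmt$rate,
             site_id %||% sub("\\.[Ww][Aa][Vv]$", "", basename(path)))
}

#' Write an audio clip as 16-bit PCM WAV
#'
#' @param clip An [audio_clip()]. Samples outside `[-1, 1]` are clipped.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- pmin(pmax(clip$samples, -1), 32767 / 32768)
  pcm <- as.integer(round(x * 32768))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, 4, endian = "little")
  writeBin(as.integer(c(1, 1)), con, 2, endian = "little")       # PCM, mono
  writeBin(as.integer(clip$rate), con, 4, endian = "little")
  writeBin(as.integer(clip$rate * 2), con, 4, endian = "little") # byte rate
  writeBin(as.integer(c(2, 16)), con, 2, endian = "little")      # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
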