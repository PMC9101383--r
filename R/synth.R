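# Seeded synthetic soundscape generator. Emulates the source inventory of an
# urban park bordered by a road: continuous low-frequency traffic noise whose
# level decays with distance from the road edge, Poisson-arriving bird chirps
# in the 1.5-8 kHz band, occasional broadband take-off transients, pulsed
# 1 kHz construction beeps, and optional broadband geophony. Every generator
# is reproducible from its seed and returns full-scale mono audio.

#' Synthesise continuous road-traffic noise
#'
#' Stationary Gaussian noise with a 4th-order Butterworth low-pass power
#' spectrum (400 Hz cutoff by default), so that well over 90% of its power
#' lies below 1 kHz, scaled to an exact RMS level. The noise is synthesised
#' in the frequency domain: independent Gaussian spectral coefficients are
#' weighted by the Butterworth magnitude response `1/sqrt(1 + (f/fc)^8)`
#' and inverse-transformed, which is exact and fast for long clips.
#'
#' @param duration Length in seconds (>= 1).
#' @param level_dbfs RMS level in dB relative to full scale.
#' @param rate Sampling rate in Hz (default 48000).
#' @param seed Integer seed (NULL = current RNG stream).
#' @param cutoff Low-pass cutoff in Hz (default 400).
#' @return An [audio_clip()].
#' @export
synth_traffic <- function(duration, level_dbfs = -20, rate = 48000,
                          seed = NULL, cutoff = 400) {
  if (duration < 1) ssm_stop("duration must be >= 1 s", "parameter_error")
  with_seed(seed, {
    n <- round(duration * rate)
    nh <- n %/% 2
    npos <- nh - 1 + n %% 2  # positive non-Nyquist bins
    f <- seq_len(npos) * rate / n
    H <- 1 / sqrt(1 + (f / cutoff)^8)
    # Hermitian spectrum with Gaussian coefficients, preallocated in place
    re <- numeric(n)
    im <- numeric(n)
    re[2:(npos + 1)] <- stats::rnorm(npos) * H
    im[2:(npos + 1)] <- stats::rnorm(npos) * H
    if (n %% 2 == 0)
      re[nh + 1] <- stats::rnorm(1) / sqrt(1 + (rate / 2 / cutoff)^8)
    re[n:(n - npos + 1)] <- re[2:(npos + 1)]
    im[n:(n - npos + 1)] <- -im[2:(npos + 1)]
    x <- Re(stats::fft(complex(real = re, imaginary = im),
                       inverse = TRUE)) / sqrt(n)
    audio_clip(x / rms(x) * dbfs_to_amp(level_dbfs), rate, "traffic")
  })
}

# Poisson chirp event table: start (s), duration (s), f0/f1 (Hz), amplitude.
draw_chirp_events <- function(duration, rate_per_min, band, seed = NULL) {
  with_seed(seed, {
    n <- stats::rpois(1, rate_per_min * duration / 60)
    if (n == 0)
      return(data.frame(start = numeric(0), duration = numeric(0),
                        f0 = numeric(0), f1 = numeric(0),
                        amplitude = numeric(0)))
    data.frame(start = stats::runif(n, 0, duration),
               duration = stats::runif(n, 0.1, 1.0),
               f0 = stats::runif(n, band[1], band[2]),
               f1 = stats::runif(n, band[1], band[2]),
               amplitude = stats::runif(n, 0.05, 0.30))
  })
}

#' Synthesise a Poisson stream of bird chirps
#'
#' Chirp count ~ Poisson(rate x duration); each chirp is a 0.1-1.0 s
#' linearly frequency-modulated tone inside `band` with a Hann amplitude
#' envelope and random amplitude; overlapping chirps sum.
#'
#' @param duration Length in seconds.
#' @param rate_per_min Mean chirp rate (events/minute, >= 0).
#' @param band Frequency band `c(lo, hi)` in Hz, within Nyquist.
#' @param rate Sampling rate in Hz.
#' @param seed Integer seed.
#' @return An [audio_clip()]; the event table is attached as attribute
#'   `events`.
#' @export
synth_chirps <- function(duration, rate_per_min = 30, band = c(1500, 8000),
                         rate = 48000, seed = NULL) {
  if (band[2] > rate / 2 || band[1] <= 0)
    ssm_stop("chirp band outside (0, Nyquist]", "parameter_error")
  ev <- draw_chirp_events(duration, rate_per_min, band, seed)
  n <- round(duration * rate)
  x <- numeric(n)
  for (i in seq_len(nrow(ev))) {
    ns <- round(ev$duration[i] * rate)
    t <- seq_len(ns) / rate
    phase <- 2 * pi * (ev$f0[i] * t +
                       (ev$f1[i] - ev$f0[i]) * t^2 / (2 * ev$duration[i]))
    env <- 0.5 - 0.5 * cos(2 * pi * seq_len(ns) / (ns + 1))
    s0 <- round(ev$start[i] * rate) + 1
    idx <- s0:min(s0 + ns - 1, n)
    x[idx] <- x[idx] + (ev$amplitude[i] * env * sin(phase))[seq_along(idx)]
  }
  clip <- audio_clip(if (all(x == 0)) x + 0 else x, rate, "chirps")
  attr(clip, "events") <- ev
  clip
}

#' Synthesise a distant take-off transient
#'
#' Noise burst with a rise-hold-decay envelope and the smoothly decaying
#' spectrum of a distant aircraft take-off: third-order roll-off above
#' `fc` (350 Hz default), low-frequency dominated with energy decaying
#' smoothly through the mid band. The transient displaces the occupancy
#' balance and the spectral centroid of its integration windows while
#' leaving the scale-free ACI nearly untouched.
#'
#' @param duration Event length in seconds (default 45, typical 30-60).
#' @param rate Sampling rate in Hz.
#' @param amplitude Peak envelope amplitude (default 0.3; 0 gives silence).
#' @param fc Spectral roll-off corner in Hz (default 350).
#' @param seed Integer seed.
#' @return An [audio_clip()] of the event segment.
#' @export
synth_takeoff <- function(duration = 45, rate = 48000, amplitude = 0.3,
                          fc = 350, seed = NULL) {
  with_seed(seed, {
    n <- round(duration * rate)
    nh <- n %/% 2
    npos <- nh - 1 + n %% 2
    f <- seq_len(npos) * rate / n
    H <- 1 / (1 + (f / fc)^3)
    re <- numeric(n); im <- numeric(n)
    re[2:(npos + 1)] <- stats::rnorm(npos) * H
    im[2:(npos + 1)] <- stats::rnorm(npos) * H
    if (n %% 2 == 0) re[nh + 1] <- stats::rnorm(1) / (1 + (rate / 2 / fc)^3)
    re[n:(n - npos + 1)] <- re[2:(npos + 1)]
    im[n:(n - npos + 1)] <- -im[2:(npos + 1)]
    x <- Re(stats::fft(complex(real = re, imaginary = im),
                       inverse = TRUE)) / sqrt(n)
    n_rise <- round(0.15 * n); n_hold <- round(0.45 * n)
    env <- c(seq(0, 1, length.out = n_rise),
             rep(1, n_hold),
             exp(-4 * seq(0, 1, length.out = n - n_rise - n_hold)))
    if (max(abs(x)) == 0) return(audio_clip(x, rate, "takeoff"))
    audio_clip(amplitude * env * x / max(abs(x)), rate, "takeoff")
  })
}

# Pulsed construction beeps: regular 0.15 s tone bursts at beep_freq.
synth_beeps <- function(duration, rate_per_min = 12, beep_freq = 1000,
                        rate = 48000, amplitude = 0.05) {
  n <- round(duration * rate)
  x <- numeric(n)
  if (rate_per_min <= 0) return(audio_clip(x + 0, rate, "beeps"))
  period <- 60 / rate_per_min
  starts <- seq(period / 2, duration, by = period)
  ns <- round(0.15 * rate)
  t <- seq_len(ns) / rate
  env <- 0.5 - 0.5 * cos(2 * pi * seq_len(ns) / (ns + 1))
  burst <- amplitude * env * sin(2 * pi * beep_freq * t)
  for (s in starts) {
    s0 <- round(s * rate) + 1
    idx <- s0:min(s0 + ns - 1, n)
    x[idx] <- x[idx] + burst[seq_along(idx)]
  }
  audio_clip(x, rate, "beeps")
}

#' Site scene configuration
#'
#' @param site_id Site label.
#' @param distance_to_road Distance from the road edge in meters (> 0).
#' @param traffic_level_at_10m Traffic RMS level at 10 m, in dBFS.
#' @param chirp_rate Bird chirp rate (events/minute).
#' @param chirp_band Chirp frequency band in Hz.
#' @param takeoff_times Numeric vector of take-off onset times (s).
#' @param takeoff_duration Take-off event length (s).
#' @param beep_rate Construction beep rate (events/minute).
#' @param duration Scene length in seconds (>= 1).
#' @param seed Integer seed.
#' @return A list of class `site_scene_config`.
#' @export
site_scene_config <- function(site_id, distance_to_road,
                              traffic_level_at_10m = -20,
                              chirp_rate = 30, chirp_band = c(1500, 8000),
                              takeoff_times = numeric(0),
                              takeoff_duration = 45,
                              beep_rate = 0, duration = 60, seed = 1) {
  if (distance_to_road <= 0)
    ssm_stop("distance_to_road must be > 0", "parameter_error")
  if (duration < 1) ssm_stop("duration must be >= 1 s", "parameter_error")
  if (chirp_rate < 0 || beep_rate < 0)
    ssm_stop("rates must be >= 0", "parameter_error")
  structure(as.list(environment()), class = "site_scene_config")
}

#' Render one site's scene
#'
#' Mixes traffic noise at `traffic_level_at_10m - 20*log10(distance/10)`
#' dBFS (spherical spreading) with the chirp stream, optional take-off
#' events and optional pulsed beeps, then peak-normalises to at most
#' −1 dBFS.
#'
#' @param cfg A [site_scene_config()].
#' @param rate Sampling rate in Hz.
#' @return A list with `clip` (an [audio_clip()]) and `meta` (every
#'   component's parameters, including the realised traffic level and any
#'   normalisation gain).
#' @export
render_site <- function(cfg, rate = 48000) {
  stopifnot(inherits(cfg, "site_scene_config"))
  traffic_db <- cfg$traffic_level_at_10m -
    20 * log10(cfg$distance_to_road / 10)
  traffic <- synth_traffic(cfg$duration, traffic_db, rate,
                           seed = cfg$seed)
  chirps <- synth_chirps(cfg$duration, cfg$chirp_rate, cfg$chirp_band,
                         rate, seed = cfg$seed + 1L)
  x <- traffic$samples + chirps$samples
  if (cfg$beep_rate > 0)
    x <- x + synth_beeps(cfg$duration, cfg$beep_rate, rate = rate)$samples
  for (i in seq_along(cfg$takeoff_times)) {
    ev <- synth_takeoff(cfg$takeoff_duration, rate, seed = cfg$seed + 10L + i)
    s0 <- round(cfg$takeoff_times[i] * rate) + 1
    idx <- s0:min(s0 + length(ev$samples) - 1, length(x))
    x[idx] <- x[idx] + ev$samples[seq_along(idx)]
  }
  gain <- 1
  peak_lim <- dbfs_to_amp(-1)
  if (max(abs(x)) > peak_lim) {
    gain <- peak_lim / max(abs(x))
    x <- x * gain
  }
  if (max(abs(x)) > 1)
    ssm_stop("clipping after normalisation", "internal_error")
  list(clip = audio_clip(x, rate, cfg$site_id),
       meta = list(site_id = cfg$site_id,
                   distance_to_road = cfg$distance_to_road,
                   traffic_level_dbfs = traffic_db,
                   chirp_rate = cfg$chirp_rate,
                   n_chirps = nrow(attr(chirps, "events")),
                   beep_rate = cfg$beep_rate,
                   takeoff_times = cfg$takeoff_times,
                   normalisation_gain = gain,
                   seed = cfg$seed))
}

#' Study configuration: recorder grid with a road-distance gradient
#'
#' Defaults emulate a 4 x 4 regular grid over a ~75 x 135 m wooded parcel
#' with the road along `x = 0`: columns at 7.5/32.5/57.5/82.5 m from the
#' road edge, rows 45 m apart. Traffic level decays with distance by
#' spherical spreading; the songbird chirp rate rises with distance
#' following a logistic road-avoidance curve centred at 45 m (the
#' road-effect zone), giving the opposing biophony gradient. The planted
#' ground truth is the near/far median split on road distance.
#'
#' @param n_cols,n_rows Grid size (default 4 x 4 = 16 sites).
#' @param col_x,row_y Column / row coordinates in meters.
#' @param duration Seconds of audio per site (default 60; desk scale).
#' @param traffic_level_at_10m Traffic level at 10 m in dBFS (default −20).
#' @param chirp_rate_max Asymptotic chirp rate far from the road
#'   (events/minute, default 60).
#' @param road_effect_center,road_effect_width Logistic midpoint and width
#'   (m) of the chirp-rate curve (defaults 45 and 8).
#' @param biophony_gradient If FALSE, every site gets the same chirp rate
#'   (`chirp_rate_constant`), planting a traffic-level gradient only.
#' @param chirp_rate_constant Chirp rate used when `biophony_gradient` is
#'   FALSE (default 30).
#' @param seed Master seed; per-site seeds are derived from it.
#' @return A list of class `study_config` with a `sites` data.frame
#'   (site_id, x, y, distance, chirp_rate, true_group).
#' @export
study_config <- function(n_cols = 4, n_rows = 4,
                         col_x = c(7.5, 32.5, 57.5, 82.5),
                         row_y = c(0, 45, 90, 135),
                         duration = 60,
                         traffic_level_at_10m = -20,
                         chirp_rate_max = 60,
                         road_effect_center = 45, road_effect_width = 8,
                         biophony_gradient = TRUE,
                         chirp_rate_constant = 30,
                         seed = 1) {
  stopifnot(length(col_x) == n_cols, length(row_y) == n_rows,
            all(col_x > 0))
  grid <- expand.grid(x = col_x, y = row_y)
  n <- nrow(grid)
  if (n < 2) ssm_stop("need at least 2 sites", "parameter_error")
  sites <- data.frame(site_id = sprintf("S%02d", seq_len(n)),
                      x = grid$x, y = grid$y,
                      distance = grid$x, stringsAsFactors = FALSE)
  if (anyDuplicated(sites$site_id))
    ssm_stop("duplicate site ids", "schema_error")
  sites$chirp_rate <- if (biophony_gradient) {
    chirp_rate_max /
      (1 + exp(-(sites$distance - road_effect_center) / road_effect_width))
  } else rep(chirp_rate_constant, n)
  sites$true_group <- ifelse(sites$distance <= stats::median(sites$distance),
                             "near", "far")
  structure(list(sites = sites, duration = duration,
                 traffic_level_at_10m = traffic_level_at_10m,
                 biophony_gradient = biophony_gradient,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Generate a full synthetic study
#'
#' Renders every site of a [study_config()] and returns the clips together
#' with geometry and the planted ground truth. Optionally writes 16-bit
#' WAVs and a truth CSV.
#'
#' @param cfg A [study_config()].
#' @param dir Optional output directory for WAVs + `truth.csv`.
#' @return A list with `clips` (named list of [audio_clip()]), `geo`
#'   (data.frame site_id, x, y), `truth` (site table with distance,
#'   chirp_rate, true_group) and `config`.
#' @export
generate_study <- function(cfg = study_config(), dir = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  sites <- cfg$sites
  clips <- vector("list", nrow(sites))
  names(clips) <- sites$site_id
  for (i in seq_len(nrow(sites))) {
    sc <- site_scene_config(
      site_id = sites$site_id[i],
      distance_to_road = sites$distance[i],
      traffic_level_at_10m = cfg$traffic_level_at_10m,
      chirp_rate = sites$chirp_rate[i],
      duration = cfg$duration,
      seed = cfg$seed + 101L * i)
    clips[[i]] <- render_site(sc)$clip
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(clips))
      write_wav(clips[[id]], file.path(dir, paste0(id, ".wav")))
    utils::write.csv(sites, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  list(clips = clips,
       geo = sites[, c("site_id", "x", "y")],
       truth = sites,
       config = cfg)
}
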