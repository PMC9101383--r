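# Closed forms, hand-computed micro-spectrogram oracles, simulation checks
# and range/monotonicity properties of the seven eco-acoustic indices.

test_that("ACI closed forms and brute-force oracle agree", {
  expect_equal(as.numeric(aci(micro_spec(matrix(2, 5, 4)))), 0)
  expect_equal(as.numeric(aci(micro_spec(matrix(c(1, 3, 1), 1)))), 0.8)
  expect_error(aci(micro_spec(matrix(1, 3, 1))),
               class = "insufficient_frames_error")
  set.seed(11)
  for (i in 1:50) {
    nr <- sample(2:4, 1); nc <- sample(2:5, 1)
    A <- matrix(sample(0:5, nr * nc, replace = TRUE), nr, nc)
    expect_equal(as.numeric(aci(micro_spec(A))), aci_bruteforce(A))
  }
})

test_that("ACI of 1-s white noise is positive and stable across seeds", {
  vals <- vapply(1:20, function(s) as.numeric(aci(wn_block(s))), 0)
  expect_true(all(vals > 0))
  expect_lt(sd(vals) / mean(vals), 0.05)
})

test_that("band occupancy saturates, confines, and counts half-filled bands", {
  cfg <- index_config(adi_band_width = 1000, adi_max_freq = 4000)
  # 86 bins at 46.875 Hz cover 0-4 kHz; uniform strong signal -> all 1
  p <- band_occupancy(micro_spec(matrix(1, 86, 4)), cfg)
  expect_true(all(p == 1))
  # signal only in band 3 ([2,3) kHz)
  A <- matrix(0, 86, 4)
  A[45, ] <- 1  # bin 44 -> 2062.5 Hz
  p <- band_occupancy(micro_spec(A), cfg)
  expect_gt(p[["band3"]], 0)
  expect_true(all(p[setdiff(names(p), "band3")] == 0))
  # half of band 1's cells above threshold by construction
  A <- matrix(0, 86, 4)
  rows1 <- which((0:85) * 46.875 < 1000)        # 22 rows in band 1
  half <- matrix(0, length(rows1), 4)
  half[seq_len(length(rows1) * 4) %% 2 == 0] <- 1
  A[rows1, ] <- half
  p <- band_occupancy(micro_spec(A), cfg)
  expect_equal(p[["band1"]], 0.5)
})

test_that("ADI matches entropy closed forms", {
  expect_equal(as.numeric(adi(rep(0.3, 7))), log(7))
  expect_equal(as.numeric(adi(c(0.8, 0, 0, 0))), 0)
  expect_equal(as.numeric(adi(c(0.75, 0.25))), 0.5623, tolerance = 1e-4)
  z <- adi(rep(0, 5))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "degenerate"))
  expect_error(adi(c(0.5, -0.1)), class = "domain_error")
})

test_that("AEI matches Gini closed forms and the pairwise brute force", {
  expect_equal(as.numeric(aei(rep(0.4, 6))), 0)
  expect_equal(as.numeric(aei(c(1, rep(0, 9)))), 0.9)
  expect_equal(as.numeric(aei(c(0.5, 0.5, 0, 0))), 0.5)
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    expect_equal(as.numeric(aei(p)), gini_bruteforce(p))
  }
})

test_that("H is ~1 for white noise, ~0 for a pure tone, in [0,1] always", {
  hs <- vapply(1:20, function(s) as.numeric(entropy_h(wn_block(s))), 0)
  expect_true(all(hs > 0.95 & hs <= 1))
  tone <- tone_clip(100 * 46.875, duration = 1)
  blk <- tile_windows(
    mask_band(compute_spectrogram(
      tone, spectrogram_params(48000, window_fn = "rectangular"))), 1)[[1]]
  expect_lt(as.numeric(entropy_h(blk)), 0.1)
})

test_that("flat spectrum with a uniform 2-frame envelope gives Ht = 1", {
  A <- matrix(c(2, 2, 2, 2, 2, 2, 2, 2), 4, 2)  # identical columns
  h <- entropy_h(micro_spec(A))
  # Ht = 1 and Hf = 1 here (flat spectrum), so H = 1
  expect_equal(as.numeric(h), 1)
  # non-flat spectrum, equal columns: H = Hf alone
  A2 <- matrix(rep(c(4, 2, 1, 1), 2), 4, 2)
  s <- rowMeans(A2) / sum(rowMeans(A2))
  hf <- -sum(s * log2(s)) / log2(4)
  expect_equal(as.numeric(entropy_h(micro_spec(A2))), hf)
})

test_that("BI equals the min-referenced band area", {
  cfg <- index_config(bi_band = c(40, 100))
  # bins at 0 / 46.875 / 93.75 Hz; band holds bins 2-3 at -10 and -14 dB
  A <- matrix(rep(c(1, 10^(-10 / 20), 10^(-14 / 20)), 3), 3)
  expect_equal(as.numeric(bi(micro_spec(A), cfg)), 4 * 46.875 / 1000)
  # flat within the band -> 0
  A[3, ] <- A[2, ]
  expect_equal(as.numeric(bi(micro_spec(A), cfg)), 0)
  # all signal outside the band -> 0
  A2 <- matrix(0, 3, 3); A2[1, ] <- 1
  expect_equal(as.numeric(bi(micro_spec(A2), cfg)), 0)
})

test_that("NDSI hits its extremes and the 3:1 power ratio", {
  cfg <- index_config(ndsi_anthro = c(0, 50), ndsi_bio = c(50, 150))
  bio_only <- matrix(0, 4, 3); bio_only[3, ] <- 1     # 93.75 Hz
  anthro_only <- matrix(0, 4, 3); anthro_only[2, ] <- 1  # 46.875 Hz
  expect_equal(as.numeric(ndsi(micro_spec(bio_only), cfg)), 1)
  expect_equal(as.numeric(ndsi(micro_spec(anthro_only), cfg)), -1)
  mixed <- matrix(0, 4, 1); mixed[2, ] <- 1; mixed[3, ] <- sqrt(3)
  expect_equal(as.numeric(ndsi(micro_spec(mixed), cfg)), 0.5)
  expect_error(index_config(ndsi_anthro = c(0, 2000), ndsi_bio = c(1000, 8000)),
               class = "configuration_error")
})

test_that("DSC recovers tone positions and symmetric means", {
  tone2k <- tone_clip(2000, duration = 1)
  blk <- tile_windows(mask_band(compute_spectrogram(tone2k)), 1)[[1]]
  expect_equal(as.numeric(dsc(blk)), 2.0, tolerance = 46.875 / 1000)
  two <- audio_clip(0.3 * sin(2 * pi * 1000 * seq_len(48000) / 48000) +
                    0.3 * sin(2 * pi * 3000 * seq_len(48000) / 48000), 48000)
  blk2 <- tile_windows(mask_band(compute_spectrogram(two)), 1)[[1]]
  expect_equal(as.numeric(dsc(blk2)), 2.0, tolerance = 0.05)
  sil <- dsc(micro_spec(matrix(0, 4, 3)))
  expect_equal(as.numeric(sil), 0)
  expect_true(attr(sil, "degenerate"))
  # both aggregation modes agree on a stationary block
  cfg2 <- index_config(dsc_aggregation = "centroid_of_mean_spectrum")
  expect_equal(as.numeric(dsc(blk, cfg2)), as.numeric(dsc(blk)),
               tolerance = 1e-6)
})

test_that("index ranges hold on 1000 random micro blocks", {
  set.seed(99)
  cfg <- index_config(adi_band_width = 100, adi_max_freq = 500,
                      bi_band = c(50, 300), ndsi_anthro = c(0, 100),
                      ndsi_bio = c(100, 400))
  for (i in 1:1000) {
    A <- matrix(runif(48, 0, 10) * rbinom(48, 1, 0.8), 12, 4)
    blk <- micro_spec(A)
    p <- band_occupancy(blk, cfg)
    vals <- c(ACI = as.numeric(aci(blk)), ADI = as.numeric(adi(p)),
              AEI = as.numeric(aei(p)), H = as.numeric(entropy_h(blk)),
              BI = as.numeric(bi(blk, cfg)), NDSI = as.numeric(ndsi(blk, cfg)),
              DSC = as.numeric(dsc(blk)))
    expect_true(all(is.finite(vals)))
    expect_true(vals["AEI"] >= 0 && vals["AEI"] <= 1)
    expect_true(vals["H"] >= 0 && vals["H"] <= 1)
    expect_true(vals["NDSI"] >= -1 && vals["NDSI"] <= 1)
    expect_true(all(vals[c("ACI", "ADI", "BI", "DSC")] >= 0))
  }
})

test_that("adding a chirp stream never decreases mean ADI or NDSI", {
  cfg <- index_config()
  for (s in 1:10) {
    base <- synth_traffic(10, -25, seed = s)
    chirps <- synth_chirps(10, rate_per_min = 60, seed = 100 + s)
    with_birds <- audio_clip(base$samples + chirps$samples, 48000, "mix")
    m <- function(clip, ix) {
      ser <- compute_indices(clip, cfg = cfg)
      mean(ser$value[ser$index == ix])
    }
    expect_gte(m(with_birds, "ADI"), m(base, "ADI") - 1e-9)
    expect_gte(m(with_birds, "NDSI"), m(base, "NDSI") - 1e-9)
  }
})

test_that("ADI and AEI are strongly anti-correlated across a scene sweep", {
  cfg <- index_config(index_set = c("ADI", "AEI"))
  set.seed(21)
  grid <- expand.grid(rate = c(0, 5, 15, 30, 50),
                      dist = c(8, 20, 40, 60, 90))
  grid <- grid[rep(1:25, 2), ]
  stats_adi <- stats_aei <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sc <- site_scene_config("s", grid$dist[i], chirp_rate = grid$rate[i],
                            duration = 5, seed = 500 + i)
    ser <- compute_indices(render_site(sc)$clip, cfg = cfg)
    stats_adi[i] <- mean(ser$value[ser$index == "ADI"])
    stats_aei[i] <- mean(ser$value[ser$index == "AEI"])
  }
  expect_lt(cor(stats_adi, stats_aei, method = "spearman"), -0.8)
})

test_that("compute_indices returns one row per window and index, deterministically", {
  clip <- render_site(site_scene_config("S", 30, duration = 10, seed = 2))$clip
  full <- compute_indices(clip)
  expect_equal(nrow(full), 10 * 7)
  expect_setequal(unique(full$index), c("ACI", "ADI", "AEI", "H", "BI", "NDSI", "DSC"))
  five <- compute_indices(clip, cfg = index_config(c("ACI", "ADI", "AEI", "H", "DSC")))
  expect_setequal(unique(five$index), c("ACI", "ADI", "AEI", "H", "DSC"))
  expect_identical(compute_indices(clip), full)
  # a silent clip yields flagged zero windows, not errors
  silent <- audio_clip(rep(0, 2 * 48000), 48000, "mute")
  ser <- compute_indices(silent)
  expect_true(all(ser$degenerate[ser$index %in% c("ADI", "AEI", "H", "DSC")]))
})
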