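# Generator statistics: spectra, levels, Poisson arrivals, event effects,
# mixing laws, and reproducibility.

test_that("traffic noise is low-frequency dominated at an exact level", {
  tr <- synth_traffic(5, -20, seed = 1)
  expect_equal(20 * log10(rms(tr$samples)), -20, tolerance = 1e-6)
  spec <- compute_spectrogram(tr)
  pw <- rowMeans(spec$A^2)
  expect_gte(sum(pw[spec$freqs < 1000]) / sum(pw), 0.9)
  # 6 dB level difference doubles the RMS
  r1 <- rms(synth_traffic(2, -20, seed = 2)$samples)
  r2 <- rms(synth_traffic(2, -26, seed = 2)$samples)
  expect_equal(r1 / r2, 2, tolerance = 0.05)
  expect_identical(synth_traffic(2, -20, seed = 9)$samples,
                   synth_traffic(2, -20, seed = 9)$samples)
})

test_that("chirp arrivals are Poisson with the configured rate", {
  expect_true(all(synth_chirps(2, rate_per_min = 0, seed = 1)$samples == 0))
  counts <- vapply(1:200, function(s)
    nrow(draw_chirp_events(600, 30, c(1500, 8000), seed = s)), 0L)
  expect_lt(abs(mean(counts) - 300), 2 * sqrt(300 / 200))
  expect_error(synth_chirps(2, band = c(1000, 30000)),
               class = "parameter_error")
})

test_that("chirp energy stays inside the configured band", {
  ch <- synth_chirps(10, rate_per_min = 60, band = c(2000, 6000), seed = 4)
  spec <- compute_spectrogram(ch)
  pw <- rowMeans(spec$A^2)
  fr <- spec$params$fr
  inside <- spec$freqs >= 2000 - fr & spec$freqs <= 6000 + fr
  expect_gt(sum(pw[inside]) / sum(pw), 0.99)
})

test_that("a take-off displaces ADI and DSC in its minute, not ACI", {
  # the transient must move the occupancy balance and the centroid of its
  # own minute well beyond the drift between the adjacent quiet minutes
  cfg <- index_config(c("ACI", "ADI", "DSC"))
  adi_hits <- dsc_hits <- aci_hits <- 0
  for (s in 1:10) {
    event_minute <- function(takeoffs) {
      sc <- site_scene_config("S", 40, chirp_rate = 30, duration = 180,
                              takeoff_times = takeoffs,
                              takeoff_duration = 40, seed = 400 + s)
      ser <- compute_indices(render_site(sc)$clip, cfg = cfg)
      minute <- findInterval(ser$t_start_s, c(0, 60, 120))
      vapply(c("ACI", "ADI", "DSC"), function(ix)
        mean(ser$value[ser$index == ix & minute == 2]), 0)
    }
    quiet <- event_minute(numeric(0))
    loud <- event_minute(70)
    rel <- abs(loud - quiet) / quiet
    if (rel[["ADI"]] > 0.1 && rel[["ADI"]] > 3 * rel[["ACI"]])
      adi_hits <- adi_hits + 1
    if (rel[["DSC"]] > 0.025) dsc_hits <- dsc_hits + 1
    if (rel[["ACI"]] < 0.05) aci_hits <- aci_hits + 1
  }
  expect_gte(adi_hits, 8)
  expect_gte(dsc_hits, 8)
  expect_gte(aci_hits, 8)
  # a zero-amplitude event changes nothing
  base <- synth_takeoff(5, amplitude = 0, seed = 1)
  expect_true(all(base$samples == 0))
})

test_that("rendered scenes follow the distance law and NDSI signs", {
  near <- render_site(site_scene_config("a", 10, duration = 2, seed = 1))
  far <- render_site(site_scene_config("b", 20, duration = 2, seed = 1))
  expect_equal(near$meta$traffic_level_dbfs - far$meta$traffic_level_dbfs,
               20 * log10(2), tolerance = 1e-9)
  expect_lte(max(abs(near$clip$samples)), dbfs_to_amp(-1) + 1e-12)
  cfg <- index_config("NDSI")
  pure_traffic <- render_site(site_scene_config("t", 10, chirp_rate = 0,
                                                duration = 5, seed = 2))
  ser <- compute_indices(pure_traffic$clip, cfg = cfg)
  expect_lt(mean(ser$value), 0)
  birdy <- render_site(site_scene_config("f", 90, chirp_rate = 60,
                                         duration = 5, seed = 3))
  ser2 <- compute_indices(birdy$clip, cfg = cfg)
  expect_gt(mean(ser2$value), 0)
})

test_that("the default study is reproducible with planted separation", {
  cfg <- study_config(duration = 10, seed = 5)
  a <- generate_study(cfg)
  b <- generate_study(cfg)
  expect_identical(a$clips$S01$samples, b$clips$S01$samples)
  expect_equal(nrow(a$truth), 16)
  expect_setequal(a$truth$true_group, c("near", "far"))
  expect_equal(sum(a$truth$true_group == "near"), 8)
  # chirp rate rises with distance (road-effect avoidance)
  expect_true(all(diff(a$truth$chirp_rate[order(a$truth$distance)]) >= 0))
  dir <- tempfile()
  generate_study(study_config(duration = 1, seed = 1), dir = dir)
  expect_length(list.files(dir, pattern = "\\.wav$"), 16)
  expect_true(file.exists(file.path(dir, "truth.csv")))
})

test_that("generated audio is always finite and in range", {
  for (s in 1:5) {
    clip <- render_site(site_scene_config("x", 15, chirp_rate = 60,
                                          beep_rate = 12, duration = 3,
                                          takeoff_times = 1, seed = s))$clip
    expect_true(all(is.finite(clip$samples)))
    expect_true(all(abs(clip$samples) <= 1))
  }
})
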