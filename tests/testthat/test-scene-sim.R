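test_that("schedule enumerates duty-cycle slots and honors gaps", {
  sc <- tiny_scene(days = 1)
  sc$end_time <- sc$start_time + 3600
  expect_equal(nrow(build_schedule(sc)), 3)  # 2 min every 20 min

  sc$end_time <- sc$start_time
  expect_equal(nrow(build_schedule(sc)), 0)

  sc2 <- tiny_scene(days = 1, n_stations = 2)
  sc2$service_gaps <- list(c(sc2$start_time + 6 * 3600,
                             sc2$start_time + 10 * 3600))
  got <- build_schedule(sc2)
  # brute-force oracle: enumerate every 20-min slot, filter the gap
  slots <- seq(sc2$start_time, sc2$end_time - 1, by = 1200)
  keep <- !(slots >= sc2$service_gaps[[1]][1] &
              slots < sc2$service_gaps[[1]][2])
  expect_equal(nrow(got), 2 * sum(keep))
  expect_equal(2 * (72 - 12), nrow(got))
  expect_setequal(unique(got$timestamp), slots[keep])
})

test_that("schedule matches brute-force enumeration for arbitrary gaps", {
  sc <- tiny_scene(days = 3)
  set.seed(17)
  for (rep in 1:5) {
    g1 <- sc$start_time + sort(runif(2, 0, 3 * 86400))
    g2 <- sc$start_time + sort(runif(2, 0, 3 * 86400))
    sc$service_gaps <- list(g1, g2)
    got <- build_schedule(sc)
    slots <- seq(sc$start_time, sc$end_time - 1, by = 1200)
    keep <- !((slots >= g1[1] & slots < g1[2]) |
                (slots >= g2[1] & slots < g2[2]))
    expect_equal(got$timestamp, slots[keep])
  }
})

test_that("environment series has the configured tide and temperature", {
  sc <- tiny_scene(days = 30)
  env <- simulate_environment(sc)
  expect_equal(as.numeric(diff(env$timestamp[1:5]), units = "mins"),
               rep(20, 4))
  expect_equal(max(env$depth_m) - min(env$depth_m), 1.8, tolerance = 0.01)

  # successive high tides spaced one semidiurnal period apart
  d <- env$depth_m
  peaks <- which(diff(sign(diff(d))) == -2) + 1
  spacing <- diff(env$timestamp[peaks])
  expect_true(all(abs(as.numeric(spacing, units = "hours") - 12.42)
                  <= 20 / 60 + 1e-9))

  # coldest day hits the configured winter minimum (seasonal component)
  sc2 <- tiny_scene(days = 3)
  sc2$start_time <- as.POSIXct("2018-01-14 00:00:00", tz = "UTC")
  sc2$end_time <- sc2$start_time + 3 * 86400
  sc2$temp_daily_amp_c <- 0
  env2 <- simulate_environment(sc2)
  expect_equal(min(env2$water_temp_c), sc2$temp_min_c, tolerance = 0.01)
})

test_that("season gates silence out-of-season producers", {
  sc <- tiny_scene(days = 2, rng_seed = 5)
  sc$start_time <- as.POSIXct("2018-07-10 00:00:00", tz = "UTC")
  sc$end_time <- sc$start_time + 2 * 86400
  truth <- simulate_events(sc)
  # black drum is a March-April caller: no July events
  expect_equal(sum(truth$counts[, "black_drum"]), 0)
  expect_equal(sum(truth$counts[, "silver_perch"]), 0)  # Mar-Jun
  # spotted seatrout is in season through September
  expect_gt(sum(truth$counts[, "spotted_seatrout"]), 0)
})

test_that("Poisson thinning recovers the planted noise response", {
  # flat producer, vessel presence a fair coin at all hours: the ratio of
  # mean counts noisy/quiet converges to noise_response
  sc <- tiny_scene(days = 56, rng_seed = 23)
  sc$producers <- list(sup = flat_producer("sup", noise_response = 0.2,
                                           base_rate = 3))
  sc$vessel <- vessel_spec(day_rate = 0.5, night_rate = 0.5,
                           weekend_multiplier = 1, band_hi_hz = 3900)
  truth <- simulate_events(sc)
  noisy <- truth$vessel_present == 1
  expect_gt(sum(noisy), 1500)
  expect_gt(sum(!noisy), 1500)
  ratio <- mean(truth$counts[noisy, "sup"]) /
    mean(truth$counts[!noisy, "sup"])
  expect_equal(ratio, 0.2, tolerance = 0.1)  # within 10% (relative)
})

test_that("identical seed and config reproduce the scene bit-for-bit", {
  sc <- tiny_scene(days = 2, rng_seed = 99)
  t1 <- simulate_events(sc)
  t2 <- simulate_events(sc)
  expect_identical(t1$counts, t2$counts)
  expect_identical(t1$events, t2$events)
  expect_identical(t1$vessel_present, t2$vessel_present)
  w1 <- render_waveform(t1, t1$schedule$file_id[30])
  w2 <- render_waveform(t2, t2$schedule$file_id[30])
  expect_identical(w1$samples, w2$samples)
})

test_that("rendered files reproduce the closed-form band SPLs", {
  cal <- calibration_spec()
  sc <- tiny_scene(days = 1, rng_seed = 3)
  truth <- simulate_events(sc)
  spl <- truth_spl_table(truth)
  for (id in truth$schedule$file_id[c(10, 60)]) {
    w <- render_waveform(truth, id, cal)
    for (bd in list(band("low"), test_high_band())) {
      got <- band_spl(w$samples, w$sample_rate, bd, cal)$spl_db
      want <- spl$spl_db[spl$file_id == id & spl$band == bd$label]
      expect_equal(got, want, tolerance = 1.5)
    }
  }
})

test_that("a zero-event file sits at the ambient floor in both bands", {
  sc <- silent_scene()
  truth <- simulate_events(sc)
  w <- render_waveform(truth, truth$schedule$file_id[1])
  for (bd in list(band("low"), test_high_band())) {
    spl <- band_spl(w$samples, w$sample_rate, bd)$spl_db
    expect_equal(spl, sc$ambient_floor_db, tolerance = 1)
  }
})

test_that("a lone fish chorus dominates the low band by 20 dB or more", {
  sc <- silent_scene()
  sc$ambient_floor_db <- 60
  truth <- simulate_events(sc)
  truth$events <- data.frame(file = rep(1L, 6),
                             producer = "spotted_seatrout",
                             level_db = rep(128, 6))
  truth$counts[1, "spotted_seatrout"] <- 6L
  w <- render_waveform(truth, truth$schedule$file_id[1])
  lo <- band_spl(w$samples, w$sample_rate, band("low"))$spl_db
  hi <- band_spl(w$samples, w$sample_rate, test_high_band())$spl_db
  expect_gte(lo - hi, 20)
})

test_that("a single snap matches the closed-form transient level", {
  sc <- silent_scene()
  sc$ambient_floor_db <- 40
  truth <- simulate_events(sc)
  truth$events <- data.frame(file = 1L, producer = "snapping_shrimp",
                             level_db = 130)
  truth$counts[1, "snapping_shrimp"] <- 1L
  w <- render_waveform(truth, truth$schedule$file_id[1])
  p <- sc$producers$snapping_shrimp
  # rms level L over duration d, averaged over the 120 s file
  want <- 130 + 10 * log10(p$duration_s / 120)
  got <- band_spl(w$samples, w$sample_rate,
                  band("custom", f_lo_hz = p$band_lo_hz,
                       f_hi_hz = p$band_hi_hz))$spl_db
  expect_equal(got, want, tolerance = 1.5)
})

test_that("rendering is band-faithful for single-producer files", {
  for (pname in c("spotted_seatrout", "snapping_shrimp",
                  "dolphin_whistles")) {
    sc <- silent_scene(rng_seed = 31)
    sc$ambient_floor_db <- 30  # negligible floor
    truth <- simulate_events(sc)
    truth$events <- data.frame(file = rep(1L, 4), producer = pname,
                               level_db = rep(120, 4))
    p <- sc$producers[[pname]]
    w <- render_waveform(truth, truth$schedule$file_id[1])
    ps <- harborscape:::welch_psd(w$samples, w$sample_rate)
    inband <- ps$freq >= p$band_lo_hz & ps$freq <= p$band_hi_hz
    frac <- sum(ps$psd[inband]) / sum(ps$psd[-1])
    expect_gte(frac, 0.9)
  }
})

test_that("producer bands above Nyquist are refused", {
  sc <- tiny_scene()
  expect_error(
    scene_config(sc$start_time, sc$end_time, sc$stations,
                 producers = list(producer_spec("x", "fish", 100, 5000)),
                 sample_rate_hz = 8000),
    "Nyquist|twice")
  truth <- simulate_events(sc)
  truth$config$producers$silver_perch$band_hi_hz <- 6000
  expect_error(render_waveform(truth, truth$schedule$file_id[1]),
               "Nyquist")
})

test_that("truth annotations apply the count-to-score map and sums", {
  sc <- tiny_scene(days = 1, rng_seed = 13)
  truth <- simulate_events(sc)
  n <- nrow(truth$schedule)
  # plant controlled counts
  truth$counts[, ] <- 0L
  truth$counts[1, "spotted_seatrout"] <- 1L
  truth$counts[2, "spotted_seatrout"] <- 3L
  truth$counts[3, "spotted_seatrout"] <- 5L
  truth$counts[4, "dolphin_whistles"] <- 7L
  truth$counts[4, "dolphin_echolocation"] <- 3L
  ann <- export_truth_annotations(truth)
  expect_equal(ann$spotted_seatrout[1:3], c(1L, 2L, 3L))
  expect_equal(ann$dolphin_whistles[4], 7L)
  expect_equal(ann$dolphin_echolocation[4], 3L)
  expect_equal(ann$dolphin_sum[4], 10L)
  # zero-event file rows are all zero
  zero_cols <- setdiff(names(ann), c("file_id", "station", "timestamp",
                                     "noise"))
  expect_true(all(ann[5, zero_cols] == 0))
  expect_equal(ann$noise, as.integer(truth$vessel_present))
})

test_that("scene WAV export writes the station_date_time naming scheme", {
  sc <- silent_scene()
  truth <- simulate_events(sc)
  dir <- withr::local_tempdir()
  out <- render_scene(truth, dir, truth$schedule$file_id[1:2])
  expect_true(all(file.exists(out$path)))
  expect_match(basename(out$path[1]),
               "^wando_\\d{8}_\\d{6}\\.wav$")
  got <- read_wav(out$path[1])
  expect_equal(got$sample_rate, sc$sample_rate_hz)
})
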