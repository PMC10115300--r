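# Scene builders shared across tests. All fixtures are generated in code;
# scenes use the scaled 8 kHz profile so renders and statistics stay fast.

# default spring scene, shortened
tiny_scene <- function(days = 2, n_stations = 1, rng_seed = 1L, ...) {
  default_scene(days = days, n_stations = n_stations, rng_seed = rng_seed,
                ...)
}

# scene with every source silenced (ambient + optional vessel only)
silent_scene <- function(days = 1, rng_seed = 1L, vessel_off = TRUE) {
  sc <- tiny_scene(days = days, rng_seed = rng_seed)
  sc$producers <- lapply(sc$producers, function(p) {
    p$base_rate <- 0
    p
  })
  if (vessel_off) {
    sc$vessel$day_rate <- 0
    sc$vessel$night_rate <- 0
  }
  sc
}

# a producer with no temporal structure at all, for planting clean
# noise-response effects without diel/seasonal confounding
flat_producer <- function(name = "unknown1", noise_response = 1,
                          base_rate = 2, band = c(200, 1200),
                          level_db = 120) {
  producer_spec(name, "fish", band[1], band[2], base_rate = base_rate,
                noise_response = noise_response, level_db = level_db,
                duration_s = 0.3)
}

# covariates for a scene truth, on the scene's own sun geometry
scene_covariates <- function(truth) {
  cfg <- truth$config
  st0 <- cfg$stations[[1]]
  sun <- make_sun_table(
    seq(as.Date(cfg$start_time, tz = "UTC") - 2,
        as.Date(cfg$end_time, tz = "UTC") + 2, by = "day"),
    st0$lat, st0$lon, cfg$utc_offset_h)
  assemble_covariates(truth$schedule, truth$env, sun, cfg$lunar_ref,
                      cfg$utc_offset_h)
}

# one full day of annotations with controlled per-file values
annotation_frame <- function(n, station = "s1",
                             start = as.POSIXct("2018-04-01 00:00:00",
                                                tz = "UTC")) {
  ts <- start + (seq_len(n) - 1) * 1200
  data.frame(file_id = paste0(station, "_", seq_len(n)), station = station,
             timestamp = ts, oyster_toadfish = 0L, spotted_seatrout = 0L,
             silver_perch = 0L, black_drum = 0L, red_drum = 0L,
             atlantic_croaker = 0L, weakfish = 0L,
             dolphin_echolocation = 0L, dolphin_whistles = 0L,
             dolphin_burst = 0L, dolphin_sum = 0L, noise = 0L, rain = 0L,
             right_whale = 0L, stringsAsFactors = FALSE)
}
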