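#' Station specification
#'
#' @param name station label, used in file ids and output tables.
#' @param lat,lon position in degrees (drives the sunrise/sunset table).
#' @param rate_multiplier scalar multiplier applied to every producer's
#'   event rate at this station (stations differ in habitat quality).
#' @return object of class `station_spec`.
#' @export
station_spec <- function(name, lat = 32.8, lon = -79.9,
                         rate_multiplier = 1) {
  stopifnot(nzchar(name), rate_multiplier >= 0)
  structure(list(name = name, lat = lat, lon = lon,
                 rate_multiplier = rate_multiplier),
            class = "station_spec")
}

#' Sound-producer specification
#'
#' Describes one sound source: its frequency band, activity windows
#' (season, local hours, temperature), base event rate per active file, and
#' multiplicative modifiers for lunar phase, tidal phase, diel period and
#' vessel-noise presence. `noise_response` is the factor applied to the
#' event rate when vessel noise is present in the same file: values below 1
#' plant acoustic suppression, above 1 a vocalization boost.
#'
#' @param name producer label (e.g. `spotted_seatrout`, `snapping_shrimp`).
#' @param kind one of `fish`, `snap`, `dolphin`, `rain`, `whale` — selects
#'   the waveform renderer and the annotation column type.
#' @param band_lo_hz,band_hi_hz declared frequency band of the sound.
#' @param season_months integer months (1-12) in which the producer is
#'   active.
#' @param active_hours integer local hours (0-23) of activity.
#' @param temp_range_c length-2 numeric; activity requires water
#'   temperature inside this range.
#' @param base_rate expected events per active 2-min file before modifiers.
#' @param lunar_effect,tidal_effect named multiplicative modifiers over the
#'   four lunar / tidal categories.
#' @param diel_effect named multiplicative modifiers, `c(day=, night=)`.
#' @param noise_response multiplicative rate modifier under vessel noise
#'   (> 0).
#' @param level_db per-event rms source level, dB re 1 uPa (received);
#'   individual events are drawn log-normal around it with `level_sd_db`.
#' @param level_sd_db event-to-event level spread, dB.
#' @param duration_s event duration, seconds.
#' @param dolphin_type for `kind = "dolphin"`: `echolocation`, `whistles`
#'   or `burst`.
#' @return object of class `producer_spec`.
#' @export
producer_spec <- function(name, kind = c("fish", "snap", "dolphin", "rain",
                                         "whale"),
                          band_lo_hz, band_hi_hz,
                          season_months = 1:12, active_hours = 0:23,
                          temp_range_c = c(-5, 40), base_rate = 1,
                          lunar_effect = c(new = 1, first_quarter = 1,
                                           full = 1, third_quarter = 1),
                          tidal_effect = c(high = 1, falling = 1, low = 1,
                                           rising = 1),
                          diel_effect = c(day = 1, night = 1),
                          noise_response = 1, level_db = 120,
                          level_sd_db = 3, duration_s = 0.3,
                          dolphin_type = NULL) {
  kind <- match.arg(kind)
  stopifnot(band_lo_hz < band_hi_hz, base_rate >= 0, noise_response > 0)
  structure(list(name = name, kind = kind, band_lo_hz = band_lo_hz,
                 band_hi_hz = band_hi_hz, season_months = season_months,
                 active_hours = active_hours, temp_range_c = temp_range_c,
                 base_rate = base_rate, lunar_effect = lunar_effect,
                 tidal_effect = tidal_effect, diel_effect = diel_effect,
                 noise_response = noise_response, level_db = level_db,
                 level_sd_db = level_sd_db, duration_s = duration_s,
                 dolphin_type = dolphin_type),
            class = "producer_spec")
}

#' Vessel-noise specification
#'
#' Vessel presence is drawn per file as Bernoulli with a day/night rate and
#' a weekend multiplier (recreational traffic is day- and weekend-biased).
#' The spectrum class sets the frequency extent of the rendered noise:
#' commercial traffic peaks at 20-200 Hz, recreational small craft span
#' roughly 100 Hz to 7 kHz (capped at Nyquist in scaled-down profiles).
#'
#' @param day_rate,night_rate per-file presence probability.
#' @param weekend_multiplier applied to the rate on Saturday/Sunday.
#' @param spectrum_class `"recreational"` or `"commercial"`.
#' @param level_db broadband received level of the vessel noise, dB re
#'   1 uPa.
#' @param band_lo_hz,band_hi_hz noise band; defaulted from the class.
#' @return object of class `vessel_spec`.
#' @export
vessel_spec <- function(day_rate = 0.45, night_rate = 0.12,
                        weekend_multiplier = 1.4,
                        spectrum_class = c("recreational", "commercial"),
                        level_db = 140, band_lo_hz = NULL,
                        band_hi_hz = NULL) {
  spectrum_class <- match.arg(spectrum_class)
  stopifnot(day_rate >= 0, day_rate <= 1, night_rate >= 0, night_rate <= 1)
  if (is.null(band_lo_hz))
    band_lo_hz <- if (spectrum_class == "commercial") 20 else 100
  if (is.null(band_hi_hz))
    band_hi_hz <- if (spectrum_class == "commercial") 200 else 7000
  structure(list(day_rate = day_rate, night_rate = night_rate,
                 weekend_multiplier = weekend_multiplier,
                 spectrum_class = spectrum_class, level_db = level_db,
                 band_lo_hz = band_lo_hz, band_hi_hz = band_hi_hz),
            class = "vessel_spec")
}

#' Scene configuration
#'
#' Full parameterization of a synthetic duty-cycled soundscape: recording
#' schedule, stations, sound producers, vessel noise, ambient floor,
#' environment (temperature/tide) model, and the seed. The duty cycle
#' defaults to 2 minutes recorded every 20 minutes.
#'
#' @param start_time,end_time POSIXct (UTC) span of the deployment.
#' @param stations list of [station_spec()].
#' @param producers list of [producer_spec()].
#' @param vessel a [vessel_spec()].
#' @param duty_on_s,duty_period_s duty cycle, seconds.
#' @param sample_rate_hz rendering sample rate; must be at least twice the
#'   highest producer band edge.
#' @param ambient_floor_db ambient Gaussian floor, expressed as the SPL it
#'   produces in the 50-1200 Hz analysis band.
#' @param rng_seed integer seed governing all stochastic draws.
#' @param service_gaps list of length-2 POSIXct vectors; slots starting
#'   inside a gap are dropped (recorder servicing).
#' @param utc_offset_h local civil time offset of the study area.
#' @param lunar_ref POSIXct of a reference new moon.
#' @param temp_min_c,temp_max_c annual water-temperature envelope.
#' @param coldest_doy day-of-year of the seasonal temperature minimum.
#' @param temp_daily_amp_c half-amplitude of the daily temperature cycle.
#' @param tidal_range_m peak-to-trough semidiurnal tide excursion.
#' @param depth_mean_m mean station depth.
#' @param score_breaks length-2 integer: minimum event counts mapping to
#'   intensity scores 2 and 3 (defaults: 2-4 events -> 2, >= 5 -> 3).
#' @return object of class `scene_config`.
#' @export
scene_config <- function(start_time, end_time, stations, producers,
                         vessel = vessel_spec(),
                         duty_on_s = 120, duty_period_s = 1200,
                         sample_rate_hz = 96000,
                         ambient_floor_db = 92, rng_seed = 1L,
                         service_gaps = list(),
                         utc_offset_h = -5,
                         lunar_ref = as.POSIXct("2018-03-17 13:12:00",
                                                tz = "UTC"),
                         temp_min_c = 9, temp_max_c = 30,
                         coldest_doy = 15, temp_daily_amp_c = 0.75,
                         tidal_range_m = 1.8, depth_mean_m = 3,
                         score_breaks = c(2L, 5L)) {
  stopifnot(duty_on_s <= duty_period_s, length(stations) >= 1)
  hi <- max(vapply(producers, function(p) p$band_hi_hz, numeric(1)))
  if (sample_rate_hz < 2 * hi)
    stop("sample_rate_hz (", sample_rate_hz,
         ") is below twice the highest producer band edge (", hi, " Hz)")
  structure(list(start_time = start_time, end_time = end_time,
                 stations = stations, producers = producers,
                 vessel = vessel, duty_on_s = duty_on_s,
                 duty_period_s = duty_period_s,
                 sample_rate_hz = sample_rate_hz,
                 ambient_floor_db = ambient_floor_db,
                 rng_seed = as.integer(rng_seed),
                 service_gaps = service_gaps,
                 utc_offset_h = utc_offset_h, lunar_ref = lunar_ref,
                 temp_min_c = temp_min_c, temp_max_c = temp_max_c,
                 coldest_doy = coldest_doy,
                 temp_daily_amp_c = temp_daily_amp_c,
                 tidal_range_m = tidal_range_m,
                 depth_mean_m = depth_mean_m,
                 score_breaks = as.integer(score_breaks)),
            class = "scene_config")
}

#' Default sound-producer registry (scaled test profile)
#'
#' Producers parameterized for the 8 kHz test profile: the low-frequency
#' fish bands are at their real values (all below 1.3 kHz), while broadband
#' sources (snapping shrimp, dolphins) are rescaled to sit inside the
#' 2.8-3.8 kHz scaled "high" analysis band. Fish calling is night-biased
#' except oyster toadfish and red drum; vessel noise suppresses oyster
#' toadfish, silver perch and red drum calling and boosts dolphin
#' vocalization rates.
#'
#' @param profile `"test"` (8 kHz rendering) or `"full"` (96 kHz bands:
#'   shrimp and dolphins placed in the real 7-40 kHz range).
#' @return named list of [producer_spec()] objects.
#' @export
default_producers <- function(profile = c("test", "full")) {
  profile <- match.arg(profile)
  shrimp_band <- if (profile == "test") c(1500, 3900) else c(2000, 39000)
  whistle_band <- if (profile == "test") c(1500, 3500) else c(4000, 20000)
  click_band <- if (profile == "test") c(2800, 3900) else c(20000, 40000)
  burst_band <- if (profile == "test") c(2000, 3600) else c(7000, 25000)
  list(
    snapping_shrimp = producer_spec("snapping_shrimp", "snap",
      shrimp_band[1], shrimp_band[2], base_rate = 30,
      lunar_effect = c(new = 0.9, first_quarter = 1.2, full = 1,
                       third_quarter = 0.8),
      tidal_effect = c(high = 1.15, falling = 0.9, low = 1.05,
                       rising = 0.9),
      diel_effect = c(day = 0.7, night = 1.3),
      level_db = 132, duration_s = 0.01),
    oyster_toadfish = producer_spec("oyster_toadfish", "fish", 190, 200,
      season_months = 3:6, temp_range_c = c(15, 30), base_rate = 1.2,
      lunar_effect = c(new = 0.8, first_quarter = 1, full = 1.3,
                       third_quarter = 0.9),
      tidal_effect = c(high = 1.2, falling = 0.95, low = 1, rising = 1),
      diel_effect = c(day = 1.3, night = 0.8),
      noise_response = 0.35, level_db = 126, duration_s = 0.5),
    silver_perch = producer_spec("silver_perch", "fish", 1000, 1280,
      season_months = 3:6, active_hours = c(15:23, 0:4),
      temp_range_c = c(15, 28), base_rate = 1.5,
      lunar_effect = c(new = 1.1, first_quarter = 1.3, full = 1,
                       third_quarter = 0.8),
      tidal_effect = c(high = 1.2, falling = 0.9, low = 1, rising = 0.95),
      diel_effect = c(day = 0.4, night = 1.8),
      noise_response = 0.35, level_db = 124, duration_s = 0.3),
    spotted_seatrout = producer_spec("spotted_seatrout", "fish", 200, 270,
      season_months = 3:9, active_hours = c(14:23, 0:1),
      temp_range_c = c(16, 30), base_rate = 2.5,
      lunar_effect = c(new = 0.8, first_quarter = 1, full = 1.4,
                       third_quarter = 0.9),
      tidal_effect = c(high = 1.2, falling = 0.9, low = 0.95,
                       rising = 1),
      diel_effect = c(day = 0.25, night = 2.2),
      noise_response = 1, level_db = 128, duration_s = 0.4),
    black_drum = producer_spec("black_drum", "fish", 70, 90,
      season_months = 3:4, active_hours = 15:23,
      temp_range_c = c(14, 24), base_rate = 0.3,
      lunar_effect = c(new = 0.9, first_quarter = 1.3, full = 1,
                       third_quarter = 0.9),
      diel_effect = c(day = 0.5, night = 1.6),
      noise_response = 1, level_db = 127, duration_s = 0.6),
    red_drum = producer_spec("red_drum", "fish", 120, 160,
      season_months = 8:10, active_hours = 13:19,
      temp_range_c = c(20, 31), base_rate = 2,
      lunar_effect = c(new = 0.9, first_quarter = 1.3, full = 1,
                       third_quarter = 0.9),
      tidal_effect = c(high = 1, falling = 0.95, low = 0.95,
                       rising = 1.2),
      diel_effect = c(day = 1.5, night = 0.6),
      noise_response = 0.35, level_db = 128, duration_s = 0.5),
    atlantic_croaker = producer_spec("atlantic_croaker", "fish", 300, 600,
      season_months = 3:8, base_rate = 0.12, diel_effect = c(day = 0.8,
                                                             night = 1.2),
      level_db = 122, duration_s = 0.3),
    weakfish = producer_spec("weakfish", "fish", 250, 550,
      season_months = 4:7, base_rate = 0.08,
      diel_effect = c(day = 0.7, night = 1.3), level_db = 122,
      duration_s = 0.3),
    dolphin_echolocation = producer_spec("dolphin_echolocation", "dolphin",
      click_band[1], click_band[2], base_rate = 1.2,
      diel_effect = c(day = 0.8, night = 1.3),
      tidal_effect = c(high = 0.95, falling = 1.2, low = 1,
                       rising = 0.85),
      noise_response = 3, level_db = 120, duration_s = 0.05,
      dolphin_type = "echolocation"),
    dolphin_whistles = producer_spec("dolphin_whistles", "dolphin",
      whistle_band[1], whistle_band[2], base_rate = 0.4,
      diel_effect = c(day = 0.8, night = 1.3),
      tidal_effect = c(high = 0.95, falling = 1.2, low = 1,
                       rising = 0.85),
      noise_response = 3, level_db = 122, duration_s = 0.8,
      dolphin_type = "whistles"),
    dolphin_burst = producer_spec("dolphin_burst", "dolphin",
      burst_band[1], burst_band[2], base_rate = 0.2,
      diel_effect = c(day = 0.8, night = 1.3),
      tidal_effect = c(high = 0.95, falling = 1.2, low = 1,
                       rising = 0.85),
      noise_response = 3, level_db = 121, duration_s = 0.3,
      dolphin_type = "burst"))
}

#' Default synthetic scene
#'
#' A 60-day spring deployment (April-May 2018) at two stations, rendered
#' at 8 kHz with the high analysis band rescaled to 2.8-3.8 kHz for fast
#' computation. The scene plants the structure typical of an urbanized
#' estuary: day- and weekend-biased vessel noise, night-biased fish
#' chorusing and snapping, noise-suppressed fish calling and noise-boosted
#' dolphin vocalization rates.
#'
#' @param days deployment length in days.
#' @param start_time POSIXct start (UTC).
#' @param n_stations number of stations (1 or 2).
#' @param rng_seed integer seed.
#' @param ... further arguments passed to [scene_config()].
#' @return a [scene_config()].
#' @export
default_scene <- function(days = 60,
                          start_time = as.POSIXct("2018-04-01 00:00:00",
                                                  tz = "UTC"),
                          n_stations = 2, rng_seed = 1L, ...) {
  stations <- list(
    station_spec("wando", lat = 32.84, lon = -79.90,
                 rate_multiplier = 1.15),
    station_spec("aquarium", lat = 32.79, lon = -79.92,
                 rate_multiplier = 0.9))[seq_len(n_stations)]
  scene_config(
    start_time = start_time,
    end_time = start_time + days * 86400,
    stations = stations,
    producers = default_producers("test"),
    vessel = vessel_spec(band_hi_hz = 3900),
    sample_rate_hz = 8000,
    rng_seed = rng_seed, ...)
}

#' Scaled high-frequency analysis band for the test profile
#'
#' The real high analysis band (7-40 kHz) does not fit under the 4 kHz
#' Nyquist of the 8 kHz test profile; the scaled stand-in is 2.8-3.8 kHz.
#'
#' @return a [band()].
#' @export
test_high_band <- function() band("high", f_lo_hz = 2800, f_hi_hz = 3800)

#' Write a scene configuration to YAML
#'
#' @param config a [scene_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scene_config <- function(config, path) {
  ser <- rapply(unclass(config), function(x) {
    if (inherits(x, "POSIXct")) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    else x
  }, how = "replace")
  yaml::write_yaml(ser, path)
  invisible(path)
}
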