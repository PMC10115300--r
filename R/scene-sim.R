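#' Build the duty-cycle recording schedule
#'
#' One file record per station per duty-cycle slot in
#' `[start_time, end_time)`, with slots starting at period boundaries
#' aligned to `start_time`. Slots whose start falls inside a service gap
#' are dropped.
#'
#' @param config a [scene_config()].
#' @return data.frame with `file_id`, `station`, `timestamp` (POSIXct UTC),
#'   `duration_s`, `sample_rate_hz`.
#' @export
build_schedule <- function(config) {
  span <- as.numeric(difftime(config$end_time, config$start_time,
                              units = "secs"))
  if (span < 0) stop("end_time precedes start_time")
  if (span == 0) {
    return(data.frame(file_id = character(), station = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      duration_s = numeric(), sample_rate_hz = numeric()))
  }
  offsets <- seq(0, by = config$duty_period_s,
                 length.out = ceiling(span / config$duty_period_s))
  starts <- config$start_time + offsets
  keep <- rep(TRUE, length(starts))
  for (g in config$service_gaps)
    keep <- keep & !(starts >= g[1] & starts < g[2])
  starts <- starts[keep]
  rows <- lapply(config$stations, function(st) {
    data.frame(
      file_id = paste0(st$name, "_", format(starts, "%Y%m%d_%H%M%S",
                                            tz = "UTC")),
      station = st$name, timestamp = starts,
      duration_s = config$duty_on_s,
      sample_rate_hz = config$sample_rate_hz,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate the environmental logger series
#'
#' Water temperature is a seasonal sinusoid between the configured annual
#' minimum and maximum (coldest at `coldest_doy`) plus a small daily cycle
#' peaking mid-afternoon; depth is a clean semidiurnal sinusoid (12.42 h
#' period) with the configured tidal range. Sampled every 20 minutes, like
#' the HOBO loggers the schedule emulates.
#'
#' @param config a [scene_config()].
#' @param pad_s seconds of padding added on both ends so edge files still
#'   have bracketing tidal extrema and temperature samples.
#' @return data.frame `timestamp`, `water_temp_c`, `depth_m`.
#' @export
simulate_environment <- function(config, pad_s = 43200) {
  ts <- seq(config$start_time - pad_s, config$end_time + pad_s, by = 1200)
  doy <- as.numeric(difftime(ts, as.POSIXct(
    paste0(format(ts[1], "%Y"), "-01-01"), tz = "UTC"), units = "days"))
  mid <- (config$temp_min_c + config$temp_max_c) / 2
  amp <- (config$temp_max_c - config$temp_min_c) / 2
  seasonal <- mid - amp * cos(2 * pi * (doy - config$coldest_doy) / 365.25)
  hour_local <- (as.numeric(ts) / 3600 + config$utc_offset_h) %% 24
  daily <- -config$temp_daily_amp_c * cos(2 * pi * (hour_local - 15) / 24)
  t_h <- as.numeric(ts) / 3600
  depth <- config$depth_mean_m +
    (config$tidal_range_m / 2) * sin(2 * pi * t_h / TIDE_PERIOD_H)
  data.frame(timestamp = ts, water_temp_c = seasonal + daily,
             depth_m = depth)
}

# per-file covariates the generator conditions on
scene_file_covariates <- function(schedule, env, config) {
  loc <- schedule$timestamp + config$utc_offset_h * 3600
  dates <- seq(as.Date(config$start_time, tz = "UTC") - 2,
               as.Date(config$end_time, tz = "UTC") + 2, by = "day")
  st0 <- config$stations[[1]]
  sun <- make_sun_table(dates, st0$lat, st0$lon, config$utc_offset_h)
  tt <- as.numeric(schedule$timestamp)
  et <- as.numeric(env$timestamp)
  pos <- findInterval(tt, et, all.inside = TRUE)
  pick <- ifelse(abs(tt - et[pos]) <=
                   abs(tt - et[pmin(pos + 1L, length(et))]),
                 pos, pmin(pos + 1L, length(et)))
  if (any(abs(tt - et[pick]) > 600))
    stop("environment series does not cover file(s) ",
         paste(utils::head(schedule$file_id[abs(tt - et[pick]) > 600], 3),
               collapse = ", "))
  data.frame(
    hour = as.integer(format(loc, "%H")),
    month = as.integer(format(loc, "%m")),
    temp = env$water_temp_c[pick],
    diel = day_night(schedule$timestamp, sun, config$utc_offset_h),
    lunar = lunar_phase(schedule$timestamp, config$lunar_ref),
    tidal = tidal_phase(schedule$timestamp, env),
    weekend = as.integer(format(loc, "%u")) >= 6L)
}

#' Simulate the ground-truth event log for a scene
#'
#' Draws, per file: vessel presence (Bernoulli with day/night and weekend
#' modifiers) and, for every producer, a Poisson event count with rate
#' `base_rate x season gate x hour gate x temperature gate x lunar x tidal
#' x diel x station multiplier x noise_response^vessel`, then a log-normal
#' received level per event. Fully reproducible under the configured seed.
#'
#' @param config a [scene_config()].
#' @param schedule optional precomputed [build_schedule()] output.
#' @param env optional precomputed [simulate_environment()] output.
#' @return object of class `scene_truth`: list with `schedule` (plus the
#'   generator covariates), `counts` (files x producers integer matrix),
#'   `events` (one row per event: file index, producer, level, duration),
#'   `vessel_present`, `rain_present`, `env`, `config`.
#' @export
simulate_events <- function(config, schedule = NULL, env = NULL) {
  if (is.null(schedule)) schedule <- build_schedule(config)
  if (is.null(env)) env <- simulate_environment(config)
  cov <- scene_file_covariates(schedule, env, config)
  n <- nrow(schedule)
  set.seed(config$rng_seed)

  v <- config$vessel
  p_vessel <- ifelse(cov$diel == "day", v$day_rate, v$night_rate) *
    ifelse(cov$weekend, v$weekend_multiplier, 1)
  vessel_present <- stats::rbinom(n, 1, pmin(1, p_vessel))

  st_mult <- vapply(config$stations, function(s) s$rate_multiplier,
                    numeric(1))
  names(st_mult) <- vapply(config$stations, function(s) s$name,
                           character(1))
  mult_file <- st_mult[schedule$station]

  prods <- config$producers
  counts <- matrix(0L, n, length(prods),
                   dimnames = list(NULL,
                                   vapply(prods, `[[`, character(1),
                                          "name")))
  ev_file <- list(); ev_prod <- list(); ev_lev <- list()
  for (j in seq_along(prods)) {
    p <- prods[[j]]
    gate <- (cov$month %in% p$season_months) &
      (cov$hour %in% p$active_hours) &
      (cov$temp >= p$temp_range_c[1] & cov$temp <= p$temp_range_c[2])
    rate <- p$base_rate * as.numeric(gate) *
      p$lunar_effect[as.character(cov$lunar)] *
      p$tidal_effect[as.character(cov$tidal)] *
      p$diel_effect[as.character(cov$diel)] *
      mult_file * p$noise_response^vessel_present
    k <- stats::rpois(n, rate)
    counts[, j] <- k
    tot <- sum(k)
    if (tot > 0) {
      ev_file[[length(ev_file) + 1L]] <- rep(seq_len(n), k)
      ev_prod[[length(ev_prod) + 1L]] <- rep(p$name, tot)
      ev_lev[[length(ev_lev) + 1L]] <-
        stats::rnorm(tot, p$level_db, p$level_sd_db)
    }
  }
  events <- data.frame(
    file = if (length(ev_file)) unlist(ev_file) else integer(),
    producer = if (length(ev_prod)) unlist(ev_prod) else character(),
    level_db = if (length(ev_lev)) unlist(ev_lev) else numeric(),
    stringsAsFactors = FALSE)
  rain_idx <- which(vapply(prods, function(p) p$kind == "rain",
                           logical(1)))
  rain_present <- if (length(rain_idx))
    as.integer(rowSums(counts[, rain_idx, drop = FALSE]) > 0)
  else integer(n)

  structure(list(schedule = cbind(schedule, cov), counts = counts,
                 events = events, vessel_present = vessel_present,
                 rain_present = rain_present, env = env, config = config),
            class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat("Synthetic soundscape ground truth\n")
  cat("  files:    ", nrow(x$schedule), " (",
      length(unique(x$schedule$station)), " station(s), ",
      format(min(x$schedule$timestamp), "%Y-%m-%d"), " to ",
      format(max(x$schedule$timestamp), "%Y-%m-%d"), ")\n", sep = "")
  cat("  events:   ", nrow(x$events), " from ",
      sum(colSums(x$counts) > 0), " active producer(s)\n", sep = "")
  cat("  vessel:   present in ",
      round(100 * mean(x$vessel_present), 1), "% of files\n", sep = "")
  invisible(x)
}

band_overlap_frac <- function(src_lo, src_hi, b_lo, b_hi) {
  max(0, min(src_hi, b_hi) - max(src_lo, b_lo)) / (src_hi - src_lo)
}

ambient_density <- function(config) {
  # floor is defined as the SPL the ambient noise produces in 50-1200 Hz
  10^(config$ambient_floor_db / 10) / 1150
}

#' Expected band SPL table from the ground truth
#'
#' Computes each file's band SPL in closed form from the event log instead
#' of rendering and re-analyzing audio: mean-square band pressure is the
#' ambient density times the bandwidth, plus the vessel contribution when
#' present, plus each event's `10^(L/10) x duration / file duration`
#' weighted by the overlap of the producer band with the analysis band
#' (event energy taken as uniform over the declared band). Rendered files
#' agree with this closed form to within a couple of dB (see the package
#' tests); it is the fast path for scene-scale statistics.
#'
#' @param truth a `scene_truth` from [simulate_events()].
#' @param bands list of [band()] objects.
#' @return data.frame `file_id`, `station`, `timestamp`, `band`, `spl_db`,
#'   `silent`.
#' @export
truth_spl_table <- function(truth,
                            bands = list(band("low"), test_high_band())) {
  cfg <- truth$config
  n <- nrow(truth$schedule)
  dur <- cfg$duty_on_s
  v <- cfg$vessel
  nms <- vapply(cfg$producers, `[[`, character(1), "name")
  dur_by_name <- stats::setNames(
    vapply(cfg$producers, `[[`, numeric(1), "duration_s"), nms)
  ev_pow <- 10^(truth$events$level_db / 10)
  ev_dur <- unname(dur_by_name[truth$events$producer])
  out <- lapply(bands, function(bd) {
    pow <- rep(ambient_density(cfg) * (bd$f_hi_hz - bd$f_lo_hz), n)
    vf <- band_overlap_frac(v$band_lo_hz, v$band_hi_hz, bd$f_lo_hz,
                            bd$f_hi_hz)
    pow <- pow + truth$vessel_present * 10^(v$level_db / 10) * vf
    if (nrow(truth$events)) {
      frac_by_name <- stats::setNames(vapply(cfg$producers, function(p)
        band_overlap_frac(p$band_lo_hz, p$band_hi_hz, bd$f_lo_hz,
                          bd$f_hi_hz), numeric(1)), nms)
      ef <- unname(frac_by_name[truth$events$producer])
      contrib <- ev_pow * ev_dur * ef / dur
      agg <- rowsum(contrib, truth$events$file)
      pow[as.integer(rownames(agg))] <- pow[as.integer(rownames(agg))] +
        agg[, 1]
    }
    data.frame(file_id = truth$schedule$file_id,
               station = truth$schedule$station,
               timestamp = truth$schedule$timestamp,
               band = bd$label, spl_db = 10 * log10(pow),
               silent = FALSE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

scale_to_rms <- function(x, target_rms) {
  r <- sqrt(mean(x^2))
  if (r == 0) return(x)
  x * target_rms / r
}

bandpass_noise <- function(n_samp, fs, f_lo, f_hi) {
  x <- stats::rnorm(n_samp)
  ny <- fs / 2
  bf <- signal::butter(4, c(max(f_lo, 1) / ny, min(f_hi, ny * 0.999) / ny),
                       type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

render_event <- function(p, level_db, fs) {
  n <- max(8L, round(p$duration_s * fs))
  t <- seq_len(n) / fs
  prms <- 10^(level_db / 20)
  fc <- (p$band_lo_hz + p$band_hi_hz) / 2
  y <- switch(p$kind,
    snap = {
      env <- exp(-t / (p$duration_s / 5))
      bandpass_noise(n, fs, p$band_lo_hz, p$band_hi_hz) * env
    },
    fish = {
      env <- sin(pi * t / p$duration_s)^2
      # pulsed tone: carrier at band center with a slow pulse train,
      # keeping energy inside the declared band
      sin(2 * pi * fc * t) * (0.6 + 0.4 * cos(2 * pi * 20 * t)) * env
    },
    dolphin = {
      env <- sin(pi * t / p$duration_s)^2
      if (identical(p$dolphin_type, "whistles")) {
        f0 <- p$band_lo_hz + 0.1 * (p$band_hi_hz - p$band_lo_hz)
        f1 <- p$band_hi_hz - 0.1 * (p$band_hi_hz - p$band_lo_hz)
        phase <- 2 * pi * cumsum(f0 + (f1 - f0) * t / p$duration_s) / fs
        sin(phase) * env
      } else {
        bandpass_noise(n, fs, p$band_lo_hz, p$band_hi_hz) * env
      }
    },
    whale = {
      env <- sin(pi * t / p$duration_s)^2
      sin(2 * pi * fc * t) * env
    },
    rain = bandpass_noise(n, fs, p$band_lo_hz, p$band_hi_hz)
  )
  scale_to_rms(y, prms)
}

#' Render one file's pressure waveform and convert to digital counts
#'
#' Superposes the ambient Gaussian floor, vessel noise (when present) and
#' every ground-truth event of the file (snaps as exponentially damped
#' band-limited clicks, fish calls as pulsed tones in the species band,
#' dolphin whistles as FM sweeps, clicks/bursts as band-limited noise),
#' converts pressure to normalized digital counts through the calibration
#' chain, and hard-clips at full scale.
#'
#' @param truth a `scene_truth`.
#' @param file_id id of the file to render.
#' @param cal a [calibration_spec()].
#' @return list `samples` (normalized, clipped), `sample_rate`, `clipped`
#'   (fraction of clipped samples).
#' @export
render_waveform <- function(truth, file_id, cal = calibration_spec()) {
  cfg <- truth$config
  i <- match(file_id, truth$schedule$file_id)
  if (is.na(i)) stop("unknown file_id: ", file_id)
  fs <- cfg$sample_rate_hz
  hi_edges <- vapply(cfg$producers, `[[`, numeric(1), "band_hi_hz")
  if (any(hi_edges > fs / 2))
    stop("producer band edge above Nyquist; raise sample_rate_hz")
  n <- round(cfg$duty_on_s * fs)
  set.seed(cfg$rng_seed + i)

  # ambient floor: white with density matching the configured band SPL
  dens <- ambient_density(cfg)
  p_uPa <- stats::rnorm(n, sd = sqrt(dens * fs / 2))

  if (truth$vessel_present[i] == 1) {
    v <- cfg$vessel
    vn <- bandpass_noise(n, fs, v$band_lo_hz, min(v$band_hi_hz,
                                                  fs / 2 * 0.99))
    p_uPa <- p_uPa + scale_to_rms(vn, 10^(v$level_db / 20))
  }

  ev <- truth$events[truth$events$file == i, , drop = FALSE]
  prod_by_name <- stats::setNames(cfg$producers,
                           vapply(cfg$producers, `[[`, character(1),
                                  "name"))
  if (nrow(ev)) {
    for (k in seq_len(nrow(ev))) {
      p <- prod_by_name[[ev$producer[k]]]
      y <- render_event(p, ev$level_db[k], fs)
      onset <- sample.int(max(1L, n - length(y)), 1L)
      idx <- onset:(onset + length(y) - 1L)
      p_uPa[idx] <- p_uPa[idx] + y
    }
  }

  # pressure -> voltage -> normalized counts, hard clip at full scale
  s <- p_uPa * 10^((cal$sensitivity_db + cal$gain_db) / 20) /
    cal$full_scale_v
  clipped <- mean(abs(s) >= 1)
  s <- pmax(pmin(s, 1 - 2^-(cal$pcm_bits - 1)), -1)
  list(samples = s, sample_rate = fs, clipped = clipped)
}

#' Render a scene subset to WAV files on disk
#'
#' Writes `<station>_<YYYYMMDD>_<HHMMSS>.wav` for each requested file.
#'
#' @param truth a `scene_truth`.
#' @param dir output directory (created if needed).
#' @param file_ids files to render; defaults to the whole schedule.
#' @param cal a [calibration_spec()].
#' @return data.frame `file_id`, `path`, `station`, `timestamp`.
#' @export
render_scene <- function(truth, dir, file_ids = truth$schedule$file_id,
                         cal = calibration_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- match(file_ids, truth$schedule$file_id)
  paths <- character(length(file_ids))
  for (k in seq_along(file_ids)) {
    w <- render_waveform(truth, file_ids[k], cal)
    paths[k] <- file.path(dir, paste0(file_ids[k], ".wav"))
    write_wav(w$samples, w$sample_rate, paths[k], cal$pcm_bits)
  }
  data.frame(file_id = file_ids, path = paths,
             station = truth$schedule$station[idx],
             timestamp = truth$schedule$timestamp[idx],
             stringsAsFactors = FALSE)
}

count_to_score <- function(k, breaks) {
  ifelse(k == 0, 0L, ifelse(k < breaks[1], 1L,
                            ifelse(k < breaks[2], 2L, 3L)))
}

#' Export ground-truth annotations
#'
#' Produces the manual-review table an observer would have generated: fish
#' calling intensity on the 0-3 scale (0 = no calls, 1 = one call,
#' 2 = multiple calls, 3 = overlapping calls / chorusing, with the
#' count-to-score thresholds taken from the scene configuration), dolphin
#' vocalization counts by type plus their sum, and presence flags for
#' anthropogenic noise, rain and right whales.
#'
#' @param truth a `scene_truth`.
#' @return data.frame, one row per file (annotation schema).
#' @export
export_truth_annotations <- function(truth) {
  cfg <- truth$config
  prods <- cfg$producers
  kinds <- vapply(prods, `[[`, character(1), "kind")
  nms <- vapply(prods, `[[`, character(1), "name")
  out <- data.frame(file_id = truth$schedule$file_id,
                    station = truth$schedule$station,
                    timestamp = truth$schedule$timestamp,
                    stringsAsFactors = FALSE)
  for (j in which(kinds == "fish"))
    out[[nms[j]]] <- count_to_score(truth$counts[, j], cfg$score_breaks)
  dtype <- rep(NA_character_, length(prods))
  dtype[kinds == "dolphin"] <- vapply(prods[kinds == "dolphin"],
                                      function(p) p$dolphin_type,
                                      character(1))
  for (ty in c("echolocation", "whistles", "burst")) {
    j <- which(!is.na(dtype) & dtype == ty)
    out[[paste0("dolphin_", ty)]] <- if (length(j))
      as.integer(rowSums(truth$counts[, j, drop = FALSE]))
    else 0L
  }
  out$dolphin_sum <- out$dolphin_echolocation + out$dolphin_whistles +
    out$dolphin_burst
  out$noise <- as.integer(truth$vessel_present)
  out$rain <- as.integer(truth$rain_present)
  j <- which(kinds == "whale")
  out$right_whale <- if (length(j))
    as.integer(rowSums(truth$counts[, j, drop = FALSE]) > 0)
  else 0L
  out
}
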