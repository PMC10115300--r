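SYNODIC_DAYS <- 29.530588
TIDE_PERIOD_H <- 12.42

#' Lunar phase category
#'
#' Assigns each timestamp to one of four equal quarters of the synodic
#' month (29.530588 d), centered on the principal phases: `new` covers
#' phase fraction `[0.875, 1) U [0, 0.125)`, then `first_quarter`, `full`
#' and `third_quarter` each cover a quarter of the cycle.
#'
#' @param t POSIXct timestamp(s).
#' @param reference_new_moon POSIXct epoch of a known new moon.
#' @return factor with levels `new`, `first_quarter`, `full`,
#'   `third_quarter`.
#' @export
lunar_phase <- function(t, reference_new_moon) {
  f <- (as.numeric(difftime(t, reference_new_moon, units = "days")) /
          SYNODIC_DAYS) %% 1
  cat <- ifelse(f < 0.125 | f >= 0.875, "new",
         ifelse(f < 0.375, "first_quarter",
         ifelse(f < 0.625, "full", "third_quarter")))
  factor(cat, levels = c("new", "first_quarter", "full", "third_quarter"))
}

# Local extrema (alternating high/low) of a depth series, located by sign
# changes of the first difference; plateaus take their midpoint.
find_tide_extrema <- function(depth_series) {
  d <- depth_series$depth_m
  t <- depth_series$timestamp
  dd <- diff(d)
  s <- sign(dd)
  s[s == 0] <- NA
  # carry last nonzero sign through plateaus
  for (i in seq_along(s)) if (is.na(s[i]) && i > 1) s[i] <- s[i - 1]
  turns <- which(diff(s) != 0) + 1L
  if (length(turns) < 2)
    stop("depth series too short to locate tidal extrema")
  data.frame(timestamp = t[turns],
             type = ifelse(s[turns] < 0, "high", "low"),
             stringsAsFactors = FALSE)
}

#' Tidal phase category
#'
#' Classifies timestamps into `high`, `falling`, `low`, `rising` by
#' quartiles of the tidal cycle centered on the depth extrema: the quarter
#' cycle around each high water is `high`, the quarter around each low
#' water is `low`, and the descending and ascending halves between them are
#' `falling` and `rising`.
#'
#' @param t POSIXct timestamp(s) within the span of `depth_series`.
#' @param depth_series data.frame with `timestamp` (POSIXct) and `depth_m`,
#'   sampled at 20 minutes or finer.
#' @return factor with levels `high`, `falling`, `low`, `rising`.
#' @export
tidal_phase <- function(t, depth_series) {
  if (any(t < min(depth_series$timestamp) | t > max(depth_series$timestamp)))
    stop("timestamp outside the span of the depth series")
  ex <- find_tide_extrema(depth_series)
  # extend half a cycle beyond the first/last extremum so edge times still
  # have bracketing extrema
  half <- if (nrow(ex) >= 2) {
    as.numeric(difftime(ex$timestamp[2], ex$timestamp[1], units = "secs"))
  } else TIDE_PERIOD_H * 3600 / 2
  pre <- data.frame(timestamp = ex$timestamp[1] - half,
                    type = ifelse(ex$type[1] == "high", "low", "high"))
  post <- data.frame(
    timestamp = ex$timestamp[nrow(ex)] + half,
    type = ifelse(ex$type[nrow(ex)] == "high", "low", "high"))
  ex <- rbind(pre, ex, post)

  tt <- as.numeric(t)
  et <- as.numeric(ex$timestamp)
  idx <- findInterval(tt, et, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  idx[idx >= nrow(ex)] <- nrow(ex) - 1L
  f <- (tt - et[idx]) / (et[idx + 1L] - et[idx])
  from_high <- ex$type[idx] == "high"
  cat <- ifelse(from_high,
    ifelse(f < 0.25, "high", ifelse(f < 0.75, "falling", "low")),
    ifelse(f < 0.25, "low", ifelse(f < 0.75, "rising", "high")))
  factor(cat, levels = c("high", "falling", "low", "rising"))
}

#' NOAA-style sunrise/sunset table
#'
#' Computes daily sunrise and sunset (local civil time) from the standard
#' solar-position approximation (fractional-year expansion of the equation
#' of time and solar declination, zenith 90.833 degrees). Accuracy is
#' within a couple of minutes, sufficient for day/night classification.
#'
#' @param dates Date vector.
#' @param lat,lon station latitude/longitude, degrees (east positive).
#' @param utc_offset_h station local-time offset from UTC in hours.
#' @return data.frame `date`, `sunrise`, `sunset` (POSIXct, UTC stored,
#'   values are the local civil times shifted by `utc_offset_h`).
#' @export
make_sun_table <- function(dates, lat = 32.8, lon = -79.9,
                           utc_offset_h = -5) {
  doy <- as.integer(format(dates, "%j"))
  g <- 2 * pi / 365 * (doy - 1 + 0.5)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g)
                      - 0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  latr <- lat * pi / 180
  cosha <- cos(90.833 * pi / 180) / (cos(latr) * cos(decl)) -
    tan(latr) * tan(decl)
  cosha <- pmin(1, pmax(-1, cosha))
  ha <- acos(cosha) * 180 / pi
  rise_utc_min <- 720 - 4 * (lon + ha) - eqtime
  set_utc_min <- 720 - 4 * (lon - ha) - eqtime
  day0 <- as.POSIXct(paste(dates, "00:00:00"), tz = "UTC")
  data.frame(
    date = dates,
    sunrise = day0 + rise_utc_min * 60 + utc_offset_h * 3600,
    sunset = day0 + set_utc_min * 60 + utc_offset_h * 3600)
}

#' Day/night classification
#'
#' A timestamp is `day` iff `sunrise <= local t < sunset` for its local
#' calendar date (closed-open convention: the sunrise instant is day, the
#' sunset instant is night).
#'
#' @param t POSIXct timestamp(s), stored UTC.
#' @param sun_table output of [make_sun_table()] (or an equivalent table
#'   with `date`, `sunrise`, `sunset` columns; sunrise/sunset are local
#'   civil times expressed on the UTC axis like the timestamps).
#' @param utc_offset_h local offset used to pick the calendar date.
#' @return factor with levels `day`, `night`.
#' @export
day_night <- function(t, sun_table, utc_offset_h = -5) {
  local_date <- as.Date(t + utc_offset_h * 3600, tz = "UTC")
  i <- match(local_date, sun_table$date)
  if (anyNA(i))
    stop("sun table missing date(s): ",
         paste(unique(local_date[is.na(i)]), collapse = ", "))
  loc <- t + utc_offset_h * 3600
  rise <- sun_table$sunrise[i] + utc_offset_h * 3600
  set <- sun_table$sunset[i] + utc_offset_h * 3600
  factor(ifelse(loc >= rise & loc < set, "day", "night"),
         levels = c("day", "night"))
}

#' Astronomical season
#'
#' Season boundaries at the Northern-Hemisphere astronomical start dates:
#' spring begins March 20, summer June 21, fall September 22, winter
#' December 21 (year-wrapped).
#'
#' @param t POSIXct or Date vector.
#' @return factor with levels `winter`, `spring`, `summer`, `fall`.
#' @export
season_of <- function(t) {
  d <- as.Date(t, tz = "UTC")
  md <- as.integer(format(d, "%m")) * 100 + as.integer(format(d, "%d"))
  cat <- ifelse(md >= 320 & md < 621, "spring",
         ifelse(md >= 621 & md < 922, "summer",
         ifelse(md >= 922 & md < 1221, "fall", "winter")))
  factor(cat, levels = c("winter", "spring", "summer", "fall"))
}

#' Assemble the per-file covariate table
#'
#' Joins each recording slot to its predictors: station, month, water
#' temperature (nearest 20-min logger sample), lunar phase, tidal phase,
#' day/night, weekday and season. Files whose nearest temperature sample is
#' farther than `max_temp_gap_s` are flagged `missing = TRUE` and a count
#' is reported via message.
#'
#' @param schedule data.frame from [build_schedule()].
#' @param env environment series from [simulate_environment()] (or a real
#'   logger table with `timestamp`, `water_temp_c`, `depth_m`).
#' @param sun_table from [make_sun_table()].
#' @param lunar_ref POSIXct reference new moon.
#' @param utc_offset_h station local-time offset.
#' @param max_temp_gap_s maximum tolerated distance to a logger sample.
#' @return data.frame, one row per file.
#' @export
assemble_covariates <- function(schedule, env, sun_table, lunar_ref,
                                utc_offset_h = -5, max_temp_gap_s = 600) {
  tt <- as.numeric(schedule$timestamp)
  et <- as.numeric(env$timestamp)
  pos <- findInterval(tt, et, all.inside = TRUE)
  pick <- ifelse(abs(tt - et[pos]) <= abs(tt - et[pmin(pos + 1L, length(et))]),
                 pos, pmin(pos + 1L, length(et)))
  gap <- abs(tt - et[pick])
  missing <- gap > max_temp_gap_s
  if (any(missing))
    message(sum(missing), " file(s) lack a temperature sample within ",
            max_temp_gap_s, " s; flagged and excluded from models")
  loc <- schedule$timestamp + utc_offset_h * 3600
  out <- data.frame(
    file_id = schedule$file_id,
    station = schedule$station,
    month = as.integer(format(loc, "%m")),
    hour = as.integer(format(loc, "%H")),
    water_temp_c = ifelse(missing, NA_real_, env$water_temp_c[pick]),
    lunar_phase = lunar_phase(schedule$timestamp, lunar_ref),
    tidal_phase = tidal_phase(schedule$timestamp, env),
    diel = day_night(schedule$timestamp, sun_table, utc_offset_h),
    weekday = factor(c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")[
      as.integer(format(loc, "%u"))],
      levels = c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")),
    season = season_of(loc),
    missing = missing,
    stringsAsFactors = FALSE)
  out
}
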