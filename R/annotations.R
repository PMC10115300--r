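FISH_SPECIES <- c("oyster_toadfish", "spotted_seatrout", "silver_perch",
                  "atlantic_croaker", "red_drum", "weakfish", "black_drum")

#' Hourly review subsample
#'
#' Manual review covers one 2-minute file per hour out of the 20-minute
#' duty cycle: the file starting at minute 00 of each hour is kept.
#'
#' @param x data.frame with a `timestamp` column (schedule, annotation or
#'   SPL table).
#' @return the subset of `x` whose timestamps fall on the hour.
#' @export
hourly_subsample <- function(x) {
  if (nrow(x) == 0) return(x)
  keep <- as.integer(format(x$timestamp, "%M", tz = "UTC")) == 0L
  x[keep, , drop = FALSE]
}

# round half up to `digits` decimals (so 27.65 -> 27.7, unlike round());
# the epsilon guards exact .5 boundaries against binary representation
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5 + 1e-9) / 10^digits
}

#' Station-by-sound-class prevalence table
#'
#' For every station and sound class: the number of files with a detection
#' (fish intensity >= 1, dolphin count >= 1, or flag = 1), that count as a
#' percentage of the files analyzed at the station (1 decimal, half-up),
#' and the summed intensity scores (fish) or summed vocalization counts
#' (dolphins). A `total_fish` row counts each file at most once regardless
#' of how many species called.
#'
#' @param annotations annotation table (see [export_truth_annotations()]
#'   for the schema).
#' @param fish_threshold minimum intensity counting as a fish detection.
#' @return data.frame with `station`, `sound_class`,
#'   `files_with_detections`, `files_analyzed`, `percent`,
#'   `sum_intensity`.
#' @export
prevalence_table <- function(annotations, fish_threshold = 1) {
  fish_cols <- intersect(FISH_SPECIES, names(annotations))
  dol_cols <- intersect(c("dolphin_echolocation", "dolphin_whistles",
                          "dolphin_burst", "dolphin_sum"),
                        names(annotations))
  flag_cols <- intersect(c("noise", "rain", "right_whale"),
                         names(annotations))
  rows <- lapply(split(annotations, annotations$station), function(a) {
    n <- nrow(a)
    cell <- function(class, det, s = NA_real_) {
      data.frame(station = a$station[1], sound_class = class,
                 files_with_detections = det, files_analyzed = n,
                 percent = round_half_up(100 * det / n, 1),
                 sum_intensity = s, stringsAsFactors = FALSE)
    }
    out <- list()
    for (cc in fish_cols)
      out[[cc]] <- cell(cc, sum(a[[cc]] >= fish_threshold), sum(a[[cc]]))
    if (length(fish_cols)) {
      any_fish <- Reduce(`|`, lapply(fish_cols,
                                     function(cc) a[[cc]] >= fish_threshold))
      out$total_fish <- cell("total_fish", sum(any_fish))
    }
    for (cc in dol_cols)
      out[[cc]] <- cell(cc, sum(a[[cc]] >= 1), sum(a[[cc]]))
    for (cc in flag_cols)
      out[[cc]] <- cell(cc, sum(a[[cc]] == 1))
    do.call(rbind, out)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Chorusing and calling timelines
#'
#' Per station, species and year: the first and last calendar dates with
#' calling (intensity at or above `calling_threshold`, default 2), the
#' water temperature at those endpoint dates, and the number of distinct
#' calendar days containing at least one chorusing file (intensity 3).
#' When the record ends while calling is still ongoing (calling within
#' `open_window_days` of the last reviewed file) the row is flagged
#' `open_ended` and the last date is not interpretable as an end of
#' season.
#'
#' @param annotations annotation table.
#' @param env environment series with `timestamp`, `water_temp_c`.
#' @param species character vector; defaults to the fish columns present.
#' @param calling_threshold minimum intensity defining "calling dates".
#' @param chorus_threshold intensity defining chorusing (3).
#' @param open_window_days window before the record end within which
#'   ongoing calling marks the row open-ended.
#' @return data.frame with one row per station x species x year.
#' @export
chorusing_timeline <- function(annotations, env,
                               species = intersect(FISH_SPECIES,
                                                   names(annotations)),
                               calling_threshold = 2,
                               chorus_threshold = 3,
                               open_window_days = 7) {
  record_end <- max(as.Date(annotations$timestamp, tz = "UTC"))
  temp_at <- function(d) {
    if (is.na(d)) return(NA_real_)
    sel <- as.Date(env$timestamp, tz = "UTC") == d
    if (!any(sel)) return(NA_real_)
    mean(env$water_temp_c[sel])
  }
  rows <- list()
  for (st in unique(annotations$station)) {
    a <- annotations[annotations$station == st, , drop = FALSE]
    yrs <- unique(format(a$timestamp, "%Y", tz = "UTC"))
    for (sp in species) for (yr in sort(yrs)) {
      ay <- a[format(a$timestamp, "%Y", tz = "UTC") == yr, , drop = FALSE]
      calling <- ay$timestamp[ay[[sp]] >= calling_threshold]
      chorus_days <- unique(as.Date(
        ay$timestamp[ay[[sp]] >= chorus_threshold], tz = "UTC"))
      if (length(calling) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          station = st, species = sp, year = as.integer(yr),
          first_calling_date = as.Date(NA), last_calling_date = as.Date(NA),
          temp_at_first = NA_real_, temp_at_last = NA_real_,
          days_chorusing = 0L, open_ended = FALSE,
          stringsAsFactors = FALSE)
        next
      }
      d0 <- min(as.Date(calling, tz = "UTC"))
      d1 <- max(as.Date(calling, tz = "UTC"))
      open <- (record_end - d1) <= open_window_days
      rows[[length(rows) + 1L]] <- data.frame(
        station = st, species = sp, year = as.integer(yr),
        first_calling_date = d0,
        last_calling_date = if (open) as.Date(NA) else d1,
        temp_at_first = temp_at(d0),
        temp_at_last = if (open) NA_real_ else temp_at(d1),
        days_chorusing = length(chorus_days), open_ended = open,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Remove files containing anthropogenic noise from an SPL table
#'
#' Retains the SPL rows whose annotation has `noise = 0`, producing the
#' "no noise" subset whose patterns are primarily biological. SPL files
#' without a matching annotation are excluded with a warning (or an error
#' under `strict`).
#'
#' @param spl_table band SPL table with a `file_id` column.
#' @param annotations annotation table with `file_id` and `noise`.
#' @param strict error on SPL files lacking an annotation.
#' @return the retained subset, with attributes `n_retained`, `n_removed`
#'   and `n_unannotated`.
#' @export
exclude_noise <- function(spl_table, annotations, strict = FALSE) {
  noise <- annotations$noise[match(spl_table$file_id,
                                   annotations$file_id)]
  unann <- is.na(noise)
  if (any(unann)) {
    msg <- paste0(sum(unann), " SPL file(s) have no annotation")
    if (strict) stop(msg)
    warning(msg, "; excluding them")
  }
  keep <- !unann & noise == 0
  out <- spl_table[keep, , drop = FALSE]
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_removed") <- sum(!unann & noise == 1)
  attr(out, "n_unannotated") <- sum(unann)
  out
}

#' Read / write annotation tables
#'
#' Plain-CSV serialization of the annotation schema with ISO-8601 UTC
#' timestamps.
#'
#' @param annotations annotation table.
#' @param path CSV path.
#' @return `read_annotations` returns the table with parsed timestamps.
#' @export
write_annotations <- function(annotations, path) {
  a <- annotations
  a$timestamp <- format(a$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(a, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  a <- utils::read.csv(path, stringsAsFactors = FALSE)
  a$timestamp <- as.POSIXct(a$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                            tz = "UTC")
  a
}
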