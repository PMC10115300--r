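#' Noon-to-noon heat-map matrix
#'
#' Pivots a timestamped value series into the display layout used for
#' soundscape heat maps: rows are time-of-day bins running from 12:00 to
#' 12:00 the next day (so overnight fish chorusing appears as a contiguous
#' block), columns are calendar dates. Gaps stay `NA` — they are never
#' imputed.
#'
#' @param values data.frame with `timestamp` (POSIXct) and a value column.
#' @param value_col name of the value column.
#' @param grid_min bin width in minutes: 20 (duty-cycle grid, 72 rows) or
#'   60 (hourly review grid, 24 rows).
#' @param utc_offset_h local offset applied before binning.
#' @param noon_aligned start rows at 12:00 local (default) or midnight.
#' @return object of class `heatmap_matrix`: numeric matrix (rows = bins,
#'   columns = dates) with `times` and `dates` attributes.
#' @export
build_heatmap <- function(values, value_col = "spl_db", grid_min = 20,
                          utc_offset_h = -5, noon_aligned = TRUE) {
  stopifnot(grid_min %in% c(20, 60))
  loc <- values$timestamp + utc_offset_h * 3600
  shift <- if (noon_aligned) 12 * 3600 else 0
  disp <- loc - shift
  dates <- as.Date(disp, tz = "UTC")
  mins <- as.integer(format(disp, "%H", tz = "UTC")) * 60L +
    as.integer(format(disp, "%M", tz = "UTC"))
  bin <- mins %/% grid_min
  key <- paste(dates, bin)
  if (anyDuplicated(key))
    stop("duplicate cell(s), e.g. ", key[duplicated(key)][1])
  nbin <- as.integer(24 * 60 / grid_min)
  all_dates <- seq(min(dates), max(dates), by = "day")
  m <- matrix(NA_real_, nrow = nbin, ncol = length(all_dates))
  m[cbind(bin + 1L, match(dates, all_dates))] <- values[[value_col]]
  hh <- ((((seq_len(nbin) - 1) * grid_min) %/% 60) +
           if (noon_aligned) 12 else 0) %% 24
  mm <- ((seq_len(nbin) - 1) * grid_min) %% 60
  structure(m, times = sprintf("%02d:%02d", hh, mm),
            dates = all_dates, quantity = value_col,
            class = c("heatmap_matrix", "matrix", "array"))
}

#' Write a heat map as CSV (and optionally PNG)
#'
#' The CSV sidecar holds the exact plotted numbers (rows = time-of-day
#' bins, columns = dates); the image is a thin convenience rendering.
#'
#' @param hm a [build_heatmap()] result.
#' @param csv_path output CSV path.
#' @param png_path optional PNG path; rendering failures (e.g. no graphics
#'   device available) are tolerated with a message.
#' @return `csv_path`, invisibly.
#' @export
write_heatmap <- function(hm, csv_path, png_path = NULL) {
  df <- as.data.frame(unclass(hm))
  names(df) <- as.character(attr(hm, "dates"))
  df <- cbind(time = attr(hm, "times"), df)
  utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(png_path)) {
    ok <- tryCatch({
      grDevices::png(png_path, width = 900, height = 500)
      on.exit(grDevices::dev.off(), add = TRUE)
      graphics::image(t(unclass(hm))[, rev(seq_len(nrow(hm))),
                                     drop = FALSE],
                      axes = FALSE, xlab = "date",
                      ylab = "time of day (noon to noon)",
                      main = attr(hm, "quantity"))
      TRUE
    }, error = function(e) {
      message("PNG rendering skipped: ", conditionMessage(e))
      FALSE
    })
    invisible(ok)
  }
  invisible(csv_path)
}

#' Format a prevalence table as station blocks
#'
#' Renders each station's counts as `"<count> (<percent>%)"` strings in
#' the conventional prevalence-table layout (fish species, total fish,
#' dolphin types and sum, other flags, files reviewed).
#'
#' @param prev output of [prevalence_table()].
#' @return data.frame with one row per sound class and one column per
#'   station, plus a `files_reviewed` bottom row.
#' @export
prevalence_report <- function(prev) {
  stations <- unique(prev$station)
  classes <- unique(prev$sound_class)
  out <- data.frame(sound_class = c(classes, "files_reviewed"),
                    stringsAsFactors = FALSE)
  for (st in stations) {
    p <- prev[prev$station == st, , drop = FALSE]
    col <- vapply(classes, function(cl) {
      r <- p[p$sound_class == cl, , drop = FALSE]
      if (nrow(r) == 0) return("")
      sprintf("%d (%.1f%%)", r$files_with_detections[1], r$percent[1])
    }, character(1))
    out[[st]] <- c(col, as.character(p$files_analyzed[1]))
  }
  out
}

#' Parse a rendered prevalence cell back to its numbers
#'
#' @param cell string like `"3244 (27.6%)"`.
#' @return list with `count` and `percent`.
#' @export
parse_prevalence_cell <- function(cell) {
  m <- regmatches(cell, regexec("^(\\d+) \\(([0-9.]+)%\\)$", cell))[[1]]
  if (length(m) != 3) stop("unparseable prevalence cell: ", cell)
  list(count = as.integer(m[2]), percent = as.numeric(m[3]))
}

#' Run the full synthetic-scene analysis pipeline
#'
#' Simulates a scene, derives band SPLs, covariates and annotations, runs
#' the prevalence/chorusing summaries and the noise-exclusion re-analysis,
#' fits the day/night DTK comparisons on the full and noise-excluded SPL
#' tables, and writes every artifact (CSV/JSON) plus a manifest with the
#' seed, a config fingerprint and per-file checksums into `out_dir`.
#'
#' @param config a [scene_config()].
#' @param out_dir output directory.
#' @param render_wavs number of files to render to WAV as an audio sample
#'   (0 disables rendering).
#' @return list with the in-memory artifacts and `manifest` (data.frame).
#' @export
run_pipeline <- function(config, out_dir, render_wavs = 0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- simulate_events(config)
  spl <- truth_spl_table(truth)
  ann <- export_truth_annotations(truth)
  st0 <- config$stations[[1]]
  sun <- make_sun_table(
    seq(as.Date(config$start_time, tz = "UTC") - 2,
        as.Date(config$end_time, tz = "UTC") + 2, by = "day"),
    st0$lat, st0$lon, config$utc_offset_h)
  cov <- assemble_covariates(truth$schedule, truth$env, sun,
                             config$lunar_ref, config$utc_offset_h)
  ann_h <- hourly_subsample(ann)
  prev <- prevalence_table(ann_h)
  timeline <- chorusing_timeline(ann_h, truth$env)
  spl_h <- spl[spl$file_id %in% ann_h$file_id, , drop = FALSE]
  spl_nonoise <- exclude_noise(spl_h, ann_h)

  diel_of <- cov$diel[match(spl$file_id, cov$file_id)]
  dtk_full <- lapply(split(seq_len(nrow(spl)), spl$band), function(i)
    dtk_posthoc(spl$spl_db[i], diel_of[i]))
  diel_nn <- cov$diel[match(spl_nonoise$file_id, cov$file_id)]
  dtk_nonoise <- lapply(split(seq_len(nrow(spl_nonoise)),
                              spl_nonoise$band), function(i)
    dtk_posthoc(spl_nonoise$spl_db[i], diel_nn[i]))

  paths <- c(
    spl = file.path(out_dir, "band_spl.csv"),
    annotations = file.path(out_dir, "annotations.csv"),
    covariates = file.path(out_dir, "covariates.csv"),
    prevalence = file.path(out_dir, "prevalence.csv"),
    timeline = file.path(out_dir, "chorusing_timeline.csv"),
    spl_nonoise = file.path(out_dir, "band_spl_no_noise.csv"),
    config = file.path(out_dir, "scene_config.yaml"),
    diel_contrast = file.path(out_dir, "diel_contrast.json"))
  wr <- function(x, p) {
    if ("timestamp" %in% names(x))
      x$timestamp <- format(x$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                            tz = "UTC")
    utils::write.csv(x, p, row.names = FALSE)
  }
  wr(spl, paths["spl"]); wr(ann, paths["annotations"])
  wr(cov, paths["covariates"]); wr(prev, paths["prevalence"])
  wr(timeline, paths["timeline"]); wr(spl_nonoise, paths["spl_nonoise"])
  write_scene_config(config, paths["config"])
  contrast <- lapply(names(dtk_full), function(b) {
    dn <- function(d) unname(d$means["day"] - d$means["night"])
    list(band = b, full_day_minus_night_db = dn(dtk_full[[b]]),
         nonoise_day_minus_night_db =
           if (b %in% names(dtk_nonoise)) dn(dtk_nonoise[[b]]) else NA)
  })
  jsonlite::write_json(contrast, paths["diel_contrast"],
                       auto_unbox = TRUE, digits = NA)
  if (render_wavs > 0) {
    rendered <- render_scene(truth, file.path(out_dir, "wav"),
                             utils::head(truth$schedule$file_id,
                                         render_wavs))
    paths <- c(paths, stats::setNames(rendered$path,
                                      paste0("wav_", rendered$file_id)))
  }

  manifest <- data.frame(
    artifact = names(paths), path = unname(paths),
    md5 = vapply(unname(paths), function(p) unname(tools::md5sum(p)),
                 character(1)),
    stringsAsFactors = FALSE)
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(cbind(manifest, seed = config$rng_seed),
                   manifest_path, row.names = FALSE)
  list(truth = truth, spl = spl, annotations = ann, covariates = cov,
       prevalence = prev, timeline = timeline,
       spl_nonoise = spl_nonoise, dtk_full = dtk_full,
       dtk_nonoise = dtk_nonoise, manifest = manifest)
}
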