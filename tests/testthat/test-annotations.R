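test_that("hourly subsample keeps the on-the-hour file", {
  sc <- tiny_scene(days = 1)
  sched <- build_schedule(sc)
  sub <- hourly_subsample(sched)
  expect_equal(nrow(sub), 24)
  expect_true(all(format(sub$timestamp, "%M") == "00"))
  expect_equal(nrow(hourly_subsample(sched[0, ])), 0)
  # irregular grid: equals the brute-force minute==0 filter
  odd <- sched[seq(1, 72, by = 5), ]
  expect_equal(hourly_subsample(odd),
               odd[as.integer(format(odd$timestamp, "%M")) == 0, ])
})

test_that("prevalence cells reproduce count/percent arithmetic", {
  a <- annotation_frame(200)
  a$oyster_toadfish[1:55] <- 1L
  a$oyster_toadfish[1:10] <- 3L
  a$spotted_seatrout[50:69] <- 2L
  a$noise[1:80] <- 1L
  a$dolphin_echolocation[1:7] <- 5L
  a$dolphin_sum <- a$dolphin_echolocation
  prev <- prevalence_table(a)
  g <- function(cl) prev[prev$sound_class == cl, ]
  expect_equal(g("oyster_toadfish")$files_with_detections, 55)
  expect_equal(g("oyster_toadfish")$percent, 27.5)
  expect_equal(g("oyster_toadfish")$sum_intensity, 45 + 30)
  expect_equal(g("noise")$files_with_detections, 80)
  expect_equal(g("dolphin_echolocation")$sum_intensity, 35)
  # total fish counts each file once: union of rows 1:55 and 50:69 is
  # 69 files, not the 75 a per-species sum would give
  expect_equal(g("total_fish")$files_with_detections, 69)
  # all-zero input
  prev0 <- prevalence_table(annotation_frame(10))
  expect_true(all(prev0$files_with_detections == 0))
  expect_true(all(prev0$percent == 0))
})

test_that("percentages round half-up and invert back to counts", {
  a <- annotation_frame(11760)
  a$oyster_toadfish[1:3244] <- 1L
  prev <- prevalence_table(a)
  cell <- prev[prev$sound_class == "oyster_toadfish", ]
  expect_equal(cell$percent, 27.6)
  # half-up at the boundary: 0.15% of 2000 files = 3 files
  b <- annotation_frame(2000)
  b$silver_perch[1:3] <- 1L
  expect_equal(prevalence_table(b)[
    prevalence_table(b)$sound_class == "silver_perch", ]$percent, 0.2)
  # consistency: percent x analyzed / 100 rounds back to the count
  set.seed(4)
  cc <- annotation_frame(500)
  cc$spotted_seatrout <- sample(0:3, 500, replace = TRUE,
                                prob = c(0.8, 0.1, 0.07, 0.03))
  prev2 <- prevalence_table(cc)
  for (i in seq_len(nrow(prev2)))
    expect_equal(round(prev2$percent[i] * prev2$files_analyzed[i] / 100),
                 prev2$files_with_detections[i], tolerance = 1)
})

test_that("random annotations match a brute-force tally", {
  set.seed(8)
  a <- rbind(annotation_frame(120, "s1"), annotation_frame(80, "s2"))
  for (cc in c("oyster_toadfish", "silver_perch", "black_drum"))
    a[[cc]] <- sample(0:3, nrow(a), replace = TRUE)
  a$noise <- sample(0:1, nrow(a), replace = TRUE)
  prev <- prevalence_table(a)
  for (st in c("s1", "s2")) {
    sub <- a[a$station == st, ]
    for (cc in c("oyster_toadfish", "silver_perch", "black_drum")) {
      det <- 0; si <- 0
      for (i in seq_len(nrow(sub))) {
        if (sub[[cc]][i] >= 1) det <- det + 1
        si <- si + sub[[cc]][i]
      }
      row <- prev[prev$station == st & prev$sound_class == cc, ]
      expect_equal(row$files_with_detections, det)
      expect_equal(row$sum_intensity, si)
      expect_equal(row$percent, floor(1000 * det / nrow(sub) + 0.5) / 10)
    }
  }
  # permutation invariance
  prev2 <- prevalence_table(a[sample(nrow(a)), ])
  o <- function(x) x[order(x$station, x$sound_class), ]
  expect_equal(o(prev2), o(prev), ignore_attr = TRUE)
})

test_that("chorusing timelines report spans, temps and chorus days", {
  sc <- tiny_scene(days = 90)
  env <- simulate_environment(sc)
  a <- annotation_frame(90 * 72)
  # plant: calling (>=2) April 10 to May 20, chorusing on known dates
  dates <- as.Date(a$timestamp, tz = "UTC")
  a$spotted_seatrout[dates == as.Date("2018-04-10")] <- 2L
  a$spotted_seatrout[dates == as.Date("2018-05-20")] <- 2L
  chorus_days <- seq(as.Date("2018-04-15"), by = "day", length.out = 58)
  for (d in chorus_days)
    a$spotted_seatrout[which(dates == d)[1]] <- 3L
  tl <- chorusing_timeline(a, env)
  row <- tl[tl$species == "spotted_seatrout", ]
  expect_equal(row$first_calling_date, as.Date("2018-04-10"))
  expect_equal(row$last_calling_date, as.Date("2018-06-11"))
  expect_equal(row$days_chorusing, 58)
  expect_false(row$open_ended)
  expect_equal(row$temp_at_first,
               mean(env$water_temp_c[as.Date(env$timestamp,
                                             tz = "UTC") ==
                                       as.Date("2018-04-10")]))
  # a species never reaching intensity 2 yields a null span
  row2 <- tl[tl$species == "black_drum", ]
  expect_true(is.na(row2$first_calling_date))
  expect_equal(row2$days_chorusing, 0)
  # single intensity-2 file: first == last, no chorusing
  b <- annotation_frame(72 * 30)
  b$red_drum[500] <- 2L
  tlb <- chorusing_timeline(b, env)
  rb <- tlb[tlb$species == "red_drum", ]
  expect_equal(rb$first_calling_date, rb$last_calling_date)
  expect_equal(rb$days_chorusing, 0)
})

test_that("records truncated mid-season are flagged open-ended", {
  sc <- tiny_scene(days = 10)
  env <- simulate_environment(sc)
  a <- annotation_frame(10 * 72)
  dates <- as.Date(a$timestamp, tz = "UTC")
  # calling continues through the final recorded day
  a$silver_perch[dates >= as.Date("2018-04-05")] <- 2L
  tl <- chorusing_timeline(a, env)
  row <- tl[tl$species == "silver_perch", ]
  expect_true(row$open_ended)
  expect_true(is.na(row$last_calling_date))
  expect_true(is.na(row$temp_at_last))
})

test_that("noise exclusion is an exact partition of the SPL table", {
  a <- annotation_frame(100)
  set.seed(14)
  a$noise <- sample(0:1, 100, replace = TRUE)
  spl <- data.frame(file_id = a$file_id, band = "low",
                    spl_db = rnorm(100, 100), stringsAsFactors = FALSE)
  sub <- exclude_noise(spl, a)
  expect_equal(sub$file_id, a$file_id[a$noise == 0])
  expect_equal(attr(sub, "n_retained") + attr(sub, "n_removed"),
               nrow(spl))
  expect_equal(attr(sub, "n_unannotated"), 0)
  # all noisy -> empty; all quiet -> identity
  a$noise <- 1L
  expect_equal(nrow(exclude_noise(spl, a)), 0)
  a$noise <- 0L
  expect_equal(nrow(exclude_noise(spl, a)), 100)
  # unannotated files warn (or error in strict mode)
  expect_warning(exclude_noise(rbind(spl, data.frame(
    file_id = "ghost", band = "low", spl_db = 90)), a),
    "no annotation")
  expect_error(exclude_noise(rbind(spl, data.frame(
    file_id = "ghost", band = "low", spl_db = 90)), a, strict = TRUE),
    "no annotation")
})

test_that("annotation CSV round-trips with ISO timestamps", {
  a <- annotation_frame(5)
  a$noise[2] <- 1L
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(a, path)
  b <- read_annotations(path)
  expect_equal(b$timestamp, a$timestamp)
  expect_equal(b$noise, a$noise)
})
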