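#' Replicated day/night inversion experiment
#'
#' The central masking phenomenon in an urbanized estuary: with day-biased
#' vessel noise and night-biased biology, the full band-SPL tables are
#' louder by day, while the noise-excluded subsets are louder by night.
#' This experiment generates `n_reps` independent synthetic scenes and
#' runs the DTK day/night comparison on the full tables (20-min grid) and
#' on the noise-excluded hourly subsets for both analysis bands.
#'
#' @param n_reps number of seeded replicate scenes.
#' @param days scene length per replicate.
#' @param base_seed seed of the first replicate; replicate r uses
#'   `base_seed + r - 1`.
#' @return data.frame with one row per replicate: the four day-minus-night
#'   mean contrasts (dB), their DTK significance, and `success` (full
#'   tables day > night and excluded subsets night > day, all
#'   significant, in both bands).
#' @export
replicate_diel_inversion <- function(n_reps = 20, days = 60,
                                     base_seed = 1L) {
  rows <- lapply(seq_len(n_reps), function(r) {
    sc <- default_scene(days = days, rng_seed = base_seed + r - 1L)
    truth <- simulate_events(sc)
    spl <- truth_spl_table(truth)
    ann_h <- hourly_subsample(export_truth_annotations(truth))
    diel <- truth$schedule$diel
    names(diel) <- truth$schedule$file_id
    res <- list(rep = r)
    ok <- TRUE
    for (b in c("low", "high")) {
      s <- spl[spl$band == b, ]
      d_full <- dtk_posthoc(s$spl_db, diel[s$file_id])
      s_h <- s[s$file_id %in% ann_h$file_id, ]
      s_nn <- exclude_noise(s_h, ann_h)
      d_nn <- dtk_posthoc(s_nn$spl_db, diel[s_nn$file_id])
      full_dn <- unname(d_full$means["day"] - d_full$means["night"])
      nn_dn <- unname(d_nn$means["day"] - d_nn$means["night"])
      res[[paste0(b, "_full_day_minus_night")]] <- full_dn
      res[[paste0(b, "_nonoise_day_minus_night")]] <- nn_dn
      ok <- ok && full_dn > 0 && d_full$table$significant &&
        nn_dn < 0 && d_nn$table$significant
    }
    res$success <- ok
    as.data.frame(res)
  })
  do.call(rbind, rows)
}

#' Replicated noise-effect direction experiment
#'
#' Verifies that the targeted species models recover the planted direction
#' of the vessel-noise effect: a noise-suppressed fish (silver perch,
#' rate modifier 0.35 under noise) should test `"0 > 1"`, noise-boosted
#' dolphins (modifier 3) `"1 > 0"`, and a null producer with no temporal
#' structure and modifier 1 `"0 = 1"`. Each replicate draws fresh scenes
#' inside the respective species windows (spring for the fish, winter for
#' the dolphins).
#'
#' @param n_reps number of seeded replicates.
#' @param base_seed first seed.
#' @return data.frame with one row per replicate x case: `case`,
#'   `direction`, `ok`.
#' @export
replicate_noise_directions <- function(n_reps = 20, base_seed = 1L) {
  run_case <- function(sc, species, windows, expected) {
    truth <- simulate_events(sc)
    ann <- hourly_subsample(export_truth_annotations(truth))
    cov <- data.frame(file_id = truth$schedule$file_id,
                      month = truth$schedule$month,
                      hour = truth$schedule$hour,
                      stringsAsFactors = FALSE)
    cov <- cov[cov$file_id %in% ann$file_id, ]
    tm <- targeted_model(species, ann, cov, windows = windows)
    data.frame(direction = tm$direction, ok = tm$direction == expected,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(n_reps), function(r) {
    seed <- base_seed + r - 1L
    fish <- run_case(default_scene(days = 45, n_stations = 1,
                                   rng_seed = seed),
                     "silver_perch", species_windows(), "0 > 1")
    dolph <- run_case(
      default_scene(days = 45, n_stations = 1, rng_seed = seed,
                    start_time = as.POSIXct("2017-12-01 00:00:00",
                                            tz = "UTC")),
      "dolphin", species_windows(), "1 > 0")
    null_sc <- default_scene(days = 30, n_stations = 1, rng_seed = seed)
    null_sc$producers <- list(
      unknown1 = producer_spec("unknown1", "fish", 200, 1200,
                               base_rate = 2, noise_response = 1,
                               level_db = 120))
    null <- run_case(null_sc, "unknown1",
                     list(unknown1 = list(months = 1:12, hours = 0:23)),
                     "0 = 1")
    cbind(rep = r, case = c("suppressed_fish", "boosted_dolphin",
                            "null_producer"),
          rbind(fish, dolph, null))
  })
  do.call(rbind, rows)
}

#' Shadow-ranking calibration experiment
#'
#' Two repeated designs check the shadow-feature selection: an informative
#' design (one strong predictor, three pure-noise predictors) where the
#' strong predictor should be confirmed and every noise predictor
#' rejected, and an all-noise design where confirmations are false
#' positives whose expected number is bounded by `alpha` per predictor.
#'
#' The design sizes reflect where the shadow procedure is statistically
#' well behaved at interactive run times: 2000 rows (the scale of a
#' multi-station season of hourly review) and a moderate 100-tree forest
#' per iteration. At much smaller n — or with very large forests whose
#' importance estimates resolve ever-weaker associations — a forest can
#' consistently exploit chance in-sample correlations of truly irrelevant
#' predictors, leaving them tentative or falsely confirmed (see the
#' methods vignette).
#'
#' @param n_runs seeded runs of the informative design.
#' @param n_null_runs seeded runs of the all-noise design.
#' @param n rows per run.
#' @param n_trees forest size per shadow iteration.
#' @param max_iter shadow iteration cap per run.
#' @param alpha shadow-test significance level.
#' @param mc_adjust forwarded to [shadow_rank()]; the calibration runs
#'   the plain binomial test at `alpha` (the wide shadow set supplies the
#'   multiplicity control here).
#' @param base_seed first seed.
#' @return list with `informative` (per run: strong_confirmed,
#'   noise_rejected, ok) and `null` (per run: n_confirmed).
#' @export
shadow_rank_calibration <- function(n_runs = 20, n_null_runs = n_runs,
                                    n = 2000, n_trees = 100,
                                    max_iter = 50, alpha = 0.01,
                                    mc_adjust = FALSE, base_seed = 1L) {
  informative <- lapply(seq_len(n_runs), function(r) {
    seed <- base_seed + r - 1L
    set.seed(seed)
    tab <- data.frame(x = stats::rnorm(n), n1 = stats::rnorm(n),
                      n2 = stats::rnorm(n), n3 = stats::rnorm(n))
    tab$y <- 2 * tab$x + stats::rnorm(n, sd = 0.5)
    rk <- shadow_rank(model_spec("y", c("x", "n1", "n2", "n3"),
                                 n_trees = n_trees, rng_seed = seed,
                                 alpha = alpha), tab,
                      max_iter = max_iter, mc_adjust = mc_adjust)
    dec <- stats::setNames(rk$importance$decision,
                           rk$importance$predictor)
    data.frame(run = r,
               strong_confirmed = dec[["x"]] == "confirmed",
               noise_rejected = all(dec[c("n1", "n2", "n3")] ==
                                      "rejected"))
  })
  informative <- do.call(rbind, informative)
  informative$ok <- informative$strong_confirmed &
    informative$noise_rejected

  null <- lapply(seq_len(n_null_runs), function(r) {
    seed <- base_seed + 1000L + r - 1L
    set.seed(seed)
    tab <- data.frame(n1 = stats::rnorm(n), n2 = stats::rnorm(n),
                      n3 = stats::rnorm(n), n4 = stats::rnorm(n))
    tab$y <- stats::rnorm(n)
    rk <- shadow_rank(model_spec("y", c("n1", "n2", "n3", "n4"),
                                 n_trees = n_trees, rng_seed = seed,
                                 alpha = alpha), tab,
                      max_iter = max_iter, mc_adjust = mc_adjust)
    data.frame(run = r,
               n_confirmed = sum(rk$importance$decision == "confirmed"))
  })
  list(informative = informative, null = do.call(rbind, null))
}
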