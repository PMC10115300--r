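#' Random-forest model specification
#'
#' @param response name of the response column.
#' @param predictors character vector of predictor columns. `month` and
#'   `water_temp_c` must never appear together (collinearity; the two
#'   variants are compared by [select_month_or_temp()]).
#' @param task `"auto"` resolves to classification for factor responses
#'   and regression otherwise.
#' @param n_trees number of trees.
#' @param rng_seed seed set before each stochastic fit.
#' @param alpha significance level of the shadow-feature binomial test.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(response, predictors,
                       task = c("auto", "regression", "classification"),
                       n_trees = 500, rng_seed = 42L, alpha = 0.01) {
  task <- match.arg(task)
  if (length(predictors) == 0) stop("predictors must be non-empty")
  if (all(c("month", "water_temp_c") %in% predictors))
    stop("month and water_temp_c must not be used together; ",
         "see select_month_or_temp()")
  structure(list(response = response, predictors = predictors,
                 task = task, n_trees = n_trees,
                 rng_seed = as.integer(rng_seed), alpha = alpha),
            class = "model_spec")
}

prepare_model_frame <- function(spec, table) {
  cols <- c(spec$response, spec$predictors)
  miss <- setdiff(cols, names(table))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- table[, cols, drop = FALSE]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < 50)
    stop("insufficient data: ", nrow(df), " complete rows (need >= 50)")
  for (cc in names(df))
    if (is.character(df[[cc]]) || is.logical(df[[cc]]))
      df[[cc]] <- factor(df[[cc]])
  y <- df[[spec$response]]
  task <- spec$task
  if (task == "auto")
    task <- if (is.factor(y)) "classification" else "regression"
  if (task == "classification" && !is.factor(y))
    df[[spec$response]] <- factor(df[[spec$response]])
  if (length(unique(df[[spec$response]])) < 2)
    stop("degenerate model: response '", spec$response, "' is constant")
  list(df = df, task = task)
}

rf_score <- function(rf, task) {
  nt <- length(if (task == "regression") rf$rsq else rf$err.rate[, "OOB"])
  if (task == "regression") 100 * rf$rsq[nt]
  else 100 * (1 - rf$err.rate[nt, "OOB"])
}

#' Fit a random forest and report its OOB score
#'
#' Fits a bagged ensemble of decision trees; each tree trains on a
#' bootstrap sample (about two-thirds of the data) and is evaluated on its
#' out-of-bag (OOB) remainder. The reported score is the percent variance
#' explained (regression) or the prediction accuracy, `100 - OOB error`
#' (classification). Deterministic under the spec's seed.
#'
#' @param spec a [model_spec()].
#' @param table data.frame containing response and predictors.
#' @return object of class `rf_fit`: list with `model` (the randomForest
#'   object), `score`, `task`, `n`, `spec`.
#' @export
fit_rf <- function(spec, table) {
  pf <- prepare_model_frame(spec, table)
  set.seed(spec$rng_seed)
  rf <- randomForest::randomForest(
    x = pf$df[, spec$predictors, drop = FALSE],
    y = pf$df[[spec$response]],
    ntree = spec$n_trees)
  structure(list(model = rf, score = rf_score(rf, pf$task),
                 task = pf$task, n = nrow(pf$df), spec = spec),
            class = "rf_fit")
}

#' @export
print.rf_fit <- function(x, ...) {
  lab <- if (x$task == "regression") "% variance explained"
  else "prediction accuracy (100 - OOB error, %)"
  cat("Random forest (", x$task, ", n = ", x$n, ", trees = ",
      x$spec$n_trees, ")\n  ", lab, ": ", round(x$score, 2), "\n",
      sep = "")
  invisible(x)
}

#' Shadow-feature importance ranking
#'
#' Iteratively appends a shuffled ("shadow") copy of every predictor to
#' the design, fits a random forest with permutation importance, and
#' scores a hit for each real predictor that outranks the best shadow. A
#' two-sided binomial test at `alpha` on the accumulated hits confirms or
#' rejects predictors; undecided predictors after `max_iter` iterations
#' are reported tentative. Mean, minimum and maximum importance Z-scores
#' (permutation importance scaled by its standard error, compared against
#' randomized data, not a p-value) are reported per predictor, together
#' with the plain-model OOB score.
#'
#' Following the usual practice of shadow-feature selection tools, the
#' binomial test is Bonferroni-adjusted for the number of attributes under
#' test (`mc_adjust = TRUE`); disabling the adjustment speeds decisions up
#' but is anti-conservative on small, overfit-prone samples.
#'
#' @param spec a [model_spec()].
#' @param table data.frame.
#' @param max_iter maximum number of shadow iterations.
#' @param mc_adjust Bonferroni-adjust the decision threshold across
#'   attributes.
#' @param min_shadows minimum size of the shadow set: when fewer live
#'   predictors remain, extra shuffled copies are added (extending the
#'   reference tool's at-least-5-shadows rule) so the max-shadow null
#'   reference stays sharp and true nulls resolve quickly.
#' @return object of class `shadow_rank`: `importance` data.frame
#'   (predictor, mean_z, min_z, max_z, hits, iters, decision), `score`,
#'   `task`, `n`.
#' @export
shadow_rank <- function(spec, table, max_iter = 100, mc_adjust = TRUE,
                        min_shadows = 9L) {
  pf <- prepare_model_frame(spec, table)
  df <- pf$df
  y <- df[[spec$response]]
  preds <- spec$predictors
  thresh <- spec$alpha / 2 / if (mc_adjust) length(preds) else 1
  set.seed(spec$rng_seed)

  decision <- stats::setNames(rep("tentative", length(preds)), preds)
  hits <- stats::setNames(integer(length(preds)), preds)
  iters <- stats::setNames(integer(length(preds)), preds)
  zhist <- stats::setNames(vector("list", length(preds)), preds)

  for (it in seq_len(max_iter)) {
    live <- names(decision)[decision != "rejected"]
    x <- df[, live, drop = FALSE]
    src <- live
    while (length(src) < min_shadows)
      src <- c(src, live[seq_len(min(length(live),
                                     min_shadows - length(src)))])
    shadow <- as.data.frame(lapply(df[, src, drop = FALSE], sample))
    names(shadow) <- paste0("shadow_", seq_along(src))
    rf <- randomForest::randomForest(x = cbind(x, shadow), y = y,
                                     ntree = spec$n_trees,
                                     importance = TRUE)
    imp <- randomForest::importance(rf, type = 1, scale = TRUE)[, 1]
    shadow_max <- max(imp[names(shadow)])
    for (p in live) {
      zhist[[p]] <- c(zhist[[p]], imp[[p]])
      hits[p] <- hits[p] + as.integer(imp[[p]] > shadow_max)
      iters[p] <- iters[p] + 1L
    }
    undecided <- names(decision)[decision == "tentative"]
    for (p in undecided) {
      p_hi <- stats::pbinom(hits[p] - 1L, iters[p], 0.5,
                            lower.tail = FALSE)
      p_lo <- stats::pbinom(hits[p], iters[p], 0.5)
      if (p_hi < thresh) decision[p] <- "confirmed"
      else if (p_lo < thresh) decision[p] <- "rejected"
    }
    if (!any(decision == "tentative")) break
  }

  imp_tab <- data.frame(
    predictor = preds,
    mean_z = vapply(zhist, function(z) mean(z), numeric(1)),
    min_z = vapply(zhist, function(z) min(z), numeric(1)),
    max_z = vapply(zhist, function(z) max(z), numeric(1)),
    hits = as.integer(hits), iters = as.integer(iters),
    decision = unname(decision), stringsAsFactors = FALSE)
  imp_tab <- imp_tab[order(-imp_tab$mean_z), ]
  rownames(imp_tab) <- NULL

  base_fit <- fit_rf(spec, table)
  structure(list(importance = imp_tab, score = base_fit$score,
                 task = base_fit$task, n = base_fit$n, spec = spec),
            class = "shadow_rank")
}

#' @export
print.shadow_rank <- function(x, ...) {
  lab <- if (x$task == "regression") "% variance explained"
  else "prediction accuracy (%)"
  cat("Shadow-feature importance ranking (", x$task, ", n = ", x$n,
      ")\n  model ", lab, ": ", round(x$score, 2), "\n", sep = "")
  print(transform(x$importance, mean_z = round(mean_z, 2),
                  min_z = round(min_z, 2), max_z = round(max_z, 2)))
  invisible(x)
}

#' Choose between the month and water-temperature model variants
#'
#' Month and water temperature are collinear, so models are fitted with
#' each separately and the higher-scoring variant is reported. Exact ties
#' resolve to the temperature variant.
#'
#' @param spec_base a [model_spec()] whose predictors include neither or
#'   one of `month` / `water_temp_c`; both are tried.
#' @param table data.frame.
#' @param rank also run [shadow_rank()] on the chosen variant.
#' @return list with `choice` (`"month"` or `"water_temp_c"`),
#'   `score_month`, `score_temp`, `fit` (chosen [fit_rf()]), and `ranking`
#'   (when `rank = TRUE`).
#' @export
select_month_or_temp <- function(spec_base, table, rank = FALSE) {
  others <- setdiff(spec_base$predictors, c("month", "water_temp_c"))
  spec_m <- model_spec(spec_base$response, c(others, "month"),
                       spec_base$task, spec_base$n_trees,
                       spec_base$rng_seed, spec_base$alpha)
  spec_t <- model_spec(spec_base$response, c(others, "water_temp_c"),
                       spec_base$task, spec_base$n_trees,
                       spec_base$rng_seed, spec_base$alpha)
  fm <- fit_rf(spec_m, table)
  ft <- fit_rf(spec_t, table)
  choice <- if (fm$score > ft$score) "month" else "water_temp_c"
  chosen_spec <- if (choice == "month") spec_m else spec_t
  list(choice = choice, score_month = fm$score, score_temp = ft$score,
       fit = if (choice == "month") fm else ft,
       ranking = if (rank) shadow_rank(chosen_spec, table) else NULL)
}

#' Dunnett-Tukey-Kramer pairwise multiple comparisons
#'
#' All pairwise group comparisons for unequal sample sizes and unequal
#' variances: each pair uses the Welch standard error and
#' Welch-Satterthwaite degrees of freedom with a studentized-range
#' critical value, giving simultaneous confidence intervals. A pair is
#' significant iff its interval excludes zero.
#'
#' @param values numeric response.
#' @param groups factor (or coercible) of group labels.
#' @param conf simultaneous confidence level.
#' @return object of class `dtk_posthoc`: `table` (pairs with difference,
#'   CI, significance), `means` (group means, decreasing), `conf`.
#' @export
dtk_posthoc <- function(values, groups, conf = 0.95) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- groups[ok]
  lev <- levels(groups)
  k <- length(lev)
  if (k < 2) stop("need at least 2 groups")
  n <- tapply(values, groups, length)
  if (any(n < 2))
    stop("group(s) with fewer than 2 observations: ",
         paste(lev[n < 2], collapse = ", "))
  m <- tapply(values, groups, mean)
  v <- tapply(values, groups, stats::var)

  pairs <- utils::combn(lev, 2)
  rows <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(v[i] / n[i] + v[j] / n[j])
    df <- se^4 / ((v[i] / n[i])^2 / (n[i] - 1) +
                    (v[j] / n[j])^2 / (n[j] - 1))
    q <- stats::qtukey(conf, nmeans = k, df = df) / sqrt(2)
    diff <- m[i] - m[j]
    data.frame(group1 = i, group2 = j, diff = unname(diff),
               lwr = unname(diff - q * se), upr = unname(diff + q * se),
               df = unname(df), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$significant <- tab$lwr > 0 | tab$upr < 0
  structure(list(table = tab, means = sort(m, decreasing = TRUE),
                 n = n, conf = conf),
            class = "dtk_posthoc")
}

#' @export
print.dtk_posthoc <- function(x, ...) {
  cat("Dunnett-Tukey-Kramer pairwise comparisons (",
      100 * x$conf, "% simultaneous CIs)\n", sep = "")
  cat("group means (decreasing): ",
      paste0(names(x$means), " = ", round(x$means, 2),
             collapse = ", "), "\n")
  print(transform(x$table, diff = round(diff, 3), lwr = round(lwr, 3),
                  upr = round(upr, 3), df = round(df, 1)))
  invisible(x)
}

#' Default species season/hour windows for targeted models
#'
#' The calling season and circadian window of each sound producer, used to
#' limit targeted models and reduce collinearity between seasonality and
#' noise presence: black drum March-April 15:00-24:00, oyster toadfish
#' March-June all hours, silver perch March-June 15:00-5:00, spotted
#' seatrout March-September 14:00-2:00, red drum August-October
#' 13:00-20:00, bottlenose dolphins November-February all hours.
#'
#' @return named list with `months` and `hours` per species.
#' @export
species_windows <- function() {
  list(
    black_drum = list(months = 3:4, hours = 15:23),
    oyster_toadfish = list(months = 3:6, hours = 0:23),
    silver_perch = list(months = 3:6, hours = c(15:23, 0:4)),
    spotted_seatrout = list(months = 3:9, hours = c(14:23, 0:1)),
    red_drum = list(months = 8:10, hours = 13:19),
    dolphin = list(months = c(11, 12, 1, 2), hours = 0:23))
}

direction_label <- function(dtk) {
  tab <- dtk$table
  row <- tab[(tab$group1 == "0" & tab$group2 == "1") |
               (tab$group1 == "1" & tab$group2 == "0"), ][1, ]
  d01 <- if (row$group1 == "0") row$diff else -row$diff
  if (!row$significant) "0 = 1" else if (d01 > 0) "0 > 1" else "1 > 0"
}

#' Targeted noise-effect model for one species
#'
#' Restricts the data to the species' calling season and circadian window,
#' optionally re-runs the shadow-feature ranking with noise presence among
#' the predictors, and tests the response against noise presence with the
#' DTK post-hoc, reporting the direction: `"0 > 1"` (response lower when
#' noise present, i.e. suppression), `"1 > 0"` (boost), or `"0 = 1"` (no
#' significant difference). Noise labels follow the annotation convention
#' 0 = no noise, 1 = noise present.
#'
#' @param species a name in `windows` (use `"dolphin"` for the summed
#'   dolphin vocalization count).
#' @param annotations annotation table.
#' @param covariates covariate table from [assemble_covariates()] (must
#'   carry `hour`).
#' @param windows window registry, see [species_windows()].
#' @param rank also run the shadow-feature ranking (slower).
#' @param n_trees,rng_seed,alpha forwarded to [model_spec()].
#' @param conf DTK confidence level.
#' @return object of class `targeted_model`: `species`, `direction`,
#'   `dtk`, `n`, `ranking` (or NULL).
#' @export
targeted_model <- function(species, annotations, covariates,
                           windows = species_windows(), rank = FALSE,
                           n_trees = 500, rng_seed = 42L, alpha = 0.01,
                           conf = 0.95) {
  if (!species %in% names(windows))
    stop("no window registered for species '", species, "'")
  w <- windows[[species]]
  response <- if (species == "dolphin") "dolphin_sum" else species
  df <- merge(annotations, covariates, by = "file_id",
              suffixes = c("", ".cov"))
  df <- df[df$month %in% w$months & df$hour %in% w$hours, , drop = FALSE]
  df <- df[!is.na(df[[response]]) & !is.na(df$noise), , drop = FALSE]
  if (nrow(df) < 50)
    stop("insufficient data for ", species, ": ", nrow(df),
         " rows in the season/hour window (need >= 50)")
  dtk <- dtk_posthoc(df[[response]], factor(df$noise, levels = c(0, 1)),
                     conf = conf)
  ranking <- NULL
  if (rank) {
    preds <- intersect(c("station", "water_temp_c", "lunar_phase",
                         "tidal_phase", "diel", "noise"), names(df))
    df$noise <- factor(df$noise)
    spec <- model_spec(response, preds, n_trees = n_trees,
                       rng_seed = rng_seed, alpha = alpha)
    ranking <- shadow_rank(spec, df)
  }
  structure(list(species = species, direction = direction_label(dtk),
                 dtk = dtk, n = nrow(df), ranking = ranking),
            class = "targeted_model")
}

#' @export
print.targeted_model <- function(x, ...) {
  cat("Targeted noise-effect model: ", x$species, " (n = ", x$n, ")\n",
      "  direction (0 = no noise, 1 = noise present): ", x$direction,
      "\n", sep = "")
  invisible(x)
}

#' Seasonal sound-producer contribution model
#'
#' Within one season and diel stratum, ranks the contribution of each
#' sound producer (fish calling intensities, dolphin vocalization count)
#' and anthropogenic noise to the band SPL via the shadow-feature
#' procedure, then tests each contributor's relationship with a DTK
#' comparison of SPL between files with and without that contributor.
#' Contributors with a significantly negative relationship (lower SPLs
#' when calling occurred) are moved to the removed list — that pattern
#' means the calling did not contribute to the band's sound level. The
#' high-frequency variant uses only dolphins and noise as candidates.
#'
#' @param spl_table band SPL table (single band) with `file_id`, `spl_db`.
#' @param annotations annotation table.
#' @param covariates covariate table (for `season` and `diel`).
#' @param season,diel the stratum.
#' @param band_label `"low"` (fish + dolphins + noise) or `"high"`
#'   (dolphins + noise).
#' @param n_trees,rng_seed,alpha forwarded to the ranking.
#' @param min_rows minimum stratum size; smaller strata are skipped with a
#'   message, returning NULL.
#' @return object of class `contribution_result` or NULL.
#' @export
contribution_model <- function(spl_table, annotations, covariates, season,
                               diel, band_label = c("low", "high"),
                               n_trees = 500, rng_seed = 42L,
                               alpha = 0.01, min_rows = 50) {
  band_label <- match.arg(band_label)
  spl <- spl_table[spl_table$band == band_label, , drop = FALSE]
  df <- merge(spl, annotations, by = "file_id", suffixes = c("", ".ann"))
  df <- merge(df, covariates[, c("file_id", "season", "diel")],
              by = "file_id")
  df <- df[df$season == season & df$diel == diel, , drop = FALSE]
  if (nrow(df) < min_rows) {
    message("stratum ", season, "/", diel, " skipped: ", nrow(df),
            " rows (< ", min_rows, ")")
    return(NULL)
  }
  fish <- intersect(FISH_SPECIES, names(df))
  fish <- fish[vapply(fish, function(cc) length(unique(df[[cc]])) > 1,
                      logical(1))]
  cand <- if (band_label == "low") c(fish, "dolphin_sum", "noise")
  else c("dolphin_sum", "noise")
  cand <- cand[vapply(cand, function(cc) length(unique(df[[cc]])) > 1,
                      logical(1))]
  if (length(cand) == 0) {
    message("stratum ", season, "/", diel,
            " skipped: no variable candidate contributors")
    return(NULL)
  }
  spec <- model_spec("spl_db", cand, task = "regression",
                     n_trees = n_trees, rng_seed = rng_seed,
                     alpha = alpha)
  rk <- shadow_rank(spec, df)

  removed <- character()
  dirs <- stats::setNames(character(length(cand)), cand)
  for (cc in cand) {
    present <- factor(as.integer(df[[cc]] >= 1), levels = c(0, 1))
    if (nlevels(droplevels(present)) < 2 ||
        any(table(present) < 2)) { dirs[cc] <- "0 = 1"; next }
    d <- dtk_posthoc(df$spl_db, present)
    dirs[cc] <- direction_label(d)
    if (dirs[cc] == "0 > 1") removed <- c(removed, cc)
  }
  ranked <- rk$importance[!rk$importance$predictor %in% removed, ,
                          drop = FALSE]
  structure(list(season = season, diel = diel, band = band_label,
                 ranked = ranked, removed = removed,
                 directions = dirs, score = rk$score, n = nrow(df)),
            class = "contribution_result")
}

#' @export
print.contribution_result <- function(x, ...) {
  cat("Sound-producer contributions to ", x$band, "-band SPL, ",
      x$season, " ", x$diel, " (n = ", x$n, ")\n", sep = "")
  cat("  % variance explained: ", round(x$score, 2), "\n", sep = "")
  print(x$ranked[, c("predictor", "mean_z", "min_z", "max_z",
                     "decision")])
  if (length(x$removed))
    cat("  removed (negative relationship): ",
        paste(x$removed, collapse = ", "), "\n", sep = "")
  invisible(x)
}
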