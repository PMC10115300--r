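make_regression_table <- function(n = 400, seed = 1) {
  set.seed(seed)
  tab <- data.frame(x = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                    n3 = rnorm(n))
  tab$y <- 2 * tab$x + rnorm(n, sd = 0.3)
  tab
}

test_that("model specs enforce their invariants", {
  expect_error(model_spec("y", character(0)), "non-empty")
  expect_error(model_spec("y", c("month", "water_temp_c", "station")),
               "month and water_temp_c")
  expect_silent(model_spec("y", c("month", "station")))
})

test_that("OOB scores track signal strength in regression", {
  # response exactly equal to one predictor: high variance explained
  # over 5 seeds despite three pure-noise predictors
  for (seed in 1:5) {
    tab <- make_regression_table(500, seed = seed)
    tab$y <- tab$x
    fit <- fit_rf(model_spec("y", c("x", "n1", "n2", "n3"),
                             rng_seed = seed), tab)
    expect_equal(fit$task, "regression")
    expect_gt(fit$score, 90)
  }
  # response independent of everything: near-zero (often negative)
  set.seed(99)
  tab <- make_regression_table(500, seed = 99)
  tab$y <- rnorm(500)
  fit0 <- fit_rf(model_spec("y", c("x", "n1", "n2", "n3")), tab)
  expect_lte(fit0$score, 10)
})

test_that("classification accuracy is 100 - OOB error", {
  set.seed(6)
  n <- 300
  tab <- data.frame(x = c(rnorm(n / 2, -4), rnorm(n / 2, 4)),
                    junk = rnorm(n),
                    cls = factor(rep(c("a", "b"), each = n / 2)))
  fit <- fit_rf(model_spec("cls", c("x", "junk")), tab)
  expect_equal(fit$task, "classification")
  expect_gte(fit$score, 99)
  expect_equal(fit$score,
               100 * (1 - fit$model$err.rate[fit$spec$n_trees, "OOB"]))
})

test_that("degenerate and undersized inputs are refused", {
  tab <- make_regression_table(100)
  tab$y <- 1
  expect_error(fit_rf(model_spec("y", "x"), tab), "constant")
  expect_error(fit_rf(model_spec("y", "x"), tab[1:10, ]),
               "insufficient")
  expect_error(fit_rf(model_spec("y", c("x", "absent")), tab),
               "missing column")
})

test_that("fits are deterministic under the spec seed", {
  tab <- make_regression_table(300)
  spec <- model_spec("y", c("x", "n1"), rng_seed = 7)
  expect_identical(fit_rf(spec, tab)$score, fit_rf(spec, tab)$score)
  r1 <- shadow_rank(spec, tab, max_iter = 12)
  r2 <- shadow_rank(spec, tab, max_iter = 12)
  expect_identical(r1$importance, r2$importance)
})

test_that("shadow ranking separates signal from noise predictors", {
  # sized where shadow selection is well behaved (see methods vignette)
  set.seed(3)
  n <- 800
  tab <- data.frame(x = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                    n3 = rnorm(n))
  tab$y <- 2 * tab$x + rnorm(n, sd = 0.3)
  r <- shadow_rank(model_spec("y", c("x", "n1", "n2", "n3"),
                              n_trees = 150), tab)
  imp <- r$importance
  expect_equal(imp$decision[imp$predictor == "x"], "confirmed")
  expect_true(all(imp$decision[imp$predictor != "x"] == "rejected"))
  expect_equal(imp$predictor[1], "x")  # ranked first by mean Z
  expect_true(all(imp$min_z <= imp$mean_z & imp$mean_z <= imp$max_z))
  # decisions partition the predictor set
  expect_setequal(imp$predictor, c("x", "n1", "n2", "n3"))
})

test_that("a duplicated informative predictor is confirmed twice", {
  tab <- make_regression_table(300, seed = 4)
  tab$x2 <- tab$x
  r <- shadow_rank(model_spec("y", c("x", "x2", "n1")), tab)
  dec <- with(r$importance, setNames(decision, predictor))
  expect_equal(unname(dec[c("x", "x2")]), c("confirmed", "confirmed"))
})

test_that("undecided predictors come back tentative at max_iter", {
  tab <- make_regression_table(200, seed = 5)
  tab$weak <- tab$y + rnorm(200, sd = 20)  # borderline signal
  r <- shadow_rank(model_spec("y", c("x", "weak", "n1")), tab,
                   max_iter = 2)
  expect_true(all(r$importance$decision %in%
                    c("confirmed", "rejected", "tentative")))
  expect_true(any(r$importance$decision == "tentative"))
})

test_that("month/temperature selection follows the built signal", {
  set.seed(10)
  n <- 600
  base <- data.frame(
    month = sample(1:12, n, replace = TRUE),
    station = factor(sample(c("a", "b"), n, replace = TRUE)))
  base$water_temp_c <- 15 - 10 * cospi(2 * (base$month - 1) / 12) +
    rnorm(n, sd = 0.5)
  # response driven by temperature alone (smooth)
  t1 <- base
  t1$y <- 0.8 * t1$water_temp_c + rnorm(n, sd = 0.5)
  s1 <- select_month_or_temp(model_spec("y", "station"), t1)
  expect_equal(s1$choice, "water_temp_c")
  # response is a month-indexed step function decoupled from temperature
  t2 <- base
  t2$water_temp_c <- rnorm(n, 20)
  t2$y <- c(5, -3, 8, 0, 2, -7, 4, 1, -2, 6, -5, 3)[t2$month] +
    rnorm(n, sd = 0.3)
  s2 <- select_month_or_temp(model_spec("y", "station"), t2)
  expect_equal(s2$choice, "month")
  # exact tie resolves to the temperature variant
  t3 <- base
  t3$month <- t3$water_temp_c <- rnorm(n)  # identical columns
  t3$y <- t3$month + rnorm(n, sd = 0.2)
  s3 <- select_month_or_temp(model_spec("y", "station"), t3)
  expect_equal(s3$score_month, s3$score_temp)
  expect_equal(s3$choice, "water_temp_c")
})

test_that("DTK intervals match direct studentized-range computation", {
  set.seed(20)
  a <- rnorm(30, 5, 2); b <- rnorm(40, 6, 2); c_ <- rnorm(25, 9, 2)
  d <- dtk_posthoc(c(a, b, c_), rep(c("a", "b", "c"), c(30, 40, 25)))
  # independent oracle: recompute each pair from group summaries
  groups <- list(a = a, b = b, c = c_)
  for (r in seq_len(nrow(d$table))) {
    g1 <- groups[[d$table$group1[r]]]
    g2 <- groups[[d$table$group2[r]]]
    se <- sqrt(var(g1) / length(g1) + var(g2) / length(g2))
    df <- se^4 / ((var(g1) / length(g1))^2 / (length(g1) - 1) +
                    (var(g2) / length(g2))^2 / (length(g2) - 1))
    q <- qtukey(0.95, 3, df) / sqrt(2)
    expect_equal(d$table$diff[r], mean(g1) - mean(g2), tolerance = 1e-6)
    expect_equal(d$table$lwr[r], mean(g1) - mean(g2) - q * se,
                 tolerance = 1e-6)
    expect_equal(d$table$upr[r], mean(g1) - mean(g2) + q * se,
                 tolerance = 1e-6)
  }
  # significance iff the interval excludes zero
  expect_equal(d$table$significant, d$table$lwr > 0 | d$table$upr < 0)
})

test_that("DTK basics: identical groups accept, separated groups reject", {
  set.seed(21)
  x <- rnorm(50)
  d0 <- dtk_posthoc(c(x, x), rep(c("g1", "g2"), each = 50))
  expect_false(d0$table$significant)
  expect_true(d0$table$lwr <= 0 & d0$table$upr >= 0)
  y <- rnorm(50) + 10
  d1 <- dtk_posthoc(c(x, y), rep(c("g1", "g2"), each = 50))
  expect_true(d1$table$significant)
  expect_lt(d1$table$diff, 0)
  expect_equal(names(d1$means)[1], "g2")  # ordered by group mean
  expect_error(dtk_posthoc(c(1, 2, 3), c("a", "a", "b")), "fewer than 2")
  expect_error(dtk_posthoc(rnorm(10), rep("a", 10)), "at least 2")
})

test_that("targeted models need enough in-window data", {
  sc <- tiny_scene(days = 2, rng_seed = 40)
  truth <- simulate_events(sc)
  ann <- hourly_subsample(export_truth_annotations(truth))
  cov <- scene_covariates(truth)
  cov <- cov[cov$file_id %in% ann$file_id, ]
  # red drum window is Aug-Oct: an April scene has no rows
  expect_error(targeted_model("red_drum", ann, cov), "insufficient")
  expect_error(targeted_model("kraken", ann, cov), "no window")
})

test_that("contribution model ranks the planted SPL driver first", {
  # stratum where only seatrout events raise the low-band SPL
  set.seed(30)
  n <- 240
  a <- annotation_frame(n)
  a$spotted_seatrout <- sample(0:3, n, replace = TRUE)
  a$silver_perch <- sample(0:1, n, replace = TRUE)
  a$dolphin_sum <- rpois(n, 0.5)
  a$noise <- 0L
  spl <- data.frame(file_id = a$file_id, band = "low",
                    spl_db = 95 + 4 * a$spotted_seatrout + rnorm(n, 0.5),
                    stringsAsFactors = FALSE)
  cov <- data.frame(file_id = a$file_id, season = "spring", diel = "night",
                    stringsAsFactors = FALSE)
  cm <- contribution_model(spl, a, cov, "spring", "night",
                           n_trees = 150)
  expect_s3_class(cm, "contribution_result")
  expect_equal(cm$ranked$predictor[1], "spotted_seatrout")
  expect_equal(cm$ranked$decision[1], "confirmed")
  expect_false("spotted_seatrout" %in% cm$removed)

  # a contributor that only suppresses (lower SPL when present) is removed
  a2 <- a
  a2$silver_perch <- as.integer(spl$spl_db <
                                  stats::median(spl$spl_db))
  cm2 <- contribution_model(spl, a2, cov, "spring", "night",
                            n_trees = 150)
  expect_true("silver_perch" %in% cm2$removed)
  expect_false("silver_perch" %in% cm2$ranked$predictor)

  # empty stratum is skipped with a message
  expect_message(
    out <- contribution_model(spl, a, cov, "winter", "day",
                              n_trees = 150),
    "skipped")
  expect_null(out)
})
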