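test_that("regression metrics match hand computations", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(m$mae, m$rmse, m$r2), c(0, 0, 1))

  m <- regression_metrics(c(1, 1), c(0, 2))
  expect_equal(c(m$mae, m$rmse, m$r2), c(1, 1, 0))

  # constant wrong prediction: SSres = 16 + 4 = 20, SStot = 2 -> R2 = -9
  m <- regression_metrics(c(4, 4), c(0, 2))
  expect_equal(m$mae, 3)
  expect_equal(m$rmse, sqrt(10))
  expect_equal(m$r2, -9)

  expect_error(regression_metrics(1:3, 1:4), "length")
  expect_warning(m <- regression_metrics(c(1, 2), c(5, 5)),
                 class = "farrowcast_r2_undefined")
  expect_true(is.na(m$r2))
})

test_that("RMSE never falls below MAE", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(2:50, 1)
    m <- regression_metrics(rnorm(n, sd = 10), rnorm(n, sd = 10))
    expect_gte(m$rmse, m$mae)
  }
})

test_that("Pearson correlation behaves at its boundary cases", {
  set.seed(10)
  x <- rnorm(30)
  expect_equal(pcc(x, x), 1)
  expect_equal(pcc(x, -x), -1)
  expect_equal(pcc(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_error(pcc(x, rep(1, 30)), class = "farrowcast_constant_series")
})

test_that("cohort correlation matrix is symmetric with unit diagonal", {
  cohort <- simulate_cohort(tiny_sim_config())
  m <- activity_pcc(cohort)
  expect_equal(dim(m), c(6L, 6L))
  expect_equal(diag(m), setNames(rep(1, 6), unique(cohort$sow_id)))
  expect_equal(m, t(m))
  expect_true(all(m >= -1 & m <= 1))
})

test_that("stronger individual bout variance lowers cross-sow correlation", {
  mean_off <- function(bsd) {
    co <- simulate_cohort(sim_config(n_sows = 8, bout_sd = bsd, seed = 21))
    m <- activity_pcc(co)
    mean(m[upper.tri(m)])
  }
  expect_gt(mean_off(1), mean_off(12))
})

test_that("AACC averages off-diagonal correlations per subject", {
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- 0.5
  m[1, 3] <- m[3, 1] <- 0.5
  m[2, 3] <- m[3, 2] <- 1
  a <- aacc(m)
  expect_equal(a$aacc, c(0.5, 0.75, 0.75))
  expect_equal(aacc(matrix(1, 4, 4))$aacc, rep(1, 4))
  expect_equal(aacc(diag(4))$aacc, rep(0, 4))
  # literal-N mode divides by the total subject count instead
  expect_equal(aacc(matrix(1, 4, 4), denominator = "all")$aacc, rep(3 / 4, 4))
  expect_error(aacc(matrix(1, 2, 3)), "square")
})

test_that("STL reconstructs its input exactly and isolates the trend", {
  # pure sinusoid: the seasonal component absorbs the cycle
  x <- 10 + 5 * sin(2 * pi * seq_len(288) / 48)
  dec <- stl_trend(x, period = 48)
  expect_equal(dec$trend + dec$seasonal + dec$remainder, dec$value,
               tolerance = 1e-10)
  expect_lt(max(abs(dec$trend - 10)), 0.5)

  # linear ramp with a seasonal cycle: trend tracks the least-squares line
  y <- seq(0, 20, length.out = 288) + 3 * sin(2 * pi * seq_len(288) / 48)
  dec2 <- stl_trend(y, period = 48)
  line <- fitted(lm(dec2$value - 3 * sin(2 * pi * seq_len(288) / 48) ~ seq_len(288)))
  expect_lt(mean(abs(dec2$trend - line)), 0.6)

  expect_error(stl_trend(rnorm(50), period = 48), "2 periods")
})

test_that("STL trend of the default cohort rises over the final day", {
  cohort <- simulate_cohort(sim_config(n_sows = 6, seed = 2))
  rising <- vapply(split(cohort, cohort$sow_id), function(d) {
    tr <- stl_trend(d$activity, period = 288)$trend
    tail(tr, 1) - tr[length(tr) - 288]
  }, numeric(1))
  expect_true(all(rising > 0))
})

test_that("daily statistics use linear-interpolation quartiles", {
  s <- daily_stats(rep(7, 288 * 2), block_points = 288)
  expect_equal(nrow(s), 2L)
  expect_true(all(s$mean == 7 & s$min == 7 & s$max == 7 &
                    s$q1 == 7 & s$q2 == 7 & s$q3 == 7 & s$sd == 0))

  s2 <- daily_stats(as.numeric(1:288), block_points = 288)
  expect_equal(s2$q2, 144.5)
  expect_equal(s2$q1, unname(quantile(1:288, 0.25)))
  expect_gte(s2$q3 - s2$q1, 0)
  expect_error(daily_stats(rnorm(300), block_points = 288), "multiple")
})

test_that("interval report bins agree with global metrics", {
  set.seed(11)
  labels <- seq(0, 1795, by = 5)
  preds <- labels + rnorm(length(labels), sd = 30)
  rep_all <- interval_report(tibble::tibble(label = labels, prediction = preds))
  expect_s3_class(rep_all, "interval_report")
  expect_equal(nrow(rep_all), 5L)
  expect_equal(sum(rep_all$n), length(labels))
  expect_false(any(rep_all$empty))

  # perfect predictions: every bin has MAE 0 and R2 1
  perf <- interval_report(tibble::tibble(label = labels, prediction = labels))
  expect_true(all(perf$mae == 0))
  expect_true(all(perf$r2 == 1))

  # a single full-range bin reproduces regression_metrics exactly
  one <- interval_report(tibble::tibble(label = labels, prediction = preds),
                         breaks_hours = c(30, 0))
  glob <- regression_metrics(preds, labels)
  expect_equal(one$mae, glob$mae)
  expect_equal(one$rmse, glob$rmse)
  expect_equal(one$r2, glob$r2)

  # empty bins are flagged, not dropped
  sub <- interval_report(tibble::tibble(label = labels[labels < 360],
                                        prediction = preds[labels < 360]))
  expect_true(sub$empty[sub$interval == "30-24 h"])
  expect_true(is.na(sub$mae[sub$empty][1]))
})

test_that("a constant-mean predictor shows the far-bin negative-R2 pattern", {
  cohort <- simulate_cohort(sim_config(n_sows = 2, seed = 4))
  windows <- make_windows(cohort, w = 72, step = 4)
  windows <- windows[windows$label <= 1800, ]
  preds <- tibble::tibble(label = windows$label,
                          prediction = mean(windows$label))
  rep <- interval_report(preds)
  expect_lt(rep$r2[rep$interval == "30-24 h"], 0)
  expect_lt(rep$r2[rep$interval == "6-0 h"], 0)
})

test_that("ROI calculator implements benefit and cost combinations", {
  r <- roi_calc(1, 100, 0, 20, 25, 25)
  expect_equal(r$b_piglets, 100)
  expect_equal(r$total_cost, 50)
  expect_equal(r$roi_pct, 100)

  expect_equal(roi_calc(0.5, 100, 0, 0, 25, 25)$roi_pct, 0)  # benefit == cost
  expect_equal(roi_calc(0, 0, 0, 0, 40, 10)$roi_pct, -100)
  expect_equal(roi_calc(1, 60, 2, 15, 5, 9,
                        cost_combine = "product")$total_cost, 45)
  expect_equal(roi_calc(1, 60, 2, 15, 5, 9, cost_combine = "product")$roi_pct,
               (60 + 30 - 45) / 45 * 100)
  expect_error(roi_calc(1, 1, 1, 1, 0, 0), "positive")
  expect_error(roi_calc(-1, 1, 1, 1, 1, 1), "delta_piglets")
})
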