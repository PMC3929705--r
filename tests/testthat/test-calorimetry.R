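test_that("Weir equation matches hand-computed values and is linear", {
  expect_equal(weir_ee(0, 0), 0)
  expect_equal(weir_ee(1, 1), 5.047)
  expect_equal(weir_ee(1, 0.7), 4.7152)
  # linearity/homogeneity
  a <- c(0.3, 0.12); b <- c(1.1, 0.74)
  expect_equal(weir_ee(a[1] + b[1], a[2] + b[2]),
               weir_ee(a[1], a[2]) + weir_ee(b[1], b[2]))
  expect_equal(weir_ee(2 * a[1], 2 * a[2]), 2 * weir_ee(a[1], a[2]))
  expect_error(weir_ee(-1, 0), "negative_gas")
})

test_that("flat traces give equal phase EE and resting equal to total", {
  n <- 960  # one day at 90 s
  tr <- make_trace(rep(80, n), rep(72, n))
  b <- summarize_trace(tr)
  expect_equal(b$ee_dark, b$ee_light)
  expect_equal(b$ee_dark + b$ee_light, b$ee_24h)
  expect_equal(b$ee_resting, b$ee_24h, tolerance = 1e-12)
  expect_equal(b$rq_24h, 72 / 80)
})

test_that("unit respiratory quotient when VCO2 equals VO2", {
  tr <- make_trace(rep(60, 960))
  b <- summarize_trace(tr)
  expect_equal(b$rq_24h, 1.0)
  expect_equal(b$rq_dark, 1.0)
  expect_equal(b$rq_light, 1.0)
})

test_that("resting EE averages the two lowest 90-s readings over a day", {
  n <- 960
  vo2 <- rep(vo2_for_epoch_kcal(0.02), n)
  vo2[100] <- vo2_for_epoch_kcal(0.008)
  vo2[500] <- vo2_for_epoch_kcal(0.010)
  tr <- make_trace(vo2)
  expect_equal(resting_ee(tr), 0.009 * 960, tolerance = 1e-9)  # 8.64
  # resting can never exceed total
  b <- summarize_trace(tr)
  expect_lte(b$ee_resting, b$ee_24h)
  expect_error(resting_ee(make_trace(c(1, 2), 0)), "bad_window")
})

test_that("resting EE is monotone in pointwise EE changes", {
  base <- rep(vo2_for_epoch_kcal(0.02), 960)
  base[c(10, 700)] <- vo2_for_epoch_kcal(c(0.009, 0.011))
  r0 <- resting_ee(make_trace(base))
  up <- base; up[700] <- up[700] * 1.5  # raise one epoch
  expect_gte(resting_ee(make_trace(up)), r0)
  dn <- base; dn[200] <- vo2_for_epoch_kcal(0.005)  # new global minimum
  expect_lte(resting_ee(make_trace(dn)), r0)
})

test_that("energy balance and phase additivity hold exactly", {
  tsp <- trace_spec(duration_h = 48, noise_cv = 0.08, seed = 14)
  tr <- simulate_clams_trace(tsp, truth_ee_kcal_d = 10.5,
                             truth_intake_kcal_d = 11.4)
  b <- summarize_trace(tr)
  expect_identical(b$balance_kcal_d, b$intake_kcal_d - b$ee_24h)
  expect_equal(b$ee_dark + b$ee_light, b$ee_24h, tolerance = 1e-12)
  expect_equal(b$intake_kcal_d, 11.4, tolerance = 1e-9)
})

test_that("noiseless simulated traces are recovered to within 0.1%", {
  tsp <- trace_spec(duration_h = 72, noise_cv = 0, seed = 8)
  tr <- simulate_clams_trace(tsp, truth_ee_kcal_d = 10.5)
  b <- summarize_trace(tr)
  expect_lt(abs(b$ee_24h - 10.5) / 10.5, 1e-3)
  expect_lt(abs(b$intake_kcal_d - 10.5) / 10.5, 1e-3)
  expect_equal(b$balance_kcal_d, b$intake_kcal_d - b$ee_24h)
  expect_lte(b$ee_resting, b$ee_24h)
  expect_gt(b$ee_dark, b$ee_light)  # circadian structure present
})

test_that("windows must span whole days within the trace", {
  tr <- make_trace(rep(50, 2 * 960))
  t0 <- tr$timestamp[1]
  expect_error(summarize_trace(tr, window = c(t0, t0 + 3600)),
               "integer number of 24-h days")
  expect_error(summarize_trace(tr, window = c(t0, t0 + 5 * 86400)),
               "bad_window")
  b <- summarize_trace(tr, window = c(t0, t0 + 86400))
  expect_equal(b$ee_24h, summarize_trace(tr)$ee_24h)
})

test_that("unflagged feeder refills are rejected, flagged ones accepted", {
  tr <- make_trace(rep(50, 960))
  tr$feeder_g <- seq(50, 45, length.out = 960)
  tr$feeder_g[500:960] <- tr$feeder_g[500:960] + 20  # refill jump
  expect_error(summarize_trace(tr), "unflagged_refill")
  tr$refill[500] <- 1L
  expect_silent(summarize_trace(tr))
})

test_that("activity summaries split counts by phase and axis", {
  tr <- make_trace(rep(50, 960))
  zero <- summarize_activity(tr)
  expect_true(all(unlist(zero) == 0))

  hour <- as.numeric(format(tr$timestamp, "%H"))
  dark <- hour >= 18 | hour < 6
  tr$x_counts <- ifelse(dark, 7L, 0L)
  tr$z_counts <- ifelse(dark, 0L, 2L)
  act <- summarize_activity(tr)
  expect_equal(act$activity_dark_x, sum(dark) * 7)
  expect_equal(act$activity_light_x, 0)
  expect_equal(act$activity_dark_z, 0)
  expect_equal(act$activity_light_z, sum(!dark) * 2)
  expect_equal(act$activity_total, sum(dark) * 7 + sum(!dark) * 2)
})

test_that("mdx-style parameterization shows reduced dark-phase rearing", {
  # lower burst rates stand in for the hypoactive dystrophic phenotype
  quiet <- trace_spec(duration_h = 48, activity_burst_rate_dark = 3,
                      seed = 31)
  lively <- trace_spec(duration_h = 48, activity_burst_rate_dark = 9,
                       seed = 31)
  act_mdx <- summarize_activity(simulate_clams_trace(quiet, 11))
  act_ctl <- summarize_activity(simulate_clams_trace(lively, 10.5))
  expect_lt(act_mdx$activity_dark_z, act_ctl$activity_dark_z)
})
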