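test_that("cohort generator is deterministic and honors degenerate noise", {
  groups <- data.frame(genotype = c("mdx", "control"),
                       age_group = "juvenile", n = c(3, 3))
  params <- expand.grid(genotype = c("mdx", "control"),
                        age_group = "juvenile",
                        variable = c("weight_g", "ffm_g"),
                        stringsAsFactors = FALSE)
  params$mean <- c(16.5, 21, 14.6, 18)
  params$sd <- 0
  spec <- cohort_spec(groups, params, seed = 11)

  cohort <- simulate_cohort(spec)
  expect_equal(nrow(cohort), 6)
  expect_equal(cohort$weight_g, c(16.5, 16.5, 16.5, 21, 21, 21))
  expect_equal(cohort$ffm_g, c(14.6, 14.6, 14.6, 18, 18, 18))

  params$sd <- c(2, 2, 1.2, 1.2, 1, 1, 0.9, 0.9)[seq_len(nrow(params))]
  spec2 <- cohort_spec(groups, params, seed = 11)
  expect_identical(simulate_cohort(spec2), simulate_cohort(spec2))
  expect_false(identical(simulate_cohort(spec2),
                         simulate_cohort(cohort_spec(groups, params,
                                                     seed = 12))))
})

test_that("invalid group labels are rejected", {
  groups <- data.frame(genotype = "wild", age_group = "juvenile", n = 2)
  params <- data.frame(genotype = "wild", age_group = "juvenile",
                       variable = "weight_g", mean = 20, sd = 1)
  expect_error(cohort_spec(groups, params), "unknown genotype")
  groups2 <- data.frame(genotype = "mdx", age_group = "elderly", n = 2)
  expect_error(cohort_spec(groups2, params), "unknown age_group")
})

test_that("group sample means converge to the specified means", {
  # juvenile mdx body weight 16.5 g (SE 0.7, n = 8 -> SD 1.98)
  spec <- default_cohort_spec(seed = 42,
                              n_per_group = c(10000, 1, 1, 1))
  cohort <- simulate_cohort(spec)
  juv <- cohort[cohort$genotype == "mdx" & cohort$age_group == "juvenile", ]
  sd_w <- 0.7 * sqrt(8)
  expect_lt(abs(mean(juv$weight_g) - 16.5), 3 * sd_w / sqrt(10000))
  # the latent size factor leaves the mean unbiased but couples variables
  expect_gt(cor(juv$ffm_g, juv$body_length_mm), 0.9)
})

test_that("enlarging the cohort does not perturb existing animals", {
  small <- simulate_cohort(default_cohort_spec(seed = 5,
                                               n_per_group = c(4, 1, 1, 1)))
  big <- simulate_cohort(default_cohort_spec(seed = 5,
                                             n_per_group = c(9, 1, 1, 1)))
  expect_equal(small[1:4, ], big[1:4, ])
})

test_that("trace simulator recovers the target energy expenditure", {
  flat <- trace_spec(duration_h = 24, circadian_amplitude = 0,
                     activity_burst_rate_dark = 0,
                     activity_burst_rate_light = 0, noise_cv = 0,
                     rq_dark = 0.9, rq_light = 0.9)
  tr <- simulate_clams_trace(flat, truth_ee_kcal_d = 10)
  b <- summarize_trace(tr)
  expect_equal(b$ee_24h, 10, tolerance = 1e-9)
  expect_equal(b$ee_dark, 5, tolerance = 1e-6)
  expect_equal(b$ee_light, 5, tolerance = 1e-6)

  wavy <- trace_spec(duration_h = 72, circadian_amplitude = 0.2,
                     noise_cv = 0, seed = 3)
  tr2 <- simulate_clams_trace(wavy, truth_ee_kcal_d = 11.0)
  b2 <- summarize_trace(tr2)
  expect_equal(b2$ee_24h, 11.0, tolerance = 0.01 / 11)

  # circadian modulation: dark-phase VO2 exceeds light-phase VO2
  hour <- as.numeric(format(tr2$timestamp, "%H"))
  dark <- hour >= 18 | hour < 6
  expect_gt(mean(tr2$vo2_ml_h[dark]), mean(tr2$vo2_ml_h[!dark]))
})

test_that("trace epoch must divide the day", {
  expect_error(trace_spec(epoch_s = 7), "divide 86400")
  expect_error(simulate_clams_trace(trace_spec(), truth_ee_kcal_d = -1),
               "must be > 0")
})

test_that("tracer plateau simulation inverts the flux estimators", {
  truth <- tracer_truth(300, 80, 0.17)
  enr <- simulate_tracer_plateau(truth)
  est <- estimate_fluxes(enr)
  expect_equal(est$ra_phe, 300, tolerance = 1e-12)
  expect_equal(est$ra_tyr, 80, tolerance = 1e-12)
  expect_equal(est$hydroxylation_fraction, 0.17, tolerance = 1e-12)

  # matched convention flags still round-trip
  enr2 <- simulate_tracer_plateau(truth, convention = "total",
                                  thompson_correction = FALSE)
  est2 <- estimate_fluxes(enr2, convention = "total", correction = FALSE)
  expect_equal(est2$ra_phe, 300, tolerance = 1e-12)
  expect_equal(est2$hydroxylation_fraction, 0.17, tolerance = 1e-12)

  # no conversion -> no label transfer
  none <- simulate_tracer_plateau(tracer_truth(300, 80, 0))
  expect_equal(none$e_d4_tyr_mpe, 0)

  expect_error(tracer_truth(300, 80, 1.2), "in \\[0, 1\\]")
})

test_that("noisy tracer estimates are unbiased and average like 1/sqrt(N)", {
  truth <- tracer_truth(300, 80, 0.17, enrichment_noise_cv = 0.05,
                        seed = 9)
  enr <- simulate_tracer_plateau(truth, n = 1000)
  est <- estimate_fluxes(enr)
  expect_lt(abs(mean(est$ra_phe) - 300) / 300, 0.01)
  expect_lt(abs(mean(est$hydroxylation_fraction) - 0.17) / 0.17, 0.01)

  # SE of the N-replicate mean scales as cv/sqrt(N): block means of 40
  # vs 160 replicates should have SDs in ratio ~2
  enr_big <- simulate_tracer_plateau(
    tracer_truth(300, 80, 0.17, enrichment_noise_cv = 0.05, seed = 10),
    n = 4800)
  ra <- estimate_fluxes(enr_big)$ra_phe
  sd40 <- sd(colMeans(matrix(ra, nrow = 40)))
  sd160 <- sd(colMeans(matrix(ra, nrow = 160)))
  expect_gt(sd40 / sd160, 1.5)
  expect_lt(sd40 / sd160, 2.7)
})

test_that("flooding-dose simulation inverts the FSR estimator", {
  truth <- flooding_truth(fsr_true_tp = 31.1, fsr_true_mp = 24.7,
                          s_a = 1, t_label = 15)
  fl <- simulate_flooding_dose(truth)
  # S_B = S_A x (FSR/100) x t/1440 = 0.311 x 15/1440
  expect_equal(fl$s_b_tp, 0.311 * 15 / 1440, tolerance = 1e-12)
  expect_equal(fsr(fl$s_b_tp, fl$s_a_tissue, fl$t_label_min), 31.1,
               tolerance = 1e-12)
  expect_equal(fsr(fl$s_b_mp, fl$s_a_tissue, fl$t_label_min), 24.7,
               tolerance = 1e-12)

  zero <- simulate_flooding_dose(flooding_truth(fsr_true_tp = 0,
                                                fsr_true_mp = 0))
  expect_equal(zero$s_b_tp, 0)
  expect_error(flooding_truth(t_label = 0), "t_label")
})

test_that("noisy flooding round trip is unbiased", {
  truth <- flooding_truth(fsr_true_tp = 31.1, fsr_true_mp = 24.7,
                          noise_cv = 0.05, seed = 21)
  fl <- simulate_flooding_dose(truth, n = 1000)
  res <- summarize_flooding(fl)
  expect_lt(abs(mean(res$fsr_tp) - 31.1) / 31.1, 0.01)
  expect_lt(abs(mean(res$fsr_mp) - 24.7) / 24.7, 0.01)
})
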