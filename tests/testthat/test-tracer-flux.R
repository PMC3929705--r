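test_that("steady-state Ra follows isotope dilution", {
  expect_equal(ra_steady_state(16, 50), 16)        # 1:1 dilution
  expect_equal(ra_steady_state(16, 4), 384)        # 16 x (25 - 1)
  expect_equal(ra_steady_state(11, 10), 99)
  expect_equal(ra_steady_state(16, 4, convention = "total"), 400)
  # strictly decreasing in enrichment
  e <- seq(1, 99, by = 7)
  expect_true(all(diff(ra_steady_state(16, e)) < 0))
  expect_error(ra_steady_state(16, 0), "bad_enrichment")
  expect_error(ra_steady_state(16, 100), "bad_enrichment")
  expect_error(ra_steady_state(0, 50), "bad_infusion")
})

test_that("hydroxylation flux behaves as specified", {
  expect_equal(hydroxylation_flux(80, 0, 5, 16, 300), 0)
  on <- hydroxylation_flux(80, 0.2, 5, 16, 300, correction = TRUE)
  off <- hydroxylation_flux(80, 0.2, 5, 16, 300, correction = FALSE)
  expect_equal(on / off, (16 + 300) / 16)
  expect_error(hydroxylation_flux(80, 60, 5, 16, 30),
               "inconsistent_enrichments")
  expect_error(hydroxylation_flux(80, -1, 5, 16, 300), "bad_enrichment")
})

test_that("flux partition conserves phenylalanine and converts units", {
  res <- partition_flux(100, 17)
  expect_equal(res$ps_phe, 83)
  expect_equal(res$net_balance, -17)
  expect_equal(res$hydroxylation_fraction, 0.17)
  # protein units: umol/kg/h x 165.19 g/mol / 4% -> g protein/kg/h
  expect_equal(res$protein_breakdown, 100 * 165.19 / 0.04 / 1e6)
  expect_equal(res$protein_balance, -res$protein_breakdown * 0.17)

  # q_pt = 0: full recycling, zero balance
  res0 <- partition_flux(250, 0)
  expect_equal(res0$ps_phe, 250)
  expect_equal(res0$net_balance, 0)

  # conservation identity over random valid inputs
  set.seed(77)
  ra <- runif(50, 50, 500)
  q <- ra * runif(50)
  res_all <- partition_flux(ra, q)
  expect_equal(res_all$ps_phe + res_all$q_pt, res_all$ra_phe,
               tolerance = 1e-12)
  expect_error(partition_flux(100, 120), "bad_flux")
})

test_that("hydroxylation fraction is invariant under flux rescaling", {
  for (s in c(0.5, 1, 3)) {
    enr <- simulate_tracer_plateau(
      tracer_truth(300 * s, 80 * s, 0.17, i_phe = 16 * s, i_tyr = 11 * s))
    est <- estimate_fluxes(enr, protocol = tracer_protocol(
      i_phe = 16 * s, i_tyr = 11 * s))
    expect_equal(est$hydroxylation_fraction, 0.17, tolerance = 1e-12)
  }
})

test_that("noiseless round trip reaches machine precision", {
  for (corr in c(TRUE, FALSE)) {
    enr <- simulate_tracer_plateau(tracer_truth(420, 110, 0.23),
                                   thompson_correction = corr)
    est <- estimate_fluxes(enr, correction = corr)
    expect_lt(abs(est$ra_phe - 420) / 420, 1e-9)
    expect_lt(abs(est$ra_tyr - 110) / 110, 1e-9)
    expect_lt(abs(est$hydroxylation_fraction - 0.23) / 0.23, 1e-9)
  }
})

test_that("sub-floor enrichments are treated as missing, not zero", {
  enr <- simulate_tracer_plateau(tracer_truth(300, 80, 0.17), n = 3)
  enr$e_d5_phe_mpe[2] <- 0.01  # below the 0.05 mpe floor
  expect_message(est <- estimate_fluxes(enr), "enrichment floor")
  expect_equal(nrow(est), 2)
  expect_setequal(est$animal_id, c("T001", "T003"))
  # an exact zero d4-tyr is a valid no-conversion observation
  none <- simulate_tracer_plateau(tracer_truth(300, 80, 0))
  expect_equal(estimate_fluxes(none)$q_pt, 0)
})

test_that("default protocol matches the infusion design", {
  p <- tracer_protocol()
  expect_equal(p$i_phe, 16)
  expect_equal(p$i_tyr, 11)
  expect_equal(p$phe_protein_content, 0.04)
  expect_error(tracer_protocol(phe_protein_content = 0.5), "bad_protocol")
})
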