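test_that("control subtraction removes shared drift", {
  t_s <- seq(0, 7200, 30)
  ctrl <- plate_trace(t_s, 0.8 - 0.03 * t_s / 3600, is_control = TRUE)
  # control identical to sample: flat zero
  same <- subtract_control(plate_trace(t_s, ctrl$a340, enzyme_conc = 4), ctrl)
  expect_true(all(abs(same$a340) < 1e-12))
  expect_false(same$is_control)

  # sample slope -0.30/hr, control slope -0.03/hr -> corrected -0.27/hr
  smp <- plate_trace(t_s, 0.8 - 0.30 * t_s / 3600, enzyme_conc = 4)
  corr <- subtract_control(smp, ctrl)
  slope <- unname(coef(lm(corr$a340 ~ I(t_s / 3600)))[2])
  expect_equal(slope, -0.27, tolerance = 1e-9)
  expect_equal(corr$enzyme_conc, 4)

  # control on a different grid is interpolated
  ctrl2 <- plate_trace(seq(0, 7200, 60), 0.8 - 0.03 * seq(0, 7200, 60) / 3600,
                       is_control = TRUE)
  corr2 <- subtract_control(smp, ctrl2)
  expect_equal(corr2$a340, corr$a340, tolerance = 1e-9)

  off <- plate_trace(c(10000, 10030), c(1, 1), is_control = TRUE)
  expect_error(subtract_control(smp, off), "overlap")
})

test_that("adp_rate inverts Beer-Lambert at the hand-checked slope", {
  t_s <- seq(0, 7200, 30)
  # slope -0.2715/hr -> 0.2715 / (6220 * 0.248) = 176.0 uM/hr
  tr <- plate_trace(t_s, 0.8 - 0.2715 * t_s / 3600, enzyme_conc = 4)
  rr <- adp_rate(tr)
  expect_lt(abs(rr$adp_rate - 176.0) / 176.0, 0.005)
  expect_gt(rr$r_squared, 0.999999)
  expect_equal(rr$fit_window[1], 300)

  # flat trace -> 0
  expect_equal(adp_rate(plate_trace(t_s, rep(0.8, length(t_s))))$adp_rate, 0)

  # rising trace -> warning, floored at 0
  up <- plate_trace(t_s, 0.8 + 0.05 * t_s / 3600)
  expect_warning(rr_up <- adp_rate(up), "increases")
  expect_equal(rr_up$adp_rate, 0)

  # doubling the light path halves the rate
  r1 <- adp_rate(tr, assay_constants(light_path = 0.248))
  r2 <- adp_rate(tr, assay_constants(light_path = 0.496))
  expect_equal(r2$adp_rate, r1$adp_rate / 2, tolerance = 1e-12)

  # linearity: scaling the corrected absorbance scales the rate
  tr3 <- plate_trace(t_s, 3 * (0.8 - 0.2715 * t_s / 3600))
  expect_equal(adp_rate(tr3)$adp_rate, 3 * rr$adp_rate, tolerance = 1e-9)

  expect_error(adp_rate(plate_trace(t_s, rep(1, length(t_s)),),
                        window = c(7000, 7100)), ">= 10 samples")
})

test_that("specific activity divides rate by enzyme concentration", {
  expect_equal(specific_activity(176, enzyme_conc = 4), 44)
  expect_equal(specific_activity(0, enzyme_conc = 4), 0)
  expect_error(specific_activity(176, enzyme_conc = 0), "> 0")

  t_s <- seq(0, 7200, 30)
  rr <- adp_rate(plate_trace(t_s, 0.8 - 0.2715 * t_s / 3600,
                             enzyme_conc = 4))
  rr <- specific_activity(rr)
  expect_lt(abs(rr$specific_activity - 44), 0.25)
})

test_that("kinetics round trip recovers the preset specific activities", {
  # noiseless, no drift: within 2%
  for (sa in c(7, 15, 27, 43, 44)) {
    sim <- simulate_atpase_trace(kinetic_truth(sa, control_drift = 0,
                                               noise_sd = 0), seed = 1)
    rec <- specific_activity(adp_rate(subtract_control(sim$sample,
                                                       sim$control)))
    expect_lt(abs(rec$specific_activity - sa) / sa, 0.02, label = paste(sa))
  }

  # with drift, at noise_sd = 0.005: within 10%
  sim <- simulate_atpase_trace(kinetic_truth(27, noise_sd = 0.005), seed = 4)
  rec <- specific_activity(adp_rate(subtract_control(sim$sample,
                                                     sim$control)))
  expect_lt(abs(rec$specific_activity - 27) / 27, 0.10)

  # drift alone is removed exactly by subtraction (within 2%)
  sim2 <- simulate_atpase_trace(kinetic_truth(15, control_drift = -0.05,
                                              noise_sd = 0), seed = 1)
  rec2 <- specific_activity(adp_rate(subtract_control(sim2$sample,
                                                      sim2$control)))
  expect_lt(abs(rec2$specific_activity - 15) / 15, 0.02)
})

test_that("specific activity is duration-invariant for linear traces", {
  for (dur in c(1, 2)) {
    sim <- simulate_atpase_trace(kinetic_truth(44, control_drift = 0,
                                               noise_sd = 0),
                                 duration_hr = dur, seed = 1)
    rec <- specific_activity(adp_rate(sim$sample))
    expect_lt(abs(rec$specific_activity - 44) / 44, 0.001)
  }
})

test_that("hyperbolic dose-response recovers K and the saturation dose", {
  d <- c(0, 2, 5, 10, 20, 40, 80)
  y <- 10 * d / (20 + d)
  fit <- dose_response(d, y)
  expect_lt(abs(fit$K - 20) / 20, 0.01)
  expect_lt(abs(fit$saturation_dose - 180) / 180, 0.01)
  expect_lt(abs(fit$plateau - 10) / 10, 0.02)

  # constant responses: plateau = constant, saturation dose 0
  flat <- dose_response(d, rep(5, length(d)))
  expect_equal(flat$plateau, 5)
  expect_equal(flat$saturation_dose, 0)

  # linear model returns the slope for non-plateauing series
  lin <- dose_response(c(1, 2, 3, 4), c(2, 4, 6, 8), model = "linear")
  expect_equal(lin$slope, 2, tolerance = 1e-12)

  expect_error(dose_response(c(1, 2, 3), c(1, 2, 3)), ">= 4 dose levels")
})

test_that("DNA dose series recovers the 40 ug/ml saturation point", {
  doses <- c(0, 1, 2, 5, 10, 20, 40, 60)
  sa <- vapply(seq_along(doses), function(i) {
    truth <- kinetic_truth(dna_stimulation_activity(doses[i]),
                           dna_conc = doses[i])
    sim <- simulate_atpase_trace(truth, seed = 10 + i)
    specific_activity(adp_rate(subtract_control(sim$sample,
                                                sim$control)))$specific_activity
  }, numeric(1))
  fit <- dose_response(doses, sa)
  expect_lt(abs(fit$saturation_dose - 40) / 40, 0.15)
  expect_lt(abs(fit$baseline - 7) / 7, 0.05)
  expect_lt(abs(fit$plateau - 15) / 15, 0.05)
})
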