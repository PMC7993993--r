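test_that("population sampling matches preset moments and is deterministic", {
  p <- population_preset("WT")
  tr <- sample_cell_population(p, 500, seed = 1)
  se <- p$length_sd / sqrt(500)
  expect_lt(abs(mean(tr$length) - 8.0), 3 * se)
  expect_lt(abs(sd(tr$length) - 1.8), 3 * se)
  expect_identical(tr, sample_cell_population(p, 500, seed = 1))
  expect_false(identical(tr$length,
                         sample_cell_population(p, 500, seed = 2)$length))
})

test_that("degenerate and boundary parameter cases behave as stated", {
  p0 <- population_params(length_mean = 5, length_sd = 0)
  expect_equal(sample_cell_population(p0, 10, seed = 1)$length, rep(5, 10))

  none <- population_params(cluster_prevalence = 0)
  expect_equal(sum(sample_cell_population(none, 100, seed = 1)$has_cluster), 0)

  all_cl <- population_params(cluster_prevalence = 1)
  tr <- sample_cell_population(all_cl, 100, seed = 1)
  expect_true(all(tr$has_cluster))
  expect_true(all(tr$cluster_position >= 0 & tr$cluster_position <= 1))
  expect_true(all(tr$cluster_amplitude > 0))

  expect_error(sample_cell_population(all_cl, 0, seed = 1), "n must be")
  expect_error(population_params(localization_mixture =
                                   c(midcell = 0.5, off_center = 0.4,
                                     subpolar = 0.2)),
               "sum to 1")
})

test_that("truth localization classes land in their position bands", {
  for (cls in c("midcell", "off_center", "subpolar")) {
    mix <- c(midcell = 0, off_center = 0, subpolar = 0)
    mix[cls] <- 1
    p <- population_params(cluster_prevalence = 1, localization_mixture = mix,
                           nucleoid_span = 0.8)
    pos <- sample_cell_population(p, 200, seed = 3)$cluster_position
    lab <- as.character(classify_localization(pos, nucleoid_span = 0.8))
    expect_true(all(lab == cls), info = cls)
  }
})

test_that("minicell share and DNA flags follow the preset", {
  p <- population_params(length_mean = 13.1, length_sd = 6.1,
                         minicell_fraction = 0.05, cluster_prevalence = 0.5)
  tr <- sample_cell_population(p, 1000, seed = 1)
  expect_lt(abs(mean(tr$is_minicell) - 0.05), 0.02)
  expect_true(all(!tr$has_dna[tr$is_minicell]))
  expect_true(all(tr$length[tr$is_minicell] >= 0.6 &
                    tr$length[tr$is_minicell] <= 1.5))
  expect_true(all(!tr$has_cluster[tr$is_minicell]))
})

test_that("rendered cell round-trips geometry and photometry", {
  truth <- list(cell_id = "c1", length = 6, has_cluster = TRUE,
                cluster_position = 0.5, cluster_amplitude = 5,
                has_constriction = FALSE)
  r <- render_cell(truth, pixel_size = 0.1, noise_sd = 0, seed = 1)
  # geometry round trip: mesh length recovers truth within one pixel
  expect_lt(abs(cell_length(r$mesh) - truth$length), 0.1)

  # brightest mesh segment is the centermost segment
  prof <- extract_profile(r$image, r$mesh)
  i_max <- which.max(prof$values)
  expect_lt(abs(prof$segment_centers[i_max] - 0.5), 0.02)

  # photometry: corrected total over the spot recovers the spot integral
  r0 <- render_cell(modifyList(truth, list(has_cluster = FALSE)),
                    pixel_size = 0.1, noise_sd = 0, seed = 1)
  spot_integral <- sum(r$image - r0$image)
  sigma_px <- 0.15 / 0.1
  expect_lt(abs(spot_integral - 5 * 2 * pi * sigma_px^2) / spot_integral, 0.1)
  captured <- prof$raw_total -
    extract_profile(r0$image, r0$mesh)$raw_total
  expect_lt(abs(captured - spot_integral) / spot_integral, 0.1)
})

test_that("clusterless noiseless render has a flat interior profile", {
  truth <- list(cell_id = "c", length = 8, has_cluster = FALSE,
                has_constriction = FALSE)
  r <- render_cell(truth, noise_sd = 0, seed = 1)
  prof <- extract_profile(r$image, r$mesh)
  core <- prof$values[prof$segment_centers > 0.2 & prof$segment_centers < 0.8]
  expect_lt((max(core) - min(core)) / mean(core), 0.01)
})

test_that("rendered constriction appears at the truth position", {
  truth <- list(cell_id = "c", length = 8, has_cluster = FALSE,
                has_constriction = TRUE, constriction_position = 0.4)
  r <- render_cell(truth, noise_sd = 0, seed = 1)
  w <- width_profile(r$mesh)
  pos <- relative_positions(r$mesh)
  core <- pos > 0.1 & pos < 0.9
  expect_lt(abs(pos[core][which.min(w[core])] - 0.4), 0.02)
  call <- detect_constriction(w, pos)
  expect_true(call$present)
  expect_lt(abs(call$relative_position - 0.4), 0.03)
  expect_gt(call$depth, 0.2)
})

test_that("atpase trace generator matches the closed-form slope and layout", {
  # hand arithmetic: 44/hr * 4e-6 M * 6220 /M/cm * 0.248 cm = 0.27149 /hr
  kt <- kinetic_truth(44, enzyme_conc = 4, control_drift = 0, noise_sd = 0)
  tr <- simulate_atpase_trace(kt, duration_hr = 2, interval_s = 30, seed = 1)
  expect_length(tr$sample$times_s, 241)
  slope <- coef(lm(tr$sample$a340 ~ I(tr$sample$times_s / 3600)))[2]
  expect_lt(abs(slope + 0.2715), 1e-4)

  # zero activity, zero drift, zero noise: perfectly flat
  flat <- simulate_atpase_trace(kinetic_truth(0, control_drift = 0,
                                              noise_sd = 0), seed = 1)
  expect_equal(diff(range(flat$sample$a340)), 0)

  # NADH exhaustion guard
  expect_error(simulate_atpase_trace(kinetic_truth(1000, enzyme_conc = 4),
                                     duration_hr = 2),
               "NADH exhausted")

  # determinism
  a <- simulate_atpase_trace(kinetic_preset("pomx_wt"), seed = 7)
  b <- simulate_atpase_trace(kinetic_preset("pomx_wt"), seed = 7)
  expect_identical(a, b)
})

test_that("timelapse truth fission fraction tracks the probability", {
  p <- population_preset("WT")
  all_f <- simulate_timelapse(p, fission_probability = 1, n_divisions = 50,
                              seed = 1)
  expect_true(all(all_f$truth$fission))

  tl <- simulate_timelapse(p, fission_probability = 0.8, n_divisions = 200,
                           seed = 1)
  expect_lt(abs(mean(tl$truth$fission) - 0.8), 0.06)
  expect_identical(tl$frames,
                   simulate_timelapse(p, 0.8, 200, seed = 1)$frames)
})

test_that("empty daughters regenerate a cluster after the configured delay", {
  p <- population_preset("WT")
  tl <- simulate_timelapse(p, fission_probability = 0, n_divisions = 20,
                           frame_interval = 20, regeneration_delay = 120,
                           seed = 2)
  fr <- tl$frames
  for (i in seq_len(nrow(tl$truth))) {
    d <- tl$truth$frame[i]
    recv <- tl$truth$receiving_daughter[i]
    empty_id <- sprintf("lin%03d_D%d", i, 3 - recv)
    track <- fr[fr$cell_id == empty_id, ]
    first_vis <- min(track$frame[track$cluster_signal > 0])
    expect_equal(first_vis - d, 6)  # 120 min / 20 min
  }
})
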