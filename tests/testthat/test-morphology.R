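test_that("centerline length matches analytic arc lengths", {
  # straight segment: 50 px at 0.1 um/px
  m <- straight_mesh(n = 51, pixel_size = 0.1)
  expect_equal(cell_length(m), 5.0)

  # semicircle of radius 20 px sampled at 1000 points: pi * 2.0 um
  theta <- seq(0, pi, length.out = 1000)
  arc <- data.frame(x = 20 * cos(theta) + 30, y = 20 * sin(theta) + 30)
  sm <- cell_mesh("arc",
                  ribs = data.frame(x_left = arc$x, y_left = arc$y - 1,
                                    x_right = arc$x, y_right = arc$y + 1),
                  centerline = arc, pixel_size = 0.1)
  expect_lt(abs(cell_length(sm) - pi * 2.0) / (pi * 2.0), 0.001)
})

test_that("cell_length is invariant under rigid motions", {
  m <- straight_mesh()
  for (ang in c(0.3, pi / 4, 2)) {
    mt <- transform_mesh(m, angle = ang, dx = 5, dy = -11)
    expect_equal(cell_length(mt), cell_length(m), tolerance = 1e-12)
    expect_equal(width_profile(mt), width_profile(m), tolerance = 1e-12)
  }
})

test_that("width profile reads rib separations in um", {
  m <- straight_mesh(half_width_px = 3.5, pixel_size = 0.1)
  expect_equal(width_profile(m), rep(0.7, 51))
  expect_true(all(width_profile(transform_mesh(m, angle = 1)) >= 0))
})

test_that("constriction detection finds dips and rejects flat profiles", {
  pos <- seq(0, 1, length.out = 101)
  flat <- rep(0.7, 101)
  expect_false(detect_constriction(flat, pos)$present)

  dip <- flat
  dip[51] <- 0.7 * 0.7  # 30% dip at relative position 0.5
  call <- detect_constriction(dip, pos, min_depth = 0.1)
  expect_true(call$present)
  expect_equal(call$relative_position, 0.5)
  expect_equal(call$depth, 0.3, tolerance = 1e-9)

  # a dip outside the central band is not called
  edge <- flat
  edge[3] <- 0.4
  expect_false(detect_constriction(edge, pos, central_band = 0.9)$present)

  expect_error(detect_constriction(numeric(0), numeric(0)), "non-empty")
})

test_that("constriction frequency and position recover generator truth", {
  p <- population_params(length_mean = 8, length_sd = 1.8,
                         constriction_frequency = 0.5)
  tr <- sample_cell_population(p, 400, seed = 5)
  calls <- lapply(seq_len(nrow(tr)), function(i) {
    r <- render_cell(tr[i, ], noise_sd = 0, seed = i)
    detect_constriction(width_profile(r$mesh), relative_positions(r$mesh),
                        cell_id = tr$cell_id[i])
  })
  detected <- vapply(calls, function(x) x$present, logical(1))
  expect_lt(abs(mean(detected) - 0.5), 0.07)

  # positions recovered within 2 ribs for noiseless renders
  idx <- which(tr$has_constriction & detected)
  err <- vapply(idx, function(i)
    abs(calls[[i]]$relative_position - tr$constriction_position[i]),
    numeric(1))
  two_ribs <- 2 / (tr$length[idx] / 0.1)
  expect_true(all(err <= two_ribs + 1e-9))
})

test_that("minicell calling combines length and DNA content", {
  expect_true(classify_minicell(1.0, has_dna = FALSE, cutoff = 2.0))
  expect_false(classify_minicell(8.0, has_dna = TRUE))
  expect_false(classify_minicell(1.0, has_dna = TRUE))   # short but has DNA
  expect_true(classify_minicell(1.0, has_dna = NA))      # length-only mode

  p <- population_params(length_mean = 13.1, length_sd = 6.1,
                         minicell_fraction = 0.05)
  tr <- sample_cell_population(p, 1000, seed = 1)
  called <- classify_minicell(tr$length, tr$has_dna)
  expect_lt(abs(mean(called) - 0.05), 0.02)
})

test_that("length summaries use the linear-interpolation percentile rule", {
  s <- summarize_lengths(1:100)
  expect_equal(s$median, 50.5)
  expect_equal(s$q25, 25.75)
  expect_equal(s$q75, 75.25)
  expect_equal(s$n, 100)
  expect_true(s$q25 <= s$median && s$median <= s$q75)
  expect_true(s$whisker_low <= s$q25)

  one <- summarize_lengths(5)
  expect_equal(one$mean, 5)
  expect_equal(one$median, 5)
  expect_equal(one$sd, 0)

  expect_error(summarize_lengths(numeric(0)), "non-empty")
})

test_that("length summary statistics are equivariant under shifts", {
  set.seed(11)
  x <- rlnorm(200, 2, 0.4)
  a <- summarize_lengths(x)
  b <- summarize_lengths(x + 3)
  for (f in c("mean", "median", "q25", "q75", "whisker_low", "whisker_high"))
    expect_equal(b[[f]], a[[f]] + 3, tolerance = 1e-12)
  expect_equal(b$sd, a$sd, tolerance = 1e-12)
  expect_true(a$q25 <= a$median && a$median <= a$q75)
})

test_that("exact rank-sum test agrees with brute-force enumeration", {
  # the worked case: a = {1,2}, b = {3,4} has exact two-sided p = 1/3
  expect_equal(rank_sum_test(c(1, 2), c(3, 4), mode = "exact"), 1 / 3,
               tolerance = 1e-12)
  expect_equal(brute_force_ranksum(c(1, 2), c(3, 4)), 1 / 3,
               tolerance = 1e-12)

  set.seed(42)
  for (rep in 1:20) {
    na <- sample(2:5, 1); nb <- sample(2:(8 - na), 1)
    x <- sample(1:50, na + nb)  # no ties
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    expect_equal(rank_sum_test(a, b, mode = "exact"),
                 brute_force_ranksum(a, b), tolerance = 1e-10,
                 info = paste("rep", rep))
  }
})

test_that("rank-sum test handles identity, ties and separated samples", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_warning(p <- rank_sum_test(c(1, 1, 2), c(2, 3, 3), mode = "exact"),
                 "ties")
  expect_true(p > 0 && p <= 1)

  # shifted normals (3 SD apart, n = 50) reject at p < 0.001 nearly always
  set.seed(1)
  rejected <- vapply(1:50, function(i) {
    a <- rnorm(50); b <- rnorm(50, mean = 3)
    rank_sum_test(a, b) < 0.001
  }, logical(1))
  expect_gte(mean(rejected), 0.99)
})
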