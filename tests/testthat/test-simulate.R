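# Synthetic-data generators: declared supports, analytic means, frame/pixel
# quantization, and determinism.

test_that("binding assay generator respects rates, quantization, and determinism", {
  zero <- simulate_binding_assay(0, 0.8, 0.3, 3, rep(10, 5), 50, 1, seed = 1)
  expect_equal(nrow(zero$events), 0)

  a <- simulate_binding_assay(1e-4, 1, 0.5, 0.5, rep(10, 40), 100, 0.6, seed = 5)
  # all timestamps are multiples of the 0.125 s frame cycle
  expect_true(all(abs(a$events$t_start_s / 0.125 - round(a$events$t_start_s / 0.125)) < 1e-9))
  expect_true(all(abs(a$events$t_end_s / 0.125 - round(a$events$t_end_s / 0.125)) < 1e-9))
  expect_true(all(a$events$duration_s > 0))

  # pure fast phase: pooled mean dwell ~ tau within 3 SE (rounding is unbiased)
  d <- a$events$duration_s[!a$events$censored]
  expect_lt(abs(mean(d) - 0.5), 3 * 0.5 / sqrt(length(d)) + 0.0625)

  b <- simulate_binding_assay(1e-4, 1, 0.5, 0.5, rep(10, 40), 100, 0.6, seed = 5)
  expect_identical(a$events, b$events)
  expect_error(
    simulate_binding_assay(1e-4, 1, 0.5, 0.5, c(10, -1), 100, 0.6),
    "mt_lengths_um"
  )
  expect_error(
    simulate_binding_assay(1e-4, 1, 0.5, 0.5, 10, 100.1, 0.6),
    "frame cycles"
  )
})

test_that("expected event counts follow the Poisson arrival model", {
  a <- simulate_binding_assay(
    kon_per_site = 1e-4, fast_fraction = 1, tau_fast_s = 5, tau_slow_s = 5,
    mt_lengths_um = rep(10, 100), duration_s = 50, conc_nM = 1,
    sites_per_um = 802, seed = 17
  )
  lam <- 1e-4 * 802 * 10 * 1 * 50 # per microtubule
  total <- nrow(a$events) + attr(a, "dropped_subframe")
  expect_lt(abs(total - 100 * lam) / (100 * lam), 3 / sqrt(100 * lam) + 0.01)
})

test_that("track generator obeys each motion model and the pixel grid", {
  st <- simulate_tracks("static", 5, noise_sd_um = 0, seed = 1)
  expect_true(all(st$position_um == 0))

  pr <- simulate_tracks("processive", 5,
    v_um_s = 0.5, mean_run_um = 10,
    pixel_size_um = 0, seed = 2
  )
  one <- dplyr::filter(pr, track_id == "trk0001")
  steps <- diff(one$position_um)
  expect_true(all(abs(steps[-length(steps)] - 0.0625) < 1e-9))

  px <- simulate_tracks("diffusive", 5, d_um2_s = 0.05, pixel_size_um = 0.16, seed = 3)
  expect_true(all(abs(px$position_um / 0.16 - round(px$position_um / 0.16)) < 1e-9))
  expect_error(simulate_tracks("diffusive", 3, d_um2_s = -1), "d_um2_s")
  expect_error(simulate_tracks("processive", 3, v_um_s = -0.1), "v_um_s")
})

test_that("particle population generator hits the class probabilities", {
  pure <- simulate_particle_population(20, 30, c(phi = 1, open = 0, ambiguous = 0), seed = 1)
  expect_true(all(pure$class_label == "phi"))

  pop <- simulate_particle_population(300, 40, seed = 4)
  frac <- mean(pop$class_label == "phi")
  se <- sqrt(0.75 * 0.25 / nrow(pop))
  expect_lt(abs(frac - 0.75), 3 * se)
  expect_length(attr(pop, "micrographs"), 300)

  expect_identical(pop, simulate_particle_population(300, 40, seed = 4))
  expect_error(
    simulate_particle_population(10, 40, c(phi = 0.7, open = 0.7, ambiguous = -0.4)),
    "class_probs"
  )
})

test_that("pair geometry generator respects the distance range and orientation probs", {
  deg <- simulate_pair_geometry("open", 50, distance_range_nm = c(20, 20), seed = 1)
  expect_true(all(abs(deg$distance_nm - 20) < 1e-9))

  big <- simulate_pair_geometry("open", 10000, seed = 2)
  expect_gte(min(big$distance_nm), 10)
  expect_lte(max(big$distance_nm), 45)
  expect_equal(big$distance_nm, sqrt((big$bx - big$ax)^2 + (big$by - big$ay)^2),
    tolerance = 1e-9
  )
  p_inv <- mean(big$orientation_label == "inverted")
  expect_lt(abs(p_inv - 0.52), 3 * sqrt(0.52 * 0.48 / 10000))

  ddb <- simulate_pair_geometry("ddb", 5000, seed = 3)
  expect_gte(min(ddb$distance_nm), 15)
  expect_lte(max(ddb$distance_nm), 25)
  expect_error(simulate_pair_geometry("open", 10, distance_range_nm = c(30, 10)), "ordered")
})

test_that("SEC trace generator matches its analytic ground truth", {
  grid <- seq(0, 24, by = 0.005)
  one <- simulate_sec_trace(
    data.frame(center_mL = 12, sigma_mL = 0.4, area = 2),
    volume_mL = grid
  )
  # single peak: a +/- 5 sigma window holds essentially all the mass
  expect_equal(as.numeric(auc_fraction(one$trace, 10, 14)), 1, tolerance = 1e-4)
  # total integral equals the declared area (quadrature oracle)
  expect_equal(
    pracma::trapz(one$trace$volume_mL, one$trace$a280), 2,
    tolerance = 1e-6
  )

  two <- simulate_sec_trace(
    data.frame(center_mL = c(8, 16), sigma_mL = c(0.3, 0.3), area = c(1, 1)),
    volume_mL = grid
  )
  expect_equal(as.numeric(auc_fraction(two$trace, 6, 10)), 0.5, tolerance = 1e-3)
  expect_equal(as.numeric(auc_fraction(two$trace, 14, 18)), 0.5, tolerance = 1e-3)
  expect_error(
    simulate_sec_trace(data.frame(center_mL = 1, sigma_mL = 1, area = 1),
      volume_mL = c(1, 1, 2)
    ),
    "strictly increasing"
  )
})

test_that("cell image generator produces flat backgrounds, true foci, and Poisson noise", {
  flat <- simulate_cell_image(c(5, 32, 32), background_level = 120)
  expect_true(all(flat$data == 120))

  st <- simulate_cell_image(
    c(11, 64, 64),
    foci = data.frame(z = 6, y = 20, x = 20, amplitude = 300, sigma_px = 1.5),
    background_level = 50
  )
  on_focus <- measure_roi(st$data[6, , ], 20, 20, 12) - 50
  off_focus <- measure_roi(st$data[6, , ], 50, 50, 12) - 50
  expect_gt(on_focus, 0)
  expect_equal(off_focus, 0, tolerance = 1e-6)

  noisy <- simulate_cell_image(c(3, 100, 100),
    background_level = 400,
    noise = "poisson", seed = 5
  )
  m <- mean(noisy$data)
  expect_lt(abs(m - 400), 3 * sqrt(400 / length(noisy$data)))

  expect_error(
    simulate_cell_image(c(3, 10, 10),
      foci = data.frame(z = 9, y = 5, x = 5, amplitude = 1, sigma_px = 1)
    ),
    "bounds"
  )
  expect_warning(
    simulate_cell_image(c(1, 8, 8),
      foci = data.frame(z = 1, y = 4, x = 4, amplitude = 1e6, sigma_px = 1)
    ),
    "clipped"
  )
})
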