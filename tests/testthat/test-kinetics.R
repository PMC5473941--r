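# Binding kinetics: lattice sites, event filtering, rates, survival curves,
# two-phase fits, Kd, and sample metrics.

test_that("lattice site density matches the 13-protofilament geometry", {
  s <- lattice_sites(13, 8.1, 0.5)
  expect_equal(s$rounded, 802L)
  expect_equal(s$real, 13 * 1000 / 8.1 * 0.5, tolerance = 1e-12)
  expect_equal(lattice_sites(1, 1000, 1)$real, 1)
  expect_equal(lattice_sites(13, 8.1, 1)$rounded, 1605L)
  expect_error(lattice_sites(13, 0, 0.5), "repeat_nm")
})

test_that("lattice sites are monotone in their arguments", {
  base <- lattice_sites(13, 8.1, 0.5)$real
  expect_gt(lattice_sites(14, 8.1, 0.5)$real, base)
  expect_gt(lattice_sites(13, 8.1, 0.6)$real, base)
  expect_lt(lattice_sites(13, 9.0, 0.5)$real, base)
})

test_that("frame rate and minimum event duration follow the acquisition timing", {
  expect_equal(frame_rate(acquisition_params(0.100, 0.025)), 8)
  expect_equal(frame_rate(acquisition_params(1, 1e-12)), 1, tolerance = 1e-9)
  expect_equal(frame_rate(acquisition_params(0.020, 0.005)), 40)
  expect_equal(min_event_duration(acquisition_params()), 0.25)
})

test_that("filter_events applies the 2-frame threshold inclusively and drops censored events", {
  ev <- tibble::tibble(
    mt_id = "mt001",
    duration_s = c(0.125, 0.25, 0.375),
    censored = FALSE
  )
  kept <- filter_events(ev)
  expect_equal(kept$duration_s, c(0.25, 0.375))
  expect_equal(attr(kept, "removal_log")$reason, "below_min_duration")

  strict <- filter_events(ev, strict = TRUE)
  expect_equal(strict$duration_s, 0.375)

  cens <- tibble::tibble(mt_id = "a", duration_s = c(0.5, 0.5), censored = c(FALSE, TRUE))
  expect_equal(nrow(filter_events(cens)), 1)
  expect_equal(nrow(filter_events(cens, drop_censored = FALSE)), 2)

  empty <- filter_events(tibble::tibble(duration_s = double(), censored = logical()))
  expect_equal(nrow(empty), 0)
})

test_that("filter_events matches a brute-force duration scan on random events", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      d <- sample(1:10, 50, replace = TRUE) * 0.125
      ev <- tibble::tibble(mt_id = "m", duration_s = d, censored = FALSE)
      kept <- filter_events(ev)$duration_s
      brute <- d[vapply(d, function(x) x >= 0.25, TRUE)]
      expect_identical(kept, brute)
    }
  })
})

test_that("binding_rate computes per-microtubule normalized rates and SEM", {
  mts <- tibble::tibble(mt_id = "mt001", length_um = 10, duration_s = 60, conc_nM = 1)
  ev <- tibble::tibble(mt_id = rep("mt001", 12), duration_s = 0.5)
  br <- binding_rate(ev, mts)
  expect_equal(br$per_mt$rate, 12 / 600)
  expect_equal(br$summary$kon_sem, 0)

  # microtubules with zero events still enter the average
  mts2 <- tibble::tibble(
    mt_id = c("a", "b"), length_um = 10, duration_s = 60, conc_nM = 1
  )
  ev2 <- tibble::tibble(mt_id = "a", duration_s = 0.5)
  br2 <- binding_rate(ev2, mts2)
  expect_equal(sort(br2$per_mt$n_events), c(0L, 1L))
  expect_error(binding_rate(ev, mts[0, ]), "microtubule")
})

test_that("simulated assays recover the true event rate within 3 SEM", {
  a <- simulate_binding_assay(
    kon_per_site = 2e-4, fast_fraction = 1, tau_fast_s = 2, tau_slow_s = 2,
    mt_lengths_um = rep(10, 50), duration_s = 100, conc_nM = 0.5, seed = 91
  )
  br <- binding_rate(filter_events(a$events), a$microtubules)
  truth <- 2e-4 * a$truth$sites_per_um
  # the 2-frame threshold keeps P(dwell >= 1.5 frames) of tau = 2 s events
  detected <- truth * exp(-0.1875 / 2)
  expect_lt(abs(br$summary$kon_mean - detected), 3.5 * br$summary$kon_sem)
  # the detection-corrected end-to-end rate recovers the truth itself
  ks <- kinetics_summary(a$events, a$microtubules)
  expect_lt(abs(ks$summary$kon_mean - truth) / truth, 0.1)
})

test_that("survival_curve equals the brute-force count and is a valid survival function", {
  sc <- survival_curve(c(0.25, 0.50), bin_s = 0.125)
  expect_equal(sc$pct_remaining[sc$time_s == 0], 100)
  expect_equal(sc$pct_remaining[abs(sc$time_s - 0.25) < 1e-9], 100)
  expect_equal(sc$pct_remaining[abs(sc$time_s - 0.375) < 1e-9], 50)

  # all equal dwells: a single step down from 100
  sc2 <- survival_curve(rep(0.5, 7), bin_s = 0.125)
  expect_true(all(sc2$pct_remaining == 100))
  expect_equal(max(sc2$time_s), 0.5)

  withr::with_seed(7, {
    for (rep in 1:25) {
      d <- rexp(40, 2) + 0.05
      sc <- survival_curve(d, bin_s = 0.125)
      expect_equal(sc$pct_remaining, oracle_survival(d, sc$time_s))
      expect_true(all(diff(sc$pct_remaining) <= 1e-12))
      expect_true(all(sc$pct_remaining >= 0 & sc$pct_remaining <= 100))
    }
  })
  expect_error(survival_curve(numeric()), "at least one")
})

test_that("fit_two_phase has near-zero residuals on noise-free model curves", {
  grid <- seq(0, 8, by = 0.125)
  cases <- list(
    c(w = 0.8, tf = 0.3, ts = 3),
    c(w = 0.5, tf = 0.5, ts = 5),
    c(w = 0.95, tf = 0.2, ts = 1.5)
  )
  for (p in cases) {
    curve <- tibble::tibble(
      time_s = grid,
      pct_remaining = 100 * (p["w"] * exp(-grid / p["tf"]) +
        (1 - p["w"]) * exp(-grid / p["ts"]))
    )
    fit <- fit_two_phase(curve)
    expect_lt(fit$rss, 1e-8)
    expect_equal(fit$w_fast, unname(p["w"]), tolerance = 1e-4)
    expect_equal(fit$tau_fast_s, unname(p["tf"]), tolerance = 1e-4)
    expect_equal(fit$tau_slow_s, unname(p["ts"]), tolerance = 1e-4)
    expect_gt(fit$r_squared, 0.999)
  }
})

test_that("fit_two_phase handles the nested single-exponential case", {
  grid <- seq(0, 6, by = 0.125)
  curve <- tibble::tibble(time_s = grid, pct_remaining = 100 * exp(-grid))
  fit <- fit_two_phase(curve)
  expect_gt(fit$r_squared, 0.999)
  # either both phases collapse to tau = 1 or the fast phase takes all weight
  tau_eff <- fit$w_fast * fit$tau_fast_s + (1 - fit$w_fast) * fit$tau_slow_s
  expect_equal(tau_eff, 1, tolerance = 0.02)
})

test_that("fit_two_phase recovers mixture parameters from sampled dwells", {
  withr::with_seed(123, {
    n <- 5000
    fast <- runif(n) < 0.8
    d <- rexp(n, 1 / ifelse(fast, 0.3, 3))
    fit <- fit_two_phase(survival_curve(d))
    expect_lt(abs(fit$w_fast - 0.8), 0.05)
    expect_lt(abs(fit$tau_fast_s - 0.3) / 0.3, 0.10)
    expect_gt(fit$r_squared, 0.99)
  })
})

test_that("parameter recovery holds across seeds (median criteria)", {
  errs <- purrr::map_dfr(1:20, function(s) {
    withr::with_seed(s, {
      n <- 2000
      fast <- runif(n) < 0.8
      d <- rexp(n, 1 / ifelse(fast, 0.3, 3))
    })
    fit <- fit_two_phase(survival_curve(d))
    tibble::tibble(w_err = abs(fit$w_fast - 0.8),
                   tf_rel = abs(fit$tau_fast_s - 0.3) / 0.3)
  })
  expect_lt(median(errs$w_err), 0.05)
  expect_lt(median(errs$tf_rel), 0.10)
})

test_that("estimate_kd applies the lattice-site scaling", {
  kd <- estimate_kd(kon_mean = 802, dwell_fast_s = 1, sites_per_um = 802)
  expect_equal(kd$kd_uM, 0.001)
  kd2 <- estimate_kd(0.1, 0.5, 802)
  expect_equal(kd2$kd_uM, 16.04)
  expect_equal(kd2$koff_s, 2)
  expect_error(estimate_kd(0, 1, 802), "kon_mean")
})

test_that("kinetics summaries satisfy the Kd internal-consistency invariant", {
  a <- simulate_binding_assay(1e-4, 0.8, 0.3, 3, rep(10, 30), 100, 0.5, seed = 2)
  ks <- kinetics_summary(a$events, a$microtubules)
  s <- ks$summary
  expect_equal(s$kd_uM, s$koff_s / s$kon_mean * s$sites_per_um / 1000,
    tolerance = 1e-9
  )
  expect_true(all(unlist(s[c("kon_mean", "koff_s", "kd_uM")]) > 0))
})

test_that("dimer labeling follows 1 - (1 - p)^2", {
  expect_equal(dimer_labeling(0.85), 0.9775)
  expect_equal(round(100 * dimer_labeling(0.85), 1), 97.8)
  expect_equal(dimer_labeling(1), 1)
  expect_equal(dimer_labeling(0.5), 0.75)
  expect_error(dimer_labeling(1.2), "0, 1")
})

test_that("molar concentration follows Beer-Lambert with the dynein extinction coefficient", {
  expect_equal(molar_concentration(0.797340)$conc_uM, 1)
  expect_equal(molar_concentration(0)$conc_M, 0)
  expect_equal(molar_concentration(0.797340, dye_conc_M = 2e-6)$labeling_ratio, 2)
})
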