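# ROI-based fluorescence quantification and the nonparametric comparison
# workflow.

test_that("sum_projection sums the centred window and rejects bad windows", {
  arr <- array(3, dim = c(11, 8, 8))
  expect_true(all(sum_projection(arr, 6, 11) == 33))
  expect_equal(sum_projection(arr, 4, 1), arr[4, , ])
  expect_error(sum_projection(arr, 3, 11), "exceeds")
  expect_error(sum_projection(arr, 6, 4), "odd")

  withr::with_seed(2, {
    r <- array(runif(11 * 10 * 12), dim = c(11, 10, 12))
  })
  expect_equal(sum_projection(r, 6, 7), oracle_sum_projection(r, 6, 7))
})

test_that("sum_projection is linear", {
  withr::with_seed(3, {
    s1 <- array(runif(5 * 6 * 6), dim = c(5, 6, 6))
    s2 <- array(runif(5 * 6 * 6), dim = c(5, 6, 6))
  })
  expect_equal(
    sum_projection(2 * s1 + 3 * s2, 3, 3),
    2 * sum_projection(s1, 3, 3) + 3 * sum_projection(s2, 3, 3),
    tolerance = 1e-12
  )
})

test_that("measure_roi handles mean/sum, even anchoring, and bounds", {
  u <- matrix(7, 30, 30)
  expect_equal(measure_roi(u, 15, 15, 12), 7)

  z <- matrix(0, 30, 30)
  z[15, 15] <- 144
  expect_equal(measure_roi(z, 15, 15, 12, "sum"), 144)
  expect_equal(measure_roi(z, 15, 15, 12, "mean"), 1)
  # even window anchoring: a 12-wide window centred at 15 spans columns 10..21
  z2 <- matrix(0, 30, 30)
  z2[15, 21] <- 1 # last included column
  z2[15, 9] <- 10 # just outside
  expect_equal(measure_roi(z2, 15, 15, 12, "sum"), 1)
  expect_error(measure_roi(u, 2, 15, 12), "outside")

  withr::with_seed(4, {
    img <- matrix(runif(40 * 40), 40, 40)
    for (i in 1:50) {
      y <- sample(10:30, 1); x <- sample(10:30, 1)
      size <- sample(c(3, 5, 12), 1)
      expect_equal(measure_roi(img, y, x, size), oracle_roi(img, y, x, size))
      expect_equal(
        measure_roi(img, y, x, size, "sum"),
        oracle_roi(img, y, x, size, "sum")
      )
    }
  })
})

test_that("centrosome_signal subtracts the mean of exactly three backgrounds", {
  u <- matrix(5, 64, 64)
  bg3 <- data.frame(y = c(40, 45, 50), x = c(40, 45, 50))
  cs <- centrosome_signal(u, list(y = 20, x = 20), bg3)
  expect_equal(cs$corrected, 0)
  expect_error(
    centrosome_signal(u, list(y = 20, x = 20), bg3[1:2, ]),
    "exactly 3"
  )

  st <- simulate_cell_image(
    c(11, 64, 64),
    foci = data.frame(z = 6, y = 20, x = 20, amplitude = 250, sigma_px = 2),
    background_level = 80
  )
  proj <- sum_projection(st, 6)
  cs2 <- centrosome_signal(proj, list(y = 20, x = 20), bg3)
  # zero noise: corrected equals the ROI mean of the pure focus to 1e-9
  pure <- st$data[6, , ] - 80
  expect_equal(cs2$corrected, measure_roi(pure, 20, 20, 12), tolerance = 1e-9)
  # negative corrected values pass through
  dark <- matrix(10, 64, 64); dark[15:26, 15:26] <- 2
  expect_lt(centrosome_signal(dark, list(y = 20, x = 20), bg3)$corrected, 0)
})

test_that("pole_ratio divides by the median background", {
  u <- matrix(5, 64, 64)
  bg3 <- data.frame(y = c(40, 45, 50), x = c(40, 45, 50))
  expect_equal(pole_ratio(u, list(y = 20, x = 20), bg3)$corrected, 1)

  # median, not mean: one aberrant background ROI does not move the divisor
  img <- matrix(1, 64, 64)
  img[35:46, 35:46] <- 100 # contaminates only the ROI at (40, 40)
  img[15:26, 15:26] <- 2
  pr <- pole_ratio(img, list(y = 20, x = 20),
                   data.frame(y = c(40, 52, 58), x = c(40, 52, 58)))
  expect_equal(pr$background, 1)
  expect_equal(pr$corrected, 2)
  expect_error(
    pole_ratio(matrix(0, 30, 30), list(y = 15, x = 15),
               data.frame(y = c(10, 15, 20), x = c(10, 15, 20))),
    "positive"
  )
})

test_that("foci_timecourse is flat for static foci and recovers appearance ramps", {
  frames <- purrr::map(1:5, function(i) {
    m <- matrix(50, 40, 40)
    m[10, 10] <- 250
    m[30, 30] <- 150
    m
  })
  tc <- foci_timecourse(frames, tibble::tibble(focus_id = 1:2, y = c(10, 30), x = c(10, 30)),
    background = list(y = 20, x = 20)
  )
  expect_equal(dplyr::n_distinct(round(tc$summary$mean, 9)), 1)
  expect_equal(dplyr::n_distinct(round(tc$summary$sd, 9)), 1)

  tl <- simulate_focus_timelapse(
    n_timepoints = 11, interval_s = 30,
    foci = data.frame(y = c(12, 30), x = c(12, 30), amplitude = 300,
                      sigma_px = 1.5, t_on_s = 60),
    background_level = 60, seed = 2
  )
  tc2 <- foci_timecourse(tl, tibble::tibble(focus_id = 1:2, y = c(12, 30), x = c(12, 30)),
    background = list(y = 50, x = 50)
  )
  late <- tc2$summary$mean[tc2$summary$t_index == 11]
  early <- tc2$summary$mean[tc2$summary$t_index == 1]
  expect_gt(late, early)
  # the mean rises monotonically once foci switch on (zero noise)
  ramp <- tc2$summary$mean[tc2$summary$time_s >= 60]
  expect_true(all(diff(ramp) > -1e-9))

  expect_error(
    foci_timecourse(frames, tibble::tibble(focus_id = integer(), y = integer(), x = integer()),
      background = list(y = 20, x = 20)
    ),
    "at least one focus"
  )
})

test_that("group_compare runs the Shapiro/Bartlett/Kruskal/Wilcoxon workflow", {
  withr::with_seed(10, {
    dat <- tidyr::expand_grid(
      experiment = c("exp1", "exp2", "exp3"),
      condition = c("ctrl", "mut"),
      i = 1:30
    ) |>
      dplyr::mutate(value = rnorm(dplyr::n(), mean = ifelse(condition == "mut", 2, 0)))
  })
  gc <- group_compare(dat)
  expect_equal(nrow(gc$omnibus), 3)
  expect_true(all(gc$omnibus$p_kruskal < 0.01))
  expect_true(all(gc$pairwise_max_p$p_reported < 0.01))
  expect_equal(nrow(gc$normality), 6)

  # identical groups: Kruskal-Wallis p ~ 1
  same <- tibble::tibble(
    experiment = "e1",
    condition = rep(c("a", "b"), each = 20),
    value = rep(seq_len(20), 2)
  )
  gs <- group_compare(same)
  expect_gt(gs$omnibus$p_kruskal, 0.9)

  # two groups from distributions shifted by 2 sd, n = 100 -> p < 0.01
  withr::with_seed(11, {
    shift <- tibble::tibble(
      experiment = "e1",
      condition = rep(c("a", "b"), each = 100),
      value = c(rnorm(100), rnorm(100, 2))
    )
  })
  expect_lt(group_compare(shift)$pairwise_max_p$p_reported, 0.01)

  # unequal group sizes within an experiment: pairwise skipped with warning
  uneq <- tibble::tibble(
    experiment = "e1", condition = c(rep("a", 5), rep("b", 4)),
    value = rnorm(9)
  )
  expect_warning(gu <- group_compare(uneq), "unequal")
  expect_true(is.na(gu$pairwise$p_wilcoxon))
  expect_error(group_compare(dplyr::filter(dat, condition == "ctrl")), "2 conditions")
})

test_that("max-p aggregation reports the largest per-experiment p value", {
  # three experiments engineered to give different Wilcoxon p values
  withr::with_seed(20, {
    dat <- purrr::map_dfr(1:3, function(e) {
      shift <- c(3, 1, 0.3)[e]
      tibble::tibble(
        experiment = paste0("e", e),
        condition = rep(c("a", "b"), each = 25),
        value = c(rnorm(25), rnorm(25, shift))
      )
    })
  })
  gc <- group_compare(dat)
  expect_equal(
    gc$pairwise_max_p$p_reported,
    max(gc$pairwise$p_wilcoxon)
  )
})
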