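test_that("thermal offset is leaf minus air, antisymmetric under channel swap", {
  s <- paired_series("p", "high", 750, 36, 35)
  expect_equal(thermal_offset(s)$mean, 1.0)
  s2 <- paired_series("p", "high", 750, 34.0, 35.5)
  expect_equal(thermal_offset(s2)$mean, -1.5)

  set.seed(5)
  s3 <- make_series(t_air = runif(11, 20, 30), t_leaf = runif(11, 20, 30))
  swapped <- paired_series("p1", "benign", s3$time_min, s3$t_air, s3$t_leaf)
  expect_equal(thermal_offset(swapped)$delta_t, -thermal_offset(s3)$delta_t)
  expect_equal(thermal_offset(swapped)$mean, -thermal_offset(s3)$mean)

  empty <- suppressWarnings(clip_to_window(make_series(time_min = 600:610)))
  expect_error(thermal_offset(empty), "empty")
})

test_that("window slopes are exact OLS and degenerate windows are skipped", {
  # collinear points: slope exactly 0.5
  s <- paired_series("p", "high", 750:752, c(30, 30.5, 31), c(30, 31, 32))
  sl <- coupling_slopes(s, min_points = 3)
  expect_equal(sl$slope[sl$retained], 0.5)
  expect_equal(sl$r_squared[sl$retained], 1)

  # constant air temperature: degenerate regressor, window skipped
  s2 <- paired_series("p", "high", 750:779, 33 + seq(0, 1, length.out = 30),
    rep(35, 30))
  s3 <- paired_series("p", "high", c(750:779, 780:809),
    c(33 + seq(0, 1, length.out = 30), 33 + 0.9 * seq(0, 2, length.out = 30)),
    c(rep(35, 30), 35 + seq(0, 2, length.out = 30)))
  sl3 <- coupling_slopes(s3)
  expect_equal(sl3$retained, c(FALSE, TRUE))
  expect_equal(sl3$skip_reason[1], "air_range_too_small")

  # a window below min_points is skipped; all-skipped is an error naming the plant
  expect_error(coupling_slopes(s2, min_points = 10), "p")
  short <- paired_series("plantX", "high", 750:754, 33:37, 34:38)
  expect_error(coupling_slopes(short), "plantX")
})

test_that("windows partition the series anchored at the window start", {
  s <- make_linear_series("p", "high", a = 2, b = 0.9)
  sl <- coupling_slopes(s)
  # 151 minutes from 12:30: five full 30-min windows plus a 1-min remainder
  expect_equal(nrow(sl), 6)
  expect_equal(sl$window_start, 750 + 30 * (0:5))
  expect_equal(sl$n_points, c(30, 30, 30, 30, 30, 1))
  expect_equal(sum(sl$retained), 5)
  expect_equal(sl$slope[sl$retained], rep(0.9, 5))
})

test_that("beta aggregates retained slopes as an unweighted mean", {
  expect_equal(beta_from_slopes(c(0.9, 1.1)), 1.0)
  expect_equal(beta_from_slopes(0.83), 0.83)
  sl <- tibble::tibble(slope = c(0.8, 1.0, 1.2), n_points = c(30L, 30L, 30L),
    retained = TRUE)
  expect_equal(beta_from_slopes(sl), beta_from_slopes(sl, "n_weighted"))
  sl$n_points <- c(30L, 10L, 5L)
  expect_false(beta_from_slopes(sl) == beta_from_slopes(sl, "n_weighted"))
})

test_that("thermoregulatory classes follow the beta = 1 band", {
  expect_equal(as.character(classify_thermoregulation(1.0)), "poikilotherm")
  expect_equal(as.character(classify_thermoregulation(0.8)), "limited_homeotherm")
  expect_equal(as.character(classify_thermoregulation(1.3)), "megatherm")
  # band edges are inclusive
  expect_equal(as.character(classify_thermoregulation(c(0.9, 1.1))),
    c("poikilotherm", "poikilotherm"))
  expect_equal(as.character(classify_thermoregulation(c(0.9 - 1e-9, 1.1 + 1e-9))),
    c("limited_homeotherm", "megatherm"))
  expect_equal(as.character(classify_thermoregulation(0.95, epsilon = 0.01)),
    "limited_homeotherm")
  expect_error(classify_thermoregulation(NaN), "finite")
})

test_that("shifting channels by constants acts on offset but not slopes", {
  set.seed(21)
  s <- make_linear_series("p", "benign", a = 1, b = 0.9)
  noisy <- paired_series("p", "benign", s$time_min,
    s$t_leaf + rnorm(nrow(s), 0, 0.3), s$t_air)
  base_sl <- coupling_slopes(noisy)
  base_dt <- thermal_offset(noisy)
  for (c0 in c(-3, 2.5)) {
    both <- paired_series("p", "benign", noisy$time_min,
      noisy$t_leaf + c0, noisy$t_air + c0)
    expect_equal(coupling_slopes(both)$slope, base_sl$slope)
    expect_equal(thermal_offset(both)$mean, base_dt$mean)
    leaf_only <- paired_series("p", "benign", noisy$time_min,
      noisy$t_leaf + c0, noisy$t_air)
    expect_equal(coupling_slopes(leaf_only)$slope, base_sl$slope)
    expect_equal(thermal_offset(leaf_only)$mean, base_dt$mean + c0)
  }
})

test_that("estimated beta recovers the generating slope as noise shrinks", {
  # t_leaf identical to t_air: beta exactly 1 and delta-T exactly 0
  s0 <- make_linear_series("p", "benign", a = 0, b = 1)
  expect_equal(beta_from_slopes(coupling_slopes(s0)), 1)
  expect_equal(thermal_offset(s0)$mean, 0)

  tm <- 750:899
  for (sigma in c(0.5, 0.1, 0.01)) {
    set.seed(1000 + round(sigma * 100))
    errs <- replicate(50, {
      t_air <- generate_air_profile("high", 150)
      t_leaf <- generate_leaf_series(t_air, offset = -1, slope = 0.8,
        noise_sd = sigma)
      s <- paired_series("p", "high", tm, t_leaf, t_air)
      s <- trim_by_air_threshold(s)$series
      beta_from_slopes(coupling_slopes(s)) - 0.8
    })
    # mean absolute error shrinks with sigma and the mean estimate is unbiased
    expect_lt(abs(mean(errs)), 0.02 + 0.1 * sigma)
    expect_lt(mean(abs(errs)), 0.02 + 0.5 * sigma)
  }
})

test_that("mean slope over replicates recovers slope 1.2 within 0.1 at sigma 0.2", {
  set.seed(99)
  tm <- 750:899
  est <- replicate(200, {
    t_air <- generate_air_profile("high", 150)
    t_leaf <- generate_leaf_series(t_air, offset = 0, slope = 1.2, noise_sd = 0.2)
    s <- paired_series("p", "high", tm, t_leaf, t_air)
    s <- trim_by_air_threshold(s)$series
    beta_from_slopes(coupling_slopes(s))
  })
  expect_lt(abs(mean(est) - 1.2), 0.1)
})

test_that("coupling_metrics assembles a consistent per-plant row", {
  s <- make_linear_series("plant7", "high", a = -1, b = 1.25)
  m <- coupling_metrics(s)
  expect_equal(m$plant_id, "plant7")
  expect_equal(m$beta, 1.25)
  expect_equal(m$thermo_class, "megatherm")
  expect_equal(m$n_windows, 5)
  # delta-T mean equals the hand value a + (b - 1) * mean(t_air)
  expect_equal(m$delta_t_mean, -1 + 0.25 * mean(s$t_air))
})
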