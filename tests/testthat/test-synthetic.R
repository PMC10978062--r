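test_that("drift products share the true field and honour the summer gap", {
  dom <- tiny_domain()
  stack0 <- make_drift_stack(dom, quiet_scenario())
  # zero noise: all products carry the identical underlying velocity
  expect_equal(stack0$products[[1]]$u, stack0$products[[2]]$u)
  expect_equal(stack0$products[[2]]$v, stack0$products[[3]]$v)
  expect_true(all(stack0$products[[1]]$u == -5))

  months <- as.POSIXlt(dom$dates)$mon + 1
  p1 <- stack0$products[[1]]$available
  expect_true(all(!p1[, , months %in% c(6, 7)]))
  expect_true(all(p1[, , !(months %in% c(6, 7))]))
  expect_true(all(stack0$products[[2]]$available))
  expect_true(all(stack0$products[[3]]$available))

  # determinism: identical (config, seed) => identical stacks
  sc <- scenario_params()
  expect_identical(make_drift_stack(dom, sc), make_drift_stack(dom, sc))
  expect_false(identical(make_drift_stack(dom, sc),
                         make_drift_stack(tiny_domain(seed = 2), sc)))
})

test_that("degenerate grids and invalid configs are rejected", {
  expect_error(domain_config(cell_km = 600), "degenerate grid")
  expect_error(domain_config(shelf_depth_m = 150), "< 100")
  expect_error(domain_config(basin_depth_m = 80), "> 100")
  expect_error(domain_config(end_date = "2000-12-31"), "2 full years")
  expect_error(domain_config(shelf_x_km = c(300, 300)), "empty")
  expect_error(domain_config(shelf_x_km = c(2000, 2400)), "outside")
  expect_error(scenario_params(terrigenous_decline = 1.5), "0, 1")
  expect_error(scenario_params(drift_noise_sd = -1), "non-negative")
})

test_that("concentration field is bounded, seasonal, and ice-free in September", {
  dom <- tiny_domain()
  conc <- make_concentration_field(dom, quiet_scenario())
  expect_true(all(conc$data >= 0 & conc$data <= 100))
  m <- dom$mooring_xy_km
  expect_equal(field_value(conc, as.Date("2001-09-05"), m[1], m[2]), 0)
  expect_equal(field_value(conc, as.Date("2001-09-28"), m[1], m[2]), 0)
  # early-June cover at the mooring matches the configured amplitude
  expect_equal(field_value(conc, as.Date("2001-06-01"), m[1], m[2]), 20,
               tolerance = 0.05)
  # deep-winter interior is fully ice covered
  expect_equal(field_value(conc, as.Date("2001-02-01"), 650, 150), 100)

  flat <- make_concentration_field(dom, quiet_scenario(conc_amplitude_pct = 0))
  expect_true(all(flat$data == as.vector(flat$data[, , 1])))

  sc <- scenario_params()
  expect_identical(make_concentration_field(dom, sc),
                   make_concentration_field(dom, sc))
})

test_that("air temperature cycles between the configured extremes", {
  dom <- tiny_domain()
  temp <- make_airtemp_field(dom, quiet_scenario())
  # summer peak is exact at the phase anchor (mid July)
  expect_equal(field_value(temp, as.Date("2001-07-15"), 100, 150), 5,
               tolerance = 1e-8)
  expect_equal(min(temp$data), -30, tolerance = 0.05)
  # annual mean equals the midpoint of the extremes
  yr <- format(dom$dates, "%Y") == "2001"
  expect_equal(mean(temp$data[1, 1, yr]), (5 - 30) / 2, tolerance = 0.1)
  sc <- scenario_params()
  expect_identical(make_airtemp_field(dom, sc), make_airtemp_field(dom, sc))
})

test_that("bathymetry splits shelf and basin strictly about 100 m", {
  dom <- tiny_domain()
  bathy <- make_bathymetry(dom)
  on_shelf <- dom$x >= 500
  expect_true(all(bathy$depth[, on_shelf] == 50))
  expect_true(all(bathy$depth[, !on_shelf] == 2500))
  expect_false(any(bathy$depth == 100))
})

test_that("cup intervals tile complete months within trap practice", {
  dom <- tiny_domain()
  iv <- cup_intervals(dom)
  expect_true(all(iv$days >= 10 & iv$days <= 31))
  # contiguous coverage: each cup starts where the previous one ended
  expect_true(all(iv$start[-1] == iv$end[-nrow(iv)]))
  expect_equal(iv$start[1], dom$start_date)
  # productive months carry two cups, others one
  ym <- format(iv$start, "%Y-%m")
  counts <- tapply(ym, ym, length)
  mo <- as.integer(substr(names(counts), 6, 7))
  expect_true(all(counts[mo %in% 3:9] == 2))
  expect_true(all(counts[!(mo %in% 3:9)] == 1))
})

test_that("flux series follows the configured decline exactly when noise-free", {
  dom <- domain_config(end_date = "2004-12-31", seed = 7)
  sc <- quiet_scenario(terrigenous_decline = 0.8)
  iv <- cup_intervals(dom)
  dist <- rep(30, nrow(iv))  # identical distance profile each year
  cups <- make_flux_series(dom, sc, dist)
  yr <- format(cups$start, "%Y")
  first <- mean(cups$terr_flux[yr == "2000"])
  last <- mean(cups$terr_flux[yr == "2004"])
  expect_equal(last, 0.2 * first, tolerance = 1e-12)
  expect_error(make_flux_series(dom, sc, dist[-1]), "one edge distance")
})

test_that("null generator gives equal near/far POC means in expectation", {
  # Monte-Carlo under the null (no ballast, no decline): pooled >= 1000 cups
  sc <- quiet_scenario(ballast_effect = 1, terrigenous_decline = 0,
                       flux_noise_cv = 0.15)
  near <- far <- c()
  for (s in 1:8) {
    dom <- domain_config(end_date = "2006-12-31", seed = s)
    iv <- cup_intervals(dom)
    dist <- rep(c(0, 200), length.out = nrow(iv))
    cups <- make_flux_series(dom, sc, dist)
    near <- c(near, cups$poc_flux[dist == 0])
    far <- c(far, cups$poc_flux[dist == 200])
  }
  expect_gte(length(near) + length(far), 1000)
  ci <- t.test(log(near), log(far))$conf.int
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("positive ballast effect couples POC to terrigenous flux", {
  dom <- domain_config(start_date = "1990-01-01", end_date = "2013-12-31",
                       seed = 11)
  iv <- cup_intervals(dom)
  set.seed(42)
  dist <- runif(nrow(iv), 0, 150)
  cups <- make_flux_series(dom, scenario_params(terrigenous_decline = 0), dist)
  expect_gte(nrow(cups), 400)
  expect_gt(spearman_rank(cups$poc_flux, cups$terr_flux)$rho, 0)
})

test_that("particle tracks encode the treatment settling multipliers", {
  # noise-free control recovers the true velocity exactly
  ctl <- make_particle_tracks(5, "control", "none", seed = 1, v_cv = 0,
                              noise_sd_mm = 0)
  v <- velocities_from_tracks(ctl)
  expect_equal(v$velocity_m_day, rep(20, 5), tolerance = 1e-9)

  big <- make_particle_tracks(5, "gypsum", "large", seed = 1, v_cv = 0,
                              noise_sd_mm = 0)
  vb <- velocities_from_tracks(big)
  expect_equal(vb$velocity_m_day, rep(200, 5), tolerance = 1e-9)

  # small crystals: enhanced early, back to control level by 15 h
  expect_gt(ballast_multiplier("small", 3), 2)
  expect_lt(ballast_multiplier("small", 15), 1.01)
  expect_equal(ballast_multiplier("none", 7), 1)
  expect_equal(ballast_multiplier("large", 15), 10)

  expect_identical(make_particle_tracks(8, "gypsum", "small", seed = 3),
                   make_particle_tracks(8, "gypsum", "small", seed = 3))
  expect_error(make_particle_tracks(0, "control", "none", 1), ">= 1")
  expect_error(make_particle_tracks(3, "control", "large", 1), "control")
})
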