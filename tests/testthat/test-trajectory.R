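test_that("uniform flow reproduces the closed-form backward path", {
  dom <- tiny_domain()
  stack <- uniform_stack(dom, list(c(-5, 2), c(-5, 2), c(-5, 2)))
  conc <- conc_field(dom, 100)
  cfg <- tracker_config(conc_threshold_pct = 25, max_duration_days = 20)
  tr <- backtrack(c(400, 150), as.Date("2001-06-15"), stack, conc, cfg)
  expect_s3_class(tr, "ice_trajectory")
  expect_identical(tr$reason, "max_duration")
  s <- tr$samples
  k <- seq_len(nrow(s)) - 1
  # x(t - k) = x0 - k * (-u) etc. under backward Euler with constant v
  expect_equal(s$x_km, 400 + 5 * k, tolerance = 1e-12)
  expect_equal(s$y_km, 150 - 2 * k, tolerance = 1e-12)
  expect_equal(as.numeric(tr$start_date - s$date), k)
  expect_equal(nrow(s), 21)  # day 0 .. day 20 inclusive
})

test_that("trace terminates as formed at the first sub-threshold sample", {
  dom <- tiny_domain()
  stack <- uniform_stack(dom)  # u = -5: backward motion is +x
  # concentration drops below 25% for x >= 500 (the shelf)
  conc <- conc_field(dom, function(x, it) ifelse(x >= 500, 10, 90))
  cfg <- tracker_config(conc_threshold_pct = 25, max_duration_days = 3650)
  tr <- backtrack(c(250, 150), as.Date("2001-06-15"), stack, conc, cfg)
  expect_identical(tr$reason, "formed")
  s <- tr$samples
  expect_lt(s$concentration_pct[nrow(s)], 25)
  expect_true(all(s$concentration_pct[-nrow(s)] >= 25))
  # formation position is on the shelf side of the step
  expect_gte(s$x_km[nrow(s)], 450)
  # terminal sample carries no step product
  expect_true(is.na(s$product_id[nrow(s)]))
  expect_true(all(s$product_id[-nrow(s)] == 1L))
})

test_that("domain exit is recorded with the exit sample", {
  dom <- tiny_domain()
  stack <- uniform_stack(dom, list(c(20, 0), c(20, 0), c(20, 0)))
  conc <- conc_field(dom, 100)
  cfg <- tracker_config(max_duration_days = 3650)
  tr <- backtrack(c(100, 150), as.Date("2001-06-15"), stack, conc, cfg)
  expect_identical(tr$reason, "left_domain")
  s <- tr$samples
  # backward motion is -x at 20 km/day from x = 100; exits past the hull
  expect_lt(s$x_km[nrow(s)], min(dom$x))
  expect_true(is.na(s$concentration_pct[nrow(s)]))
})

test_that("reaching the start of the record reports max_duration", {
  dom <- tiny_domain()
  stack <- uniform_stack(dom, list(c(0, 0), c(0, 0), c(0, 0)))
  conc <- conc_field(dom, 100)
  cfg <- tracker_config(max_duration_days = 1e6)
  tr <- backtrack(c(350, 150), as.Date("2000-01-05"), stack, conc, cfg)
  expect_identical(tr$reason, "max_duration")
  expect_equal(tr$samples$date[nrow(tr$samples)], dom$dates[1])
})

test_that("product fallback follows priority order and is audited", {
  dom <- tiny_domain()
  stack <- uniform_stack(dom, list(c(-5, 0), c(-3, 0), c(-1, 0)),
                         gap_months = c(6, 7))
  conc <- conc_field(dom, 100)
  # mask product 2 everywhere in June as well: June should fall to product 3
  months <- as.POSIXlt(dom$dates)$mon + 1
  stack$products[[2]]$available[, , months == 6] <- FALSE

  mid_may <- sample_drift(stack, c(350, 150), as.Date("2001-05-10"))
  expect_equal(mid_may$product, 1L)
  expect_equal(mid_may$u, -5)
  in_july <- sample_drift(stack, c(350, 150), as.Date("2001-07-10"))
  expect_equal(in_july$product, 2L)
  expect_equal(in_july$u, -3)
  in_june <- sample_drift(stack, c(350, 150), as.Date("2001-06-10"))
  expect_equal(in_june$product, 3L)
  expect_equal(in_june$u, -1)

  # trajectory spanning the gap months records the switch per step
  cfg <- tracker_config(max_duration_days = 120)
  tr <- backtrack(c(350, 150), as.Date("2001-08-15"), stack, conc, cfg)
  s <- tr$samples
  mo <- as.POSIXlt(s$date)$mon + 1
  used <- s$product_id[-nrow(s)]
  expect_true(all(used[mo[-nrow(s)] == 8] == 1L))
  expect_true(all(used[mo[-nrow(s)] == 7] == 2L))
  expect_true(all(used[mo[-nrow(s)] == 6] == 3L))
})

test_that("spatial search radius recovers motion near masked cells", {
  dom <- tiny_domain()
  stack <- uniform_stack(dom, list(c(-5, 0), c(-4, 0), c(-2, 0)))
  it <- iceballast:::date_index(stack$dates, as.Date("2001-05-10"))
  i <- iceballast:::cell_of(stack$x, 350)
  j <- iceballast:::cell_of(stack$y, 150)
  # mask only the containing cell of product 1
  stack$products[[1]]$available[j, i, it] <- FALSE

  with_r <- sample_drift(stack, c(350, 150), as.Date("2001-05-10"), radius = 1L)
  expect_equal(with_r$product, 1L)  # neighbor cell of product 1 wins
  no_r <- sample_drift(stack, c(350, 150), as.Date("2001-05-10"), radius = 0L)
  expect_equal(no_r$product, 2L)    # falls through to product 2

  # all products masked in a 3x3 patch: nothing within radius 1
  for (k in 1:3)
    stack$products[[k]]$available[(j - 1):(j + 1), (i - 1):(i + 1), it] <- FALSE
  none <- sample_drift(stack, c(350, 150), as.Date("2001-05-10"), radius = 1L)
  expect_true(is.na(none$product))

  conc <- conc_field(dom, 100)
  tr <- backtrack(c(350, 150), as.Date("2001-05-10"), stack, conc,
                  tracker_config(search_radius_cells = 1L))
  expect_identical(tr$reason, "no_motion_data")
})

test_that("batch_backtrack starts on the first of every month", {
  dom <- tiny_domain()
  stack <- uniform_stack(dom, list(c(0, 0), c(0, 0), c(0, 0)))
  conc <- conc_field(dom, 100)
  cfg <- tracker_config(start_xy_km = c(250, 150), max_duration_days = 5)
  trs <- batch_backtrack(stack, conc, cfg)
  expect_length(trs, 24)
  starts <- as.Date(vapply(trs, function(t) format(t$start_date), ""))
  expect_equal(starts, seq(as.Date("2000-01-01"), by = "month",
                           length.out = 24))
  expect_true(all(vapply(trs, function(t) t$reason, "") == "max_duration"))
})

test_that("invalid starts are rejected", {
  dom <- tiny_domain()
  stack <- uniform_stack(dom)
  conc <- conc_field(dom, 100)
  cfg <- tracker_config()
  expect_error(backtrack(c(250, 150), as.Date("1999-06-15"), stack, conc, cfg),
               "calendar")
  expect_error(backtrack(c(-50, 150), as.Date("2001-06-15"), stack, conc, cfg),
               "outside")
  expect_error(tracker_config(step_days = 0), "> 0")
  expect_error(tracker_config(conc_threshold_pct = 100), "0, 100")
})

test_that("track density counts each trajectory once per cell", {
  dom <- tiny_domain()
  # trajectory oscillating between two cells, visiting each many times
  tr <- fake_trajectory(rep(-10, 10),
                        xs = rep(c(120, 180), 5), ys = rep(150, 10))
  dens <- track_density(list(tr, tr, tr), dom)
  expect_equal(sum(dens), 6L)  # 3 trajectories x 2 distinct cells
  expect_true(all(dens %in% c(0L, 3L)))
  empty <- track_density(list(), dom)
  expect_true(all(empty == 0L))
  expect_equal(dim(empty), c(length(dom$y), length(dom$x)))
})
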