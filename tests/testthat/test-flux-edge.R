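test_that("flux normalization matches mass / (area x days)", {
  expect_identical(compute_flux(10, 0.5, 20), 1)
  expect_equal(compute_flux(c(5, 10), 0.5, c(10, 10)), c(1, 2))
  expect_identical(compute_flux(0, 0.5, 15), 0)
  expect_error(compute_flux(-1, 0.5, 10), ">= 0")
  expect_error(compute_flux(1, 0, 10), "> 0")
  expect_error(compute_flux(1, 0.5, 0), "> 0")
})

test_that("edge distance is zero on ice, minimal to the edge, NA when ice-free", {
  dom <- tiny_domain()
  # ice strictly at x >= 400 (cells 425, 475, ...) at 80%
  conc <- conc_field(dom, function(x, it) ifelse(x >= 400, 80, 0))
  d0 <- edge_distance(conc, dom$dates[1], c(450, 150))
  expect_identical(d0, 0)
  # point at the cell center (100, 125): nearest qualifying center (425, 125)
  d1 <- edge_distance(conc, dom$dates[1], c(100, 125))
  expect_equal(d1, 325)
  # off-axis point: Euclidean, not axis distance (nearest center (425, 75))
  d2 <- edge_distance(conc, dom$dates[1], c(100, 60))
  expect_equal(d2, sqrt(325^2 + (75 - 60)^2))
  # below-threshold ice everywhere => no edge
  thin <- conc_field(dom, 10)
  expect_true(is.na(edge_distance(thin, dom$dates[1], c(100, 150))))
  # threshold is inclusive at exactly 15%
  at15 <- conc_field(dom, 15)
  expect_identical(edge_distance(at15, dom$dates[1], c(100, 150)), 0)
  expect_error(edge_distance(conc, as.Date("1999-01-01"), c(100, 150)),
               "calendar")
})

test_that("edge distance agrees with a brute-force scan on random fields", {
  dom <- tiny_domain()
  set.seed(99)
  for (rep in 1:25) {
    conc <- conc_field(dom, function(x, it) runif(length(x), 0, 40))
    pt <- c(runif(1, 0, 700), runif(1, 0, 300))
    got <- edge_distance(conc, dom$dates[1], pt)
    # oracle: exhaustive scan over all cells
    slice <- conc$data[, , 1]
    best <- Inf
    for (j in seq_along(dom$y)) for (i in seq_along(dom$x)) {
      if (slice[j, i] >= 15) {
        own <- abs(dom$x[i] - pt[1]) <= 25 && abs(dom$y[j] - pt[2]) <= 25
        d <- if (own) 0 else sqrt((dom$x[i] - pt[1])^2 + (dom$y[j] - pt[2])^2)
        best <- min(best, d)
      }
    }
    if (is.finite(best)) expect_equal(got, best) else expect_true(is.na(got))
  }
})

test_that("integrated cover averages the daily concentration over [start, end)", {
  dom <- tiny_domain()
  # concentration equal to the day index at every cell
  conc <- conc_field(dom, function(x, it) rep(it %% 100, length(x)))
  got <- integrate_cover(conc, c(100, 150), dom$dates[1], dom$dates[1] + 10)
  expect_equal(got, mean(1:10))
  expect_error(integrate_cover(conc, c(100, 150), dom$dates[5], dom$dates[5]),
               "after")
})

test_that("cup conditions summarize daily distances with ice-free days dropped", {
  dom <- tiny_domain()
  # ice present (x >= 400) only on the first 5 days of the calendar
  conc <- conc_field(dom, function(x, it)
    if (it <= 5) ifelse(x >= 400, 80, 0) else rep(0, length(x)))
  cups <- data.frame(start = dom$dates[1], end = dom$dates[1] + 10)
  out <- cup_ice_conditions(cups, conc, c(100, 125))
  expect_equal(out$distance_km, 325)   # NA ice-free days dropped from mean
  expect_equal(out$cover_pct, 0)       # mooring cell itself never iced
  allfree <- data.frame(start = dom$dates[20], end = dom$dates[30])
  out2 <- cup_ice_conditions(allfree, conc, c(100, 125))
  expect_true(is.na(out2$distance_km))
})

test_that("distance bins are half-open, exhaustive and mutually exclusive", {
  cups <- data.frame(start = as.Date("2000-03-01") + 0:7,
                     end = as.Date("2000-03-16") + 0:7)
  d <- c(0, 39.999, 40, 79.999, 80, 149.999, 150, NA)
  out <- classify_cups(cups, distances = d)
  expect_equal(as.character(out$bin),
               c("0-40", "0-40", "40-80", "40-80", "80-150", "80-150",
                 "excluded", "excluded"))
  # every distance lands in exactly one bin
  expect_false(any(is.na(out$bin)))
  set.seed(3)
  rnd <- classify_cups(data.frame(start = rep(as.Date("2000-03-01"), 500),
                                  end = rep(as.Date("2000-03-16"), 500)),
                       distances = runif(500, -0, 300))
  expect_false(any(is.na(rnd$bin)))
  tab <- table(rnd$bin)
  expect_equal(sum(tab), 500)
  expect_error(classify_cups(cups, distances = d[-1]), "one distance")
  expect_error(classify_cups(data.frame(start = 1, end = 2)), "no distances")
})

test_that("classify_cups picks up generator distances by default", {
  dom <- tiny_domain()
  iv <- cup_intervals(dom)
  set.seed(5)
  cups <- make_flux_series(dom, quiet_scenario(),
                           runif(nrow(iv), 0, 200))
  out <- classify_cups(cups)
  expect_true(all(levels(out$bin) == c("0-40", "40-80", "80-150", "excluded")))
  expect_equal(as.character(out$bin) == "excluded", out$distance_km >= 150)
})

test_that("seasonal filter keeps midpoint months March through September", {
  cups <- data.frame(
    start = as.Date(c("2000-02-20", "2000-03-01", "2000-09-16", "2000-09-25")),
    end = as.Date(c("2000-03-05", "2000-03-16", "2000-10-01", "2000-10-08")))
  # midpoints: Feb 26 (drop), Mar 8 (keep), Sep 23 (keep), Oct 1 (drop)
  kept <- seasonal_filter(cups)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$start, as.Date(c("2000-03-01", "2000-09-16")))
  expect_identical(seasonal_filter(kept), kept)  # idempotent
  none <- seasonal_filter(cups, months = 12)
  expect_equal(nrow(none), 0)
})

test_that("edge_config rejects inconsistent thresholds", {
  expect_error(edge_config(edge_threshold_pct = 0), "0, 100")
  expect_error(edge_config(bin_edges_km = c(0, 80, 40)), "increasing")
  expect_error(edge_config(far_exclusion_km = 80), "exceed")
})
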