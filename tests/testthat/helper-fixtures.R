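# Small in-code fixtures shared across the suite. Everything is built at
# test time; nothing is read from disk.

# Compact 2-year domain for fast end-to-end runs.
tiny_domain <- function(seed = 1L, ...) {
  domain_config(x_extent_km = c(0, 700), y_extent_km = c(0, 300),
                cell_km = 50,
                start_date = "2000-01-01", end_date = "2001-12-31",
                shelf_x_km = c(500, 700), mooring_xy_km = c(100, 150),
                gate_xy_km = c(250, 150), seed = seed, ...)
}

# Scenario with every noise source switched off.
quiet_scenario <- function(...) {
  args <- list(drift_noise_sd = 0, conc_noise_cv = 0, temp_noise_sd = 0,
               edge_noise_km = 0, flux_noise_cv = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(scenario_params, args)
}

# Drift stack with spatially/temporally constant velocity per product.
# `uv` is a list of c(u, v) per product; `gap_months` masks product 1.
uniform_stack <- function(domain, uv = list(c(-5, 0), c(-5, 0), c(-5, 0)),
                          gap_months = integer(0)) {
  ny <- length(domain$y); nx <- length(domain$x); nt <- length(domain$dates)
  months <- as.POSIXlt(domain$dates)$mon + 1
  products <- lapply(seq_along(uv), function(k) {
    avail <- array(TRUE, c(ny, nx, nt))
    if (k == 1 && length(gap_months))
      avail[, , months %in% gap_months] <- FALSE
    list(name = paste0("drift", k),
         u = array(uv[[k]][1], c(ny, nx, nt)),
         v = array(uv[[k]][2], c(ny, nx, nt)),
         available = avail)
  })
  structure(list(x = domain$x, y = domain$y, dates = domain$dates,
                 products = products), class = "drift_stack")
}

# Concentration field from a function of (x, date_index) or a constant.
conc_field <- function(domain, value) {
  ny <- length(domain$y); nx <- length(domain$x); nt <- length(domain$dates)
  arr <- array(NA_real_, c(ny, nx, nt))
  for (it in seq_len(nt)) {
    v <- if (is.function(value)) value(domain$x, it) else rep(value, nx)
    arr[, , it] <- matrix(v, ny, nx, byrow = TRUE)
  }
  iceballast:::new_ice_field(domain, arr, "concentration", "%")
}

# Hand-built trajectory (daily backward steps) for ice-state tests.
fake_trajectory <- function(temps, reason = "formed",
                            start_date = as.Date("2001-03-01"),
                            xs = NULL, ys = NULL, step = 1) {
  n <- length(temps)
  if (is.null(xs)) xs <- seq(0, by = 5, length.out = n)
  if (is.null(ys)) ys <- rep(0, n)
  conc <- c(rep(100, n - 1), if (reason == "formed") 10 else 100)
  structure(list(
    samples = data.frame(date = start_date - step * (seq_len(n) - 1),
                         x_km = xs, y_km = ys,
                         concentration_pct = conc, t2m_c = temps,
                         product_id = c(rep(1L, n - 1), NA)),
    reason = reason, start = c(xs[1], ys[1]), start_date = start_date,
    step_days = step), class = "ice_trajectory")
}

# Brute-force Mann-Kendall S by explicit double loop (independent oracle).
brute_S <- function(x) {
  s <- 0
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) s <- s + sign(x[j] - x[i])
  s
}
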