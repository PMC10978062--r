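# Synthetic-Arctic scenario generator.
#
# Every generator derives an independent RNG stream from domain$seed (or an
# explicit seed argument) via withr::with_seed, so identical configuration
# gives bit-identical output and no global RNG state leaks.

SEED_DRIFT <- 101L
SEED_CONC <- 202L
SEED_TEMP <- 303L
SEED_FLUX <- 404L

#' Generate a prioritized stack of gridded ice-drift products
#'
#' Three drift products observe the same underlying idealized Transpolar
#' Drift field (spatially uniform mean flow) with independent per-cell,
#' per-day velocity noise. The highest-priority product is unavailable every
#' June and July, emulating the summer gap of scatterometer-based motion
#' estimates that the tracking algorithm bridges with the lower-priority
#' products; products 2 and 3 are complete.
#'
#' @param domain a [domain_config()].
#' @param scenario a [scenario_params()].
#' @return A `drift_stack`: grid axes, calendar and an ordered list of three
#'   products, each with `u`, `v` velocity arrays (km/day, indexed
#'   y-by-x-by-day) and a logical `available` array of the same shape.
#'   Priority is list order.
#' @examples
#' dom <- domain_config(end_date = "2002-12-31", cell_km = 200)
#' stack <- make_drift_stack(dom, scenario_params(drift_noise_sd = 0))
#' stack
#' @export
make_drift_stack <- function(domain, scenario) {
  stopifnot(inherits(domain, "domain_config"),
            inherits(scenario, "scenario_params"))
  ny <- length(domain$y); nx <- length(domain$x); nt <- length(domain$dates)
  theta <- scenario$drift_direction_deg * pi / 180
  u0 <- scenario$drift_speed_km_day * cos(theta)
  v0 <- scenario$drift_speed_km_day * sin(theta)
  months <- month_of(domain$dates)
  gap <- months %in% c(6L, 7L)  # priority-1 product missing June-July
  products <- withr::with_seed(domain$seed + SEED_DRIFT, {
    lapply(1:3, function(k) {
      noise_u <- if (scenario$drift_noise_sd > 0)
        array(rnorm(ny * nx * nt, 0, scenario$drift_noise_sd), c(ny, nx, nt))
      else array(0, c(ny, nx, nt))
      noise_v <- if (scenario$drift_noise_sd > 0)
        array(rnorm(ny * nx * nt, 0, scenario$drift_noise_sd), c(ny, nx, nt))
      else array(0, c(ny, nx, nt))
      avail <- array(TRUE, c(ny, nx, nt))
      if (k == 1L) avail[, , gap] <- FALSE
      list(name = paste0("drift", k),
           u = u0 + noise_u, v = v0 + noise_v, available = avail)
    })
  })
  structure(list(x = domain$x, y = domain$y, dates = domain$dates,
                 products = products),
            class = "drift_stack")
}

#' @export
print.drift_stack <- function(x, ...) {
  cat(sprintf("<drift_stack> %d products, %d x %d cells, %d days\n",
              length(x$products), length(x$x), length(x$y), length(x$dates)))
  for (k in seq_along(x$products)) {
    p <- x$products[[k]]
    cat(sprintf("  [%d] %s: %.1f%% available\n", k, p$name,
                100 * mean(p$available)))
  }
  invisible(x)
}

# Ice-edge x-position (km) for each date: seasonal sine about the mooring
# (westernmost in early June, giving the configured peak cover there) plus a
# random monthly offset. Concentration ramps up east of this position.
edge_position <- function(domain, scenario, dates) {
  doy <- day_of_year(dates)
  s <- sin(2 * pi * (doy - 60) / 365.25)
  ym <- year_of(dates) * 100L + month_of(dates)
  keys <- sort(unique(ym))
  offs <- rnorm(length(keys), 0, scenario$edge_noise_km)
  eta <- offs[match(ym, keys)]
  domain$mooring_xy_km[1] - scenario$edge_migration_km * s + eta
}

# Open-water factor in [0, 1]: 1 in the ice season, 0 between melt-out and
# freeze-up (with 10-day linear ramps). Freeze-up may be delayed linearly
# over the years of the series.
melt_factor <- function(scenario, dates) {
  doy <- day_of_year(dates)
  yr <- year_of(dates)
  fz <- scenario$freezeup_doy +
    scenario$freezeup_delay_days_per_year * (yr - min(yr))
  fz <- pmin(fz, 360)
  m0 <- scenario$meltout_doy
  ramp <- 10
  f <- rep(1, length(dates))
  f[doy >= m0 - ramp & doy < m0] <- (m0 - doy[doy >= m0 - ramp & doy < m0]) / ramp
  f[doy >= m0 & doy < fz] <- 0
  up <- doy >= fz & doy < fz + ramp
  f[up] <- (doy[up] - fz[up]) / ramp
  f
}

#' Generate the daily sea-ice concentration field
#'
#' Concentration (%) increases linearly eastward from the seasonally
#' migrating ice-edge position to full cover over a fixed ramp width, is
#' multiplied by an open-water factor that makes the whole domain ice-free
#' between melt-out (default Sep 1) and freeze-up (default Oct 15), and
#' carries multiplicative noise. At the mooring the interval-integrated cover
#' rises from ~0-5% in late winter to the configured peak (default 20%) in
#' early June and is exactly 0% in September.
#'
#' @inheritParams make_drift_stack
#' @return An `ice_field` named `"concentration"` with values in \[0, 100\] %.
#' @export
make_concentration_field <- function(domain, scenario) {
  stopifnot(inherits(domain, "domain_config"),
            inherits(scenario, "scenario_params"))
  ny <- length(domain$y); nx <- length(domain$x); nt <- length(domain$dates)
  ramp_w <- if (scenario$conc_amplitude_pct > 0)
    scenario$edge_migration_km / (scenario$conc_amplitude_pct / 100)
  else Inf
  arr <- withr::with_seed(domain$seed + SEED_CONC, {
    e <- edge_position(domain, scenario, domain$dates)
    f <- melt_factor(scenario, domain$dates)
    a <- array(0, c(ny, nx, nt))
    for (it in seq_len(nt)) {
      frac <- pmin(pmax((domain$x - e[it]) / ramp_w, 0), 1)
      a[, , it] <- matrix(100 * frac * f[it], ny, nx, byrow = TRUE)
    }
    if (scenario$conc_noise_cv > 0) {
      a <- a * (1 + array(rnorm(length(a), 0, scenario$conc_noise_cv), dim(a)))
    }
    pmin(pmax(a, 0), 100)
  })
  new_ice_field(domain, arr, "concentration", "%")
}

#' Generate the daily 2 m air-temperature field
#'
#' Spatially uniform sinusoidal annual cycle between the configured winter
#' and summer extremes (summer peak at day-of-year 196, mid July), plus
#' additive per-cell noise.
#'
#' @inheritParams make_drift_stack
#' @return An `ice_field` named `"t2m"` in degrees C.
#' @export
make_airtemp_field <- function(domain, scenario) {
  stopifnot(inherits(domain, "domain_config"),
            inherits(scenario, "scenario_params"))
  ny <- length(domain$y); nx <- length(domain$x); nt <- length(domain$dates)
  mid <- (scenario$winter_temp_c + scenario$summer_temp_c) / 2
  amp <- (scenario$summer_temp_c - scenario$winter_temp_c) / 2
  doy <- day_of_year(domain$dates)
  base <- mid + amp * cos(2 * pi * (doy - 196) / 365.25)
  arr <- withr::with_seed(domain$seed + SEED_TEMP, {
    a <- array(rep(base, each = ny * nx), c(ny, nx, nt))
    if (scenario$temp_noise_sd > 0)
      a <- a + array(rnorm(length(a), 0, scenario$temp_noise_sd), dim(a))
    a
  })
  new_ice_field(domain, arr, "t2m", "degC")
}

#' Generate the static bathymetry grid
#'
#' Cells whose centers fall inside the shelf rectangle get the shelf depth
#' (< 100 m); all others the basin depth (> 100 m). Depths are positive-down
#' metres, and 100 m itself is never generated (the shelf/off-shelf regimes
#' are defined by strict inequalities).
#'
#' @param domain a [domain_config()].
#' @return A `depth_grid`: grid axes and a depth matrix indexed y-by-x.
#' @export
make_bathymetry <- function(domain) {
  stopifnot(inherits(domain, "domain_config"))
  in_x <- domain$x >= domain$shelf_x_km[1] & domain$x <= domain$shelf_x_km[2]
  in_y <- domain$y >= domain$shelf_y_km[1] & domain$y <= domain$shelf_y_km[2]
  depth <- matrix(domain$basin_depth_m, length(domain$y), length(domain$x))
  depth[in_y, in_x] <- domain$shelf_depth_m
  structure(list(x = domain$x, y = domain$y, depth = depth),
            class = "depth_grid")
}

#' @export
print.depth_grid <- function(x, ...) {
  cat(sprintf("<depth_grid> %d x %d cells; depths %g-%g m (%.0f%% shelf < 100 m)\n",
              length(x$x), length(x$y), min(x$depth), max(x$depth),
              100 * mean(x$depth < 100)))
  invisible(x)
}

#' Sediment-trap cup collection intervals for a domain calendar
#'
#' Every complete calendar month in the domain span is covered: productive
#' months (March-September) are split into two cups (day 1-15 and the
#' remainder), all other months get one month-long cup. All intervals fall
#' in the 10-31 day range of sequencing sediment-trap deployments. Intervals
#' are half-open: a cup collects from `start` up to but excluding `end`.
#'
#' @param domain a [domain_config()].
#' @return A data.frame with `start`, `end` (Date) and `days`.
#' @export
cup_intervals <- function(domain) {
  stopifnot(inherits(domain, "domain_config"))
  firsts <- seq(as.Date(format(domain$start_date, "%Y-%m-01")),
                domain$end_date, by = "month")
  if (firsts[1] < domain$start_date) firsts <- firsts[-1]
  starts <- ends <- as.Date(character(0))
  for (m1 in as.list(firsts)) {
    m2 <- seq(m1, by = "month", length.out = 2)[2]
    if (m2 - 1 > domain$end_date) next  # incomplete trailing month
    if (month_of(m1) %in% 3:9) {
      mid <- m1 + 15
      starts <- c(starts, m1, mid); ends <- c(ends, mid, m2)
    } else {
      starts <- c(starts, m1); ends <- c(ends, m2)
    }
  }
  data.frame(start = starts, end = ends,
             days = as.integer(ends - starts))
}

#' Generate a synthetic sediment-trap flux series
#'
#' For the cup intervals of the domain (see [cup_intervals()]) and one mean
#' ice-edge distance per cup, generates terrigenous marker and POC fluxes
#' with the structure the downstream analysis assumes:
#'
#' * the mean terrigenous flux decays with edge distance (e-folding
#'   `edge_decay_km`, plus a background floor) — ice-rafted sediment is
#'   released where ice melts, near the edge;
#' * the mean terrigenous flux declines linearly across years by the
#'   configured `terrigenous_decline` fraction (first-year mean times
#'   `1 - decline` in the final year);
#' * mean POC flux is a baseline plus a ballast term proportional to the
#'   terrigenous mean, scaled so that the near-edge/far-from-edge mean POC
#'   ratio equals `ballast_effect`;
#' * both fluxes carry independent multiplicative lognormal noise with
#'   mean 1 and coefficient of variation `flux_noise_cv`.
#'
#' A *Phaeocystis*-like OTU relative abundance covarying with edge proximity
#' is included for completeness.
#'
#' @inheritParams make_drift_stack
#' @param edge_distances numeric vector, one mean ice-edge distance (km) per
#'   cup interval; `NA` marks intervals with no ice edge in the domain
#'   (treated as infinitely far for the flux model).
#' @return A `cup_table` data.frame: `cup_id`, `start`, `end`, `days`,
#'   `edge_distance_km`, `poc_flux`, `terr_flux` (mg m^-2 d^-1),
#'   `otu_rel_abundance`.
#' @export
make_flux_series <- function(domain, scenario, edge_distances) {
  stopifnot(inherits(domain, "domain_config"),
            inherits(scenario, "scenario_params"))
  iv <- cup_intervals(domain)
  if (nrow(iv) == 0) stop("empty cup interval list for this domain span")
  if (length(edge_distances) != nrow(iv))
    stop(sprintf("need one edge distance per cup interval (%d != %d)",
                 length(edge_distances), nrow(iv)))
  yr <- year_of(iv$start)
  n_years <- max(yr) - min(yr) + 1
  decline_factor <- if (n_years > 1)
    1 - scenario$terrigenous_decline * (yr - min(yr)) / (n_years - 1)
  else rep(1, nrow(iv))
  d_factor <- ifelse(is.na(edge_distances), 0,
                     exp(-edge_distances / scenario$edge_decay_km))
  floorf <- scenario$terr_floor_frac
  terr_mean <- scenario$terr_base_flux * decline_factor *
    (floorf + (1 - floorf) * d_factor)
  r <- scenario$ballast_effect
  if (r * floorf >= 1)
    stop("ballast_effect * terr_floor_frac must be < 1")
  b <- scenario$poc_base_flux * (r - 1) /
    (scenario$terr_base_flux * (1 - r * floorf))
  poc_mean <- scenario$poc_base_flux + b * terr_mean
  otu_mean <- 0.02 + 0.2 * d_factor
  cv <- scenario$flux_noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  withr::with_seed(domain$seed + SEED_FLUX, {
    n <- nrow(iv)
    noise <- function() rlnorm(n, -sdlog^2 / 2, sdlog)
    out <- data.frame(
      cup_id = seq_len(n),
      start = iv$start, end = iv$end, days = iv$days,
      edge_distance_km = as.numeric(edge_distances),
      poc_flux = poc_mean * noise(),
      terr_flux = terr_mean * noise(),
      otu_rel_abundance = pmin(pmax(otu_mean * noise(), 0), 1))
    class(out) <- c("cup_table", "data.frame")
    out
  })
}

#' Ballast multiplier of settling velocity for a gypsum crystal class
#'
#' Large crystals (> 63 um) multiply the settling velocity by a constant
#' factor over the whole 15 h incubation; small crystals (30-63 um) give a
#' short-lived enhancement that decays back to 1 within roughly 5-7 h after
#' addition (rapid dissolution); controls and ice-free particles are
#' unaffected.
#'
#' @param crystal_class one of `"none"`, `"small"`, `"large"`.
#' @param timepoint_h hours since gypsum addition.
#' @param large_multiplier constant velocity factor of the large class
#'   (default 10).
#' @param small_multiplier initial velocity factor of the small class
#'   (default 3).
#' @param small_decay_h decay scale (h) of the small-class enhancement.
#' @return Numeric multiplier (>= 1).
#' @export
ballast_multiplier <- function(crystal_class, timepoint_h,
                               large_multiplier = 10,
                               small_multiplier = 3,
                               small_decay_h = 5) {
  crystal_class <- match.arg(crystal_class, c("none", "small", "large"))
  switch(crystal_class,
         none = rep(1, length(timepoint_h)),
         large = rep(large_multiplier, length(timepoint_h)),
         small = 1 + (small_multiplier - 1) *
           exp(-(timepoint_h / small_decay_h)^4))
}

#' Generate synthetic roller-tank particle tracks
#'
#' Each particle gets a true settling velocity (lognormal spread around
#' `v_mean_m_day`, scaled by the [ballast_multiplier()] of its treatment,
#' crystal class and time point) and a depth-time series sampled every
#' `dt_s` seconds for `duration_s` seconds, with additive Gaussian position
#' noise. The OLS slope of depth on time recovers the effective velocity.
#'
#' @param n_particles particles per call (>= 1), assigned round-robin to the
#'   incubation time points.
#' @param treatment `"control"` or `"gypsum"`.
#' @param crystal_class `"none"` (control), `"small"` (30-63 um) or
#'   `"large"` (> 63 um).
#' @param seed integer seed.
#' @param timepoints_h incubation time points (h); default the 3, 5, 7, 10,
#'   15 h observation schedule.
#' @param v_mean_m_day mean true settling velocity of unballasted particles
#'   (m/day).
#' @param v_cv between-particle coefficient of variation of the true
#'   velocity (0 for identical particles).
#' @param noise_sd_mm additive position noise sd (mm).
#' @param duration_s,dt_s video duration and sampling step (s).
#' @param diameter_mean_um,diameter_cv equivalent spherical diameter
#'   distribution.
#' @inheritParams ballast_multiplier
#' @return A `particle_tracks` data.frame in long form: `particle_id`,
#'   `treatment`, `crystal_class`, `timepoint_h`, `diameter_um`, `t_s`,
#'   `z_mm` (depth, positive down).
#' @export
make_particle_tracks <- function(n_particles, treatment, crystal_class, seed,
                                 timepoints_h = c(3, 5, 7, 10, 15),
                                 v_mean_m_day = 20, v_cv = 0.3,
                                 large_multiplier = 10, small_multiplier = 3,
                                 small_decay_h = 5,
                                 noise_sd_mm = 0.3,
                                 duration_s = 60, dt_s = 2,
                                 diameter_mean_um = 1500, diameter_cv = 0.4) {
  if (!is.numeric(n_particles) || n_particles < 1)
    stop("`n_particles` must be >= 1")
  n_particles <- as.integer(n_particles)
  treatment <- match.arg(treatment, c("control", "gypsum"))
  crystal_class <- match.arg(crystal_class, c("none", "small", "large"))
  if (treatment == "control" && crystal_class != "none")
    stop("control tracks carry no gypsum: use crystal_class = \"none\"")
  if (treatment == "gypsum" && crystal_class == "none")
    stop("gypsum tracks need crystal_class \"small\" or \"large\"")
  withr::with_seed(as.integer(seed), {
    tp <- timepoints_h[(seq_len(n_particles) - 1L) %% length(timepoints_h) + 1L]
    sdl <- sqrt(log(1 + v_cv^2))
    v_true <- v_mean_m_day * rlnorm(n_particles, -sdl^2 / 2, sdl)
    mult <- ballast_multiplier(crystal_class, tp, large_multiplier,
                               small_multiplier, small_decay_h)
    sdd <- sqrt(log(1 + diameter_cv^2))
    diam <- diameter_mean_um * rlnorm(n_particles, -sdd^2 / 2, sdd)
    tgrid <- seq(0, duration_s, by = dt_s)
    out <- do.call(rbind, lapply(seq_len(n_particles), function(i) {
      v_mm_s <- v_true[i] * mult[i] * 1000 / 86400
      z <- v_mm_s * tgrid
      if (noise_sd_mm > 0) z <- z + rnorm(length(tgrid), 0, noise_sd_mm)
      data.frame(particle_id = i, treatment = treatment,
                 crystal_class = crystal_class, timepoint_h = tp[i],
                 diameter_um = diam[i], t_s = tgrid, z_mm = z)
    }))
    class(out) <- c("particle_tracks", "data.frame")
    out
  })
}
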