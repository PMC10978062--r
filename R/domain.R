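#' Synthetic-Arctic domain configuration
#'
#' Defines the planar Cartesian study domain shared by all generated fields:
#' grid extent and resolution (km), daily calendar, a shallow shelf rectangle
#' where ice formation entrains terrigenous sediment, the deep basin, the
#' sediment-trap mooring, and the export gate where backward tracking starts.
#'
#' Geometry is deliberately idealized: distances are Euclidean km on a plane,
#' the shelf is an axis-aligned rectangle with uniform depth strictly below
#' 100 m, and the rest of the domain has uniform basin depth strictly above
#' 100 m, so the shelf/off-shelf classification threshold never sits on a
#' generated value.
#'
#' @param x_extent_km,y_extent_km numeric length-2, domain extent in km.
#' @param cell_km grid cell size in km (cell centers are offset half a cell
#'   from the domain edge).
#' @param start_date,end_date `Date` (or coercible); the daily calendar.
#'   Must span at least 2 full years.
#' @param shelf_x_km,shelf_y_km numeric length-2, the shelf rectangle.
#' @param shelf_depth_m shelf water depth, must be < 100 m.
#' @param basin_depth_m basin water depth, must be > 100 m.
#' @param mooring_xy_km,gate_xy_km numeric length-2 positions (km) of the
#'   sediment-trap mooring and of the ice-export gate used as the tracking
#'   start.
#' @param seed integer base seed; all generators derive their streams from it
#'   so that identical configuration implies bit-identical output.
#'
#' @return An object of class `domain_config`: a list with the fields above
#'   plus derived grid axes `x`, `y` (cell centers) and `dates`.
#' @examples
#' dom <- domain_config(end_date = "2002-12-31")
#' dom
#' @export
domain_config <- function(x_extent_km = c(0, 1400),
                          y_extent_km = c(0, 600),
                          cell_km = 50,
                          start_date = "2000-01-01",
                          end_date = "2013-12-31",
                          shelf_x_km = c(1000, 1400),
                          shelf_y_km = y_extent_km,
                          shelf_depth_m = 50,
                          basin_depth_m = 2500,
                          mooring_xy_km = c(100, 300),
                          gate_xy_km = c(400, 300),
                          seed = 1L) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  stopifnot(length(x_extent_km) == 2, length(y_extent_km) == 2,
            diff(x_extent_km) > 0, diff(y_extent_km) > 0)
  if (!is.numeric(cell_km) || cell_km <= 0)
    stop("`cell_km` must be a positive number")
  if (!(shelf_depth_m < 100))
    stop("`shelf_depth_m` must be < 100 m (shelf regime)")
  if (!(basin_depth_m > 100))
    stop("`basin_depth_m` must be > 100 m (basin regime)")
  if (as.numeric(end_date - start_date) < 730)
    stop("time span must cover at least 2 full years")
  x <- grid_centers(x_extent_km, cell_km)
  y <- grid_centers(y_extent_km, cell_km)
  if (length(x) < 2 || length(y) < 2)
    stop("degenerate grid: need at least 2 cells per axis")
  if (diff(shelf_x_km) <= 0 || diff(shelf_y_km) <= 0)
    stop("shelf rectangle is empty")
  if (shelf_x_km[1] >= x_extent_km[2] || shelf_x_km[2] <= x_extent_km[1] ||
      shelf_y_km[1] >= y_extent_km[2] || shelf_y_km[2] <= y_extent_km[1])
    stop("shelf rectangle lies outside the domain")
  in_dom <- function(p) p[1] >= x_extent_km[1] && p[1] <= x_extent_km[2] &&
    p[2] >= y_extent_km[1] && p[2] <= y_extent_km[2]
  if (!in_dom(mooring_xy_km) || !in_dom(gate_xy_km))
    stop("mooring and gate positions must lie inside the domain")
  structure(list(
    x_extent_km = x_extent_km, y_extent_km = y_extent_km, cell_km = cell_km,
    start_date = start_date, end_date = end_date,
    shelf_x_km = shelf_x_km, shelf_y_km = shelf_y_km,
    shelf_depth_m = shelf_depth_m, basin_depth_m = basin_depth_m,
    mooring_xy_km = mooring_xy_km, gate_xy_km = gate_xy_km,
    seed = as.integer(seed),
    x = x, y = y,
    dates = seq(start_date, end_date, by = "day")
  ), class = "domain_config")
}

grid_centers <- function(extent, cell) {
  n <- floor(diff(extent) / cell + 1e-9)
  extent[1] + cell / 2 + cell * seq_len(n) - cell
}

#' @export
print.domain_config <- function(x, ...) {
  cat("<domain_config>\n")
  cat(sprintf("  grid: %d x %d cells of %g km (x: %g-%g, y: %g-%g km)\n",
              length(x$x), length(x$y), x$cell_km,
              x$x_extent_km[1], x$x_extent_km[2],
              x$y_extent_km[1], x$y_extent_km[2]))
  cat(sprintf("  calendar: %s to %s (%d days)\n",
              format(x$start_date), format(x$end_date), length(x$dates)))
  cat(sprintf("  shelf: x %g-%g km at %g m; basin %g m\n",
              x$shelf_x_km[1], x$shelf_x_km[2], x$shelf_depth_m,
              x$basin_depth_m))
  cat(sprintf("  mooring (%g, %g) km; export gate (%g, %g) km; seed %d\n",
              x$mooring_xy_km[1], x$mooring_xy_km[2],
              x$gate_xy_km[1], x$gate_xy_km[2], x$seed))
  invisible(x)
}

#' Scenario parameters of the synthetic generator
#'
#' Tunable knobs of the idealized Transpolar-Drift scenario. Defaults encode
#' the study conditions the analysis is designed around: ice drifting toward
#' the export gate and mooring, a seasonally migrating ice edge whose
#' interval-integrated cover at the mooring peaks near 20% in early summer
#' and drops to 0% in September, winter air temperatures cold enough for
#' substantial freezing-degree-day ice growth, a > 80% terrigenous-flux
#' decline across the series, and near-edge POC export elevated by ~30%
#' relative to far-from-edge conditions.
#'
#' @param drift_speed_km_day mean drift speed of the idealized Transpolar
#'   Drift (km/day).
#' @param drift_direction_deg drift direction, degrees counterclockwise from
#'   the +x axis (180 = toward the mooring at low x).
#' @param drift_noise_sd per-cell, per-day standard deviation of the velocity
#'   noise each drift product adds to the shared true field (km/day).
#' @param conc_amplitude_pct seasonal concentration amplitude: the early-June
#'   peak ice cover at the mooring (%). 0 gives a time-constant (ice-free)
#'   field.
#' @param edge_migration_km seasonal excursion of the ice-edge position about
#'   the mooring (km).
#' @param edge_noise_km standard deviation of the random monthly offset of
#'   the edge position (km); drives year-to-year variability of edge
#'   distances.
#' @param conc_noise_cv multiplicative coefficient of variation of the
#'   concentration field noise.
#' @param winter_temp_c,summer_temp_c annual 2 m air-temperature extremes
#'   (degrees C).
#' @param temp_noise_sd additive air-temperature noise sd (degrees C).
#' @param freezeup_doy day-of-year of autumn freeze-up (concentration
#'   returns after the open-water season); default Oct 15.
#' @param meltout_doy day-of-year at which the open-water season begins;
#'   default Sep 1, so September is ice-free.
#' @param freezeup_delay_days_per_year linear trend in freeze-up timing
#'   (days/year); positive values delay freeze-up over the series, moving
#'   the formation zone of exported ice off the shelf.
#' @param terrigenous_decline fraction in \[0, 1\] by which the mean
#'   terrigenous marker flux declines from the first to the last year.
#' @param ballast_effect ratio of mean POC flux at the ice edge (distance 0)
#'   to mean POC flux far from the edge; 1 disables the ballast coupling.
#' @param flux_noise_cv lognormal coefficient of variation of the flux noise.
#' @param terr_base_flux,poc_base_flux mean terrigenous marker and baseline
#'   POC fluxes (mg m^-2 d^-1) at the ice edge in the first year.
#' @param edge_decay_km e-folding distance (km) of the ice-edge influence on
#'   terrigenous release.
#' @param terr_floor_frac background fraction of terrigenous flux present
#'   even far from the edge.
#'
#' @return An object of class `scenario_params` (a validated list).
#' @examples
#' scenario_params(terrigenous_decline = 0)
#' @export
scenario_params <- function(drift_speed_km_day = 5,
                            drift_direction_deg = 180,
                            drift_noise_sd = 1,
                            conc_amplitude_pct = 20,
                            edge_migration_km = 60,
                            edge_noise_km = 25,
                            conc_noise_cv = 0.05,
                            winter_temp_c = -30,
                            summer_temp_c = 5,
                            temp_noise_sd = 1.5,
                            freezeup_doy = 288,
                            meltout_doy = 244,
                            freezeup_delay_days_per_year = 0,
                            terrigenous_decline = 0.8,
                            ballast_effect = 1.3,
                            flux_noise_cv = 0.15,
                            terr_base_flux = 5,
                            poc_base_flux = 10,
                            edge_decay_km = 40,
                            terr_floor_frac = 0.1) {
  p <- list(drift_speed_km_day = drift_speed_km_day,
            drift_direction_deg = drift_direction_deg,
            drift_noise_sd = drift_noise_sd,
            conc_amplitude_pct = conc_amplitude_pct,
            edge_migration_km = edge_migration_km,
            edge_noise_km = edge_noise_km,
            conc_noise_cv = conc_noise_cv,
            winter_temp_c = winter_temp_c,
            summer_temp_c = summer_temp_c,
            temp_noise_sd = temp_noise_sd,
            freezeup_doy = freezeup_doy,
            meltout_doy = meltout_doy,
            freezeup_delay_days_per_year = freezeup_delay_days_per_year,
            terrigenous_decline = terrigenous_decline,
            ballast_effect = ballast_effect,
            flux_noise_cv = flux_noise_cv,
            terr_base_flux = terr_base_flux,
            poc_base_flux = poc_base_flux,
            edge_decay_km = edge_decay_km,
            terr_floor_frac = terr_floor_frac)
  rates <- c(drift_speed_km_day, drift_noise_sd, conc_amplitude_pct,
             edge_migration_km, edge_noise_km, conc_noise_cv, temp_noise_sd,
             flux_noise_cv, terr_base_flux, poc_base_flux, edge_decay_km)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and non-negative")
  if (!is.finite(terrigenous_decline) ||
      terrigenous_decline < 0 || terrigenous_decline > 1)
    stop("`terrigenous_decline` must lie in [0, 1]")
  if (!is.finite(ballast_effect) || ballast_effect < 1)
    stop("`ballast_effect` is a near/far mean POC ratio and must be >= 1")
  if (summer_temp_c <= winter_temp_c)
    stop("`summer_temp_c` must exceed `winter_temp_c`")
  if (terr_floor_frac < 0 || terr_floor_frac >= 1)
    stop("`terr_floor_frac` must lie in [0, 1)")
  structure(p, class = "scenario_params")
}

#' @export
print.scenario_params <- function(x, ...) {
  cat("<scenario_params>\n")
  cat(sprintf("  drift %g km/day @ %g deg, product noise sd %g\n",
              x$drift_speed_km_day, x$drift_direction_deg, x$drift_noise_sd))
  cat(sprintf("  ice edge: peak mooring cover %g%%, migration %g km, monthly sd %g km\n",
              x$conc_amplitude_pct, x$edge_migration_km, x$edge_noise_km))
  cat(sprintf("  air temp %g to %g degC; freeze-up doy %d (+%g d/yr)\n",
              x$winter_temp_c, x$summer_temp_c, x$freezeup_doy,
              x$freezeup_delay_days_per_year))
  cat(sprintf("  fluxes: terrigenous decline %g, ballast effect %g, noise cv %g\n",
              x$terrigenous_decline, x$ballast_effect, x$flux_noise_cv))
  invisible(x)
}

# ---- internal grid/date helpers ------------------------------------------

day_of_year <- function(dates) as.POSIXlt(dates)$yday + 1

year_of <- function(dates) as.POSIXlt(dates)$year + 1900

month_of <- function(dates) as.POSIXlt(dates)$mon + 1

date_index <- function(dates, date) {
  i <- as.integer(as.Date(date) - dates[1]) + 1L
  i[i < 1L | i > length(dates)] <- NA_integer_
  i
}

# Bilinear interpolation on a regular grid. Z is indexed [y, x]. Points
# outside the cell-center hull return NA. Cross-checked against
# pracma::interp2 in the test suite.
bilinear <- function(xax, yax, Z, px, py) {
  nx <- length(xax); ny <- length(yax)
  if (is.na(px) || is.na(py) ||
      px < xax[1] || px > xax[nx] || py < yax[1] || py > yax[ny])
    return(NA_real_)
  hx <- xax[2] - xax[1]; hy <- yax[2] - yax[1]
  i <- min(max(floor((px - xax[1]) / hx) + 1, 1), nx - 1)
  j <- min(max(floor((py - yax[1]) / hy) + 1, 1), ny - 1)
  wx <- (px - xax[i]) / hx
  wy <- (py - yax[j]) / hy
  (1 - wy) * ((1 - wx) * Z[j, i] + wx * Z[j, i + 1]) +
    wy * ((1 - wx) * Z[j + 1, i] + wx * Z[j + 1, i + 1])
}

# Index of the cell containing a point (cells are [center - h/2, center + h/2)).
cell_of <- function(ax, p) {
  h <- ax[2] - ax[1]
  i <- round((p - ax[1]) / h) + 1
  ifelse(i < 1 | i > length(ax), NA_integer_, as.integer(i))
}

inside_domain <- function(domain, px, py) {
  px >= domain$x[1] && px <= domain$x[length(domain$x)] &&
    py >= domain$y[1] && py <= domain$y[length(domain$y)]
}

# ---- gridded field container ---------------------------------------------

new_ice_field <- function(domain, data, name, units) {
  stopifnot(identical(dim(data),
                      c(length(domain$y), length(domain$x),
                        length(domain$dates))))
  structure(list(x = domain$x, y = domain$y, dates = domain$dates,
                 data = data, name = name, units = units),
            class = "ice_field")
}

#' @export
print.ice_field <- function(x, ...) {
  cat(sprintf("<ice_field> %s [%s]: %d x %d cells, %d days (%s to %s)\n",
              x$name, x$units, length(x$x), length(x$y), length(x$dates),
              format(x$dates[1]), format(x$dates[length(x$dates)])))
  rng <- range(x$data, na.rm = TRUE)
  cat(sprintf("  range: %.3g to %.3g\n", rng[1], rng[2]))
  invisible(x)
}

#' Sample a gridded daily field at a point and date
#'
#' Bilinear interpolation in space on the nearest-day slice (fields are daily
#' composites; no temporal interpolation).
#'
#' @param field an `ice_field`.
#' @param date a `Date` within the field calendar.
#' @param px,py point coordinates in km.
#' @return Interpolated value, or `NA` outside the grid.
#' @export
field_value <- function(field, date, px, py) {
  it <- date_index(field$dates, date)
  if (is.na(it)) stop("date outside field calendar: ", format(as.Date(date)))
  bilinear(field$x, field$y, field$data[, , it], px, py)
}
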