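#' Tracker configuration for backward sea-ice tracing
#'
#' @param start_xy_km default start position (km), typically the export gate.
#' @param start_dates optional vector of trace start dates. `NULL` (default)
#'   makes [batch_backtrack()] start one trace on the first of every month of
#'   the drift-stack calendar.
#' @param step_days backward integration step (days, > 0). Drift products
#'   are daily composites, so the default step of 1 day matches their
#'   resolution; it stays configurable for convergence checks.
#' @param conc_threshold_pct ice-concentration threshold (%) below which the
#'   trace terminates and the position is taken as where the ice formed
#'   (default 25).
#' @param max_duration_days maximum trace length (days); also the reported
#'   termination reason when a trace reaches the start of the motion record.
#' @param search_radius_cells spatial search radius (grid cells) for a valid
#'   motion vector when the interpolation cell of a product is unavailable.
#' @return A `tracker_config` list.
#' @export
tracker_config <- function(start_xy_km = c(400, 300),
                           start_dates = NULL,
                           step_days = 1,
                           conc_threshold_pct = 25,
                           max_duration_days = 3650,
                           search_radius_cells = 1L) {
  if (!(conc_threshold_pct > 0 && conc_threshold_pct < 100))
    stop("`conc_threshold_pct` must lie in (0, 100)")
  if (step_days <= 0) stop("`step_days` must be > 0")
  if (search_radius_cells < 0) stop("`search_radius_cells` must be >= 0")
  if (!is.null(start_dates)) start_dates <- as.Date(start_dates)
  structure(list(start_xy_km = start_xy_km, start_dates = start_dates,
                 step_days = step_days,
                 conc_threshold_pct = conc_threshold_pct,
                 max_duration_days = max_duration_days,
                 search_radius_cells = as.integer(search_radius_cells)),
            class = "tracker_config")
}

#' Sample ice drift from a prioritized product stack
#'
#' Walks the products in priority order. For each product the velocity is the
#' bilinear interpolation of its daily (u, v) grids at the query position; it
#' is used when the cell containing the position is available on that day.
#' If not, the nearest available cell within the search radius supplies its
#' cell value; failing that, the next product is tried. The identifier of the
#' product actually used is returned, so fallback behaviour can be audited.
#'
#' @param stack a `drift_stack` from [make_drift_stack()].
#' @param position numeric length-2 (x, y) in km.
#' @param date query date (within the stack calendar).
#' @param radius search radius in cells (default 1).
#' @return `list(u, v, product)` in km/day; `product` is `NA` (and u, v are
#'   `NA`) when no product has valid motion data within the radius.
#' @export
sample_drift <- function(stack, position, date, radius = 1L) {
  it <- date_index(stack$dates, date)
  if (is.na(it)) stop("date outside stack calendar: ", format(as.Date(date)))
  px <- position[1]; py <- position[2]
  i <- cell_of(stack$x, px); j <- cell_of(stack$y, py)
  if (!is.na(i) && !is.na(j)) {
    for (k in seq_along(stack$products)) {
      p <- stack$products[[k]]
      if (p$available[j, i, it]) {
        u <- bilinear(stack$x, stack$y, p$u[, , it], px, py)
        v <- bilinear(stack$x, stack$y, p$v[, , it], px, py)
        if (is.finite(u) && is.finite(v))
          return(list(u = u, v = v, product = k))
      }
      if (radius > 0) {
        hit <- nearest_available(p$available[, , it], stack$x, stack$y,
                                 i, j, px, py, radius)
        if (!is.null(hit))
          return(list(u = p$u[hit[1], hit[2], it],
                      v = p$v[hit[1], hit[2], it], product = k))
      }
    }
  }
  list(u = NA_real_, v = NA_real_, product = NA_integer_)
}

# Nearest available cell (by Euclidean center distance) within a Chebyshev
# radius of cell (j, i); NULL if none. Excludes the center cell itself (it
# was already tested).
nearest_available <- function(avail, xax, yax, i, j, px, py, radius) {
  ii <- max(1, i - radius):min(length(xax), i + radius)
  jj <- max(1, j - radius):min(length(yax), j + radius)
  best <- NULL; bestd <- Inf
  for (a in jj) for (b in ii) {
    if (a == j && b == i) next
    if (!avail[a, b]) next
    d <- (xax[b] - px)^2 + (yax[a] - py)^2
    if (d < bestd) { bestd <- d; best <- c(a, b) }
  }
  best
}

#' Backward-in-time Lagrangian trace of sea-ice
#'
#' Explicit backward Euler: `position(t - dt) = position(t) - dt * v(t,
#' position(t))`, with velocity taken from the highest-priority available
#' drift product (see [sample_drift()]) on the nearest-day field. Along the
#' track, ice concentration (and air temperature, when a field is supplied)
#' are sampled by bilinear interpolation. The trace terminates at the first
#' sample whose concentration drops below the threshold — that position is
#' interpreted as where the ice formed — or on domain exit, motion-data
#' loss, the maximum duration, or the start of the motion record (reported
#' as `max_duration`).
#'
#' @param start numeric length-2 start position (km), inside the domain.
#' @param start_date trace start (export) date.
#' @param stack a `drift_stack`.
#' @param concentration an `ice_field` of sea-ice concentration (%).
#' @param config a [tracker_config()].
#' @param airtemp optional `ice_field` of 2 m air temperature for
#'   along-track sampling (needed for freezing-degree-day thickness).
#' @return An `ice_trajectory`: `samples` data.frame (`date`, `x_km`,
#'   `y_km`, `concentration_pct`, `t2m_c`, `product_id`; dates strictly
#'   decreasing; `product_id` is the drift product used for the step taken
#'   *from* each sample, `NA` on the terminal sample) and a termination
#'   `reason` in `formed`, `max_duration`, `left_domain`, `no_motion_data`.
#' @examples
#' dom <- domain_config(end_date = "2002-12-31", cell_km = 100)
#' sc <- scenario_params(drift_noise_sd = 0, conc_noise_cv = 0, edge_noise_km = 0)
#' stack <- make_drift_stack(dom, sc)
#' conc <- make_concentration_field(dom, sc)
#' tr <- backtrack(dom$gate_xy_km, as.Date("2002-03-01"), stack, conc,
#'                 tracker_config())
#' tr
#' @export
backtrack <- function(start, start_date, stack, concentration, config,
                      airtemp = NULL) {
  start_date <- as.Date(start_date)
  if (is.na(date_index(stack$dates, start_date)))
    stop("start date outside stack calendar")
  if (!inside_domain(stack, start[1], start[2]))
    stop("start position outside the domain")
  step <- config$step_days
  pos <- as.numeric(start)
  date <- start_date
  n_guess <- min(ceiling(config$max_duration_days / step) + 2L, 100000L)
  dates <- rep(as.Date(NA), n_guess)
  xs <- ys <- cc <- tt <- numeric(n_guess)
  pid <- integer(n_guess)
  n <- 0L
  reason <- NULL
  repeat {
    it <- date_index(stack$dates, date)
    if (is.na(it)) { reason <- "max_duration"; break }  # start of record
    if (!inside_domain(stack, pos[1], pos[2])) {
      # record the exit position, then stop
      n <- n + 1L
      dates[n] <- date; xs[n] <- pos[1]; ys[n] <- pos[2]
      cc[n] <- NA; tt[n] <- NA; pid[n] <- NA
      reason <- "left_domain"; break
    }
    conc <- bilinear(concentration$x, concentration$y,
                     concentration$data[, , it], pos[1], pos[2])
    temp <- if (is.null(airtemp)) NA_real_ else
      bilinear(airtemp$x, airtemp$y, airtemp$data[, , it], pos[1], pos[2])
    n <- n + 1L
    dates[n] <- date; xs[n] <- pos[1]; ys[n] <- pos[2]
    cc[n] <- conc; tt[n] <- temp; pid[n] <- NA
    if (is.finite(conc) && conc < config$conc_threshold_pct) {
      reason <- "formed"; break
    }
    if (as.numeric(start_date - date) + step > config$max_duration_days) {
      reason <- "max_duration"; break
    }
    drift <- sample_drift(stack, pos, date, config$search_radius_cells)
    if (is.na(drift$product)) { reason <- "no_motion_data"; break }
    pid[n] <- drift$product
    pos <- pos - step * c(drift$u, drift$v)
    date <- date - step
  }
  keep <- seq_len(n)
  structure(list(
    samples = data.frame(date = dates[keep], x_km = xs[keep], y_km = ys[keep],
                         concentration_pct = cc[keep], t2m_c = tt[keep],
                         product_id = pid[keep]),
    reason = reason, start = start, start_date = start_date,
    step_days = step), class = "ice_trajectory")
}

#' @export
print.ice_trajectory <- function(x, ...) {
  s <- x$samples
  cat(sprintf("<ice_trajectory> start %s at (%g, %g) km; %d samples; reason: %s\n",
              format(x$start_date), x$start[1], x$start[2], nrow(s), x$reason))
  if (nrow(s) > 0)
    cat(sprintf("  final: %s at (%.1f, %.1f) km, concentration %.1f%%\n",
                format(s$date[nrow(s)]), s$x_km[nrow(s)], s$y_km[nrow(s)],
                s$concentration_pct[nrow(s)]))
  invisible(x)
}

#' Backtrack one trajectory per monthly start date
#'
#' Runs [backtrack()] once per start date (by default the first of every
#' month of the stack calendar, the monthly export sampling of the study
#' design), preserving order. Per-trace failures terminate that trace with
#' its recorded reason; the batch never aborts.
#'
#' @inheritParams backtrack
#' @return A list of `ice_trajectory` objects, one per start date.
#' @export
batch_backtrack <- function(stack, concentration, config, airtemp = NULL) {
  starts <- config$start_dates
  if (is.null(starts)) {
    first <- as.Date(format(stack$dates[1], "%Y-%m-01"))
    if (first < stack$dates[1]) first <- seq(first, by = "month",
                                             length.out = 2)[2]
    starts <- seq(first, stack$dates[length(stack$dates)], by = "month")
  }
  lapply(starts, function(d)
    backtrack(config$start_xy_km, d, stack, concentration, config, airtemp))
}

#' Areal track density of trajectories on a grid
#'
#' Counts, per grid cell, the number of distinct trajectories that entered
#' the cell; a trajectory increments a cell at most once no matter how many
#' of its samples fall there.
#'
#' @param trajectories list of `ice_trajectory` objects.
#' @param grid any object with cell-center axes `x` and `y` (a
#'   `domain_config`, `drift_stack`, `ice_field`, ...).
#' @return Integer matrix (y-by-x) of counts; all zero for an empty list.
#' @export
track_density <- function(trajectories, grid) {
  dens <- matrix(0L, length(grid$y), length(grid$x))
  for (tr in trajectories) {
    s <- tr$samples
    i <- cell_of(grid$x, s$x_km)
    j <- cell_of(grid$y, s$y_km)
    ok <- !is.na(i) & !is.na(j)
    cells <- unique(cbind(j[ok], i[ok]))
    if (nrow(cells) > 0) dens[cells] <- dens[cells] + 1L
  }
  dens
}
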