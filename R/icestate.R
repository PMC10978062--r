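#' Freezing-degree-day ice growth model
#'
#' Thermodynamic thickness of first-year ice as an empirical power law of
#' accumulated freezing-degree-days (FDD): `h_cm = a * FDD^b`, with
#' `FDD = sum over days of max(0, T_f - T_air)`. The defaults are the
#' classical Lebedev parameterization (a = 1.33 cm per (degC day)^b,
#' b = 0.58) with a seawater freezing point of -1.8 degC; all three
#' parameters are exposed so an alternative growth law can be swapped in.
#' Melt is not modeled: FDD only accumulates, consistent with a
#' thermodynamic growth proxy.
#'
#' @param t_freeze_c freezing point (degC).
#' @param a growth coefficient (cm per (degC day)^b), > 0.
#' @param b growth exponent, in (0, 1].
#' @return An `fdd_model` list.
#' @export
fdd_model <- function(t_freeze_c = -1.8, a = 1.33, b = 0.58) {
  if (!(a > 0)) stop("`a` must be > 0")
  if (!(b > 0 && b <= 1)) stop("`b` must lie in (0, 1]")
  structure(list(t_freeze_c = t_freeze_c, a = a, b = b),
            class = "fdd_model")
}

#' Ice age of a formed trajectory
#'
#' Export date minus formation date, in days. Only defined for trajectories
#' that terminated because concentration dropped below the formation
#' threshold.
#'
#' @param trajectory an `ice_trajectory` with `reason == "formed"`.
#' @return Age in days (>= 0).
#' @export
ice_age <- function(trajectory) {
  stopifnot(inherits(trajectory, "ice_trajectory"))
  if (trajectory$reason != "formed")
    stop("ice age is defined only for trajectories with reason 'formed'")
  s <- trajectory$samples
  as.numeric(trajectory$start_date - s$date[nrow(s)])
}

#' Freezing-degree-day thermodynamic thickness along a trajectory
#'
#' Accumulates `max(0, T_f - T_air)` over the along-track daily air
#' temperatures from formation to export and evaluates the growth law of an
#' [fdd_model()]. Returns 0 cm when no day was below freezing.
#'
#' @param trajectory an `ice_trajectory` whose samples carry air
#'   temperatures (`t2m_c`).
#' @param model an [fdd_model()].
#' @return Thickness in cm.
#' @export
fdd_thickness <- function(trajectory, model = fdd_model()) {
  stopifnot(inherits(trajectory, "ice_trajectory"),
            inherits(model, "fdd_model"))
  temps <- trajectory$samples$t2m_c
  if (trajectory$reason == "left_domain" && nrow(trajectory$samples) > 1)
    temps <- temps[-nrow(trajectory$samples)]  # exit sample has no field value
  if (any(is.na(temps))) {
    gaps <- which(is.na(temps))
    stop(sprintf("missing air temperature on %d track day(s) (first gap: %s)",
                 length(gaps),
                 format(trajectory$samples$date[gaps[1]])))
  }
  fdd <- sum(pmax(0, model$t_freeze_c - temps)) * trajectory$step_days
  if (fdd == 0) return(0)
  model$a * fdd^model$b
}

#' Formation depth and shelf classification
#'
#' Bilinear bathymetry at the formation (terminal) position of a formed
#' trajectory, and whether that depth marks a shallow shelf formation
#' region (< 100 m; strictly, matching the bathymetry generator's regime
#' split).
#'
#' @param trajectory an `ice_trajectory` with `reason == "formed"`.
#' @param bathymetry a `depth_grid` from [make_bathymetry()].
#' @return `list(depth_m, shelf)`.
#' @export
formation_properties <- function(trajectory, bathymetry) {
  stopifnot(inherits(trajectory, "ice_trajectory"),
            inherits(bathymetry, "depth_grid"))
  if (trajectory$reason != "formed")
    stop("formation properties require reason 'formed'")
  s <- trajectory$samples
  d <- bilinear(bathymetry$x, bathymetry$y, bathymetry$depth,
                s$x_km[nrow(s)], s$y_km[nrow(s)])
  list(depth_m = d, shelf = is.finite(d) && d < 100)
}

#' Per-trajectory ice export records
#'
#' Convenience wrapper assembling one record per trajectory: export date,
#' formation date/position, ice age, FDD thickness, formation depth and
#' shelf flag. Non-formed trajectories yield a record with `formed = FALSE`
#' and `NA` metrics.
#'
#' @param trajectories list of `ice_trajectory` objects.
#' @param bathymetry a `depth_grid`.
#' @param model an [fdd_model()].
#' @return An `ice_export_records` data.frame.
#' @export
ice_export_records <- function(trajectories, bathymetry,
                               model = fdd_model()) {
  rows <- lapply(trajectories, function(tr) {
    s <- tr$samples
    base <- data.frame(
      start_date = tr$start_date, reason = tr$reason,
      formed = tr$reason == "formed",
      formation_date = as.Date(NA), age_days = NA_real_,
      thickness_cm = NA_real_, formation_x_km = NA_real_,
      formation_y_km = NA_real_, formation_depth_m = NA_real_,
      shelf = NA)
    if (tr$reason == "formed") {
      fp <- formation_properties(tr, bathymetry)
      base$formation_date <- s$date[nrow(s)]
      base$age_days <- ice_age(tr)
      base$thickness_cm <- fdd_thickness(tr, model)
      base$formation_x_km <- s$x_km[nrow(s)]
      base$formation_y_km <- s$y_km[nrow(s)]
      base$formation_depth_m <- fp$depth_m
      base$shelf <- fp$shelf
    }
    base
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ice_export_records", "data.frame")
  out
}

#' Monthly export summary of ice-state records
#'
#' Per export (start) month: mean ice age, mean thickness, mean formation
#' depth, shelf fraction (shelf formations / formed trajectories), and
#' counts. Months in which no trajectory formed are kept with `NA` metrics
#' rather than zeros.
#'
#' @param records an `ice_export_records` data.frame (or compatible).
#' @param by grouping, currently `"month"`: one row per (year, month) of the
#'   export date.
#' @return A data.frame with `year`, `month`, `n_total`, `n_formed`,
#'   `mean_age_days`, `mean_thickness_cm`, `mean_depth_m`, `shelf_fraction`.
#' @export
export_summary <- function(records, by = "month") {
  by <- match.arg(by, "month")
  if (nrow(records) < 1) stop("need at least one record")
  yr <- year_of(records$start_date)
  mo <- month_of(records$start_date)
  key <- paste(yr, sprintf("%02d", mo), sep = "-")
  out <- do.call(rbind, lapply(unique(key), function(k) {
    r <- records[key == k, ]
    f <- r[r$formed, ]
    data.frame(
      year = yr[key == k][1], month = mo[key == k][1],
      n_total = nrow(r), n_formed = nrow(f),
      mean_age_days = if (nrow(f)) mean(f$age_days) else NA_real_,
      mean_thickness_cm = if (nrow(f)) mean(f$thickness_cm) else NA_real_,
      mean_depth_m = if (nrow(f)) mean(f$formation_depth_m) else NA_real_,
      shelf_fraction = if (nrow(f)) mean(f$shelf) else NA_real_)
  }))
  out[order(out$year, out$month), ]
}
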