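#' Ice-edge conditioning configuration
#'
#' @param edge_threshold_pct concentration (%) defining the ice edge: cells
#'   at or above it count as ice-covered (default 15).
#' @param far_exclusion_km cups whose mean edge distance exceeds this are
#'   excluded from analysis (default 150 km).
#' @param bin_edges_km lower edges of the distance bins (km), strictly
#'   increasing; default `c(0, 40, 80)` giving bins 0-40, 40-80 and
#'   80-`far_exclusion_km`. Bins are half-open `[lo, hi)`, boundary values
#'   assigned upward.
#' @return An `edge_config` list.
#' @export
edge_config <- function(edge_threshold_pct = 15,
                        far_exclusion_km = 150,
                        bin_edges_km = c(0, 40, 80)) {
  if (!(edge_threshold_pct > 0 && edge_threshold_pct < 100))
    stop("`edge_threshold_pct` must lie in (0, 100)")
  if (any(diff(bin_edges_km) <= 0))
    stop("`bin_edges_km` must be strictly increasing")
  if (far_exclusion_km <= max(bin_edges_km))
    stop("`far_exclusion_km` must exceed the last bin edge")
  structure(list(edge_threshold_pct = edge_threshold_pct,
                 far_exclusion_km = far_exclusion_km,
                 bin_edges_km = bin_edges_km),
            class = "edge_config")
}

#' Normalize a collected trap mass to a flux
#'
#' Standard sediment-trap normalization: collected mass divided by trap
#' collection area and interval length.
#'
#' @param mass_mg collected mass (mg), >= 0.
#' @param area_m2 trap collection area (m^2); sequencing traps of this
#'   design sample ~0.5 m^2.
#' @param interval_days cup collection interval (days), > 0.
#' @return Flux in mg m^-2 d^-1.
#' @examples
#' compute_flux(10, 0.5, 20)  # 1 mg m^-2 d^-1
#' @export
compute_flux <- function(mass_mg, area_m2 = 0.5, interval_days) {
  if (any(mass_mg < 0)) stop("`mass_mg` must be >= 0")
  if (any(area_m2 <= 0) || any(interval_days <= 0))
    stop("`area_m2` and `interval_days` must be > 0")
  mass_mg / (area_m2 * interval_days)
}

#' Distance from a point to the sea-ice edge on a given day
#'
#' The ice edge is the set of cells with concentration at or above the
#' threshold. The distance is the minimum Euclidean distance from the point
#' to the center of any such cell, and 0 when the cell containing the point
#' itself qualifies. When no cell qualifies the day is ice-free and `NA` is
#' returned (a "no ice" flag, not an error).
#'
#' @param concentration an `ice_field` of concentration (%).
#' @param date query date.
#' @param point numeric length-2 (x, y) km.
#' @param config an [edge_config()].
#' @return Distance in km, or `NA` when no ice is present.
#' @export
edge_distance <- function(concentration, date, point,
                          config = edge_config()) {
  it <- date_index(concentration$dates, date)
  if (is.na(it)) stop("date outside field calendar: ", format(as.Date(date)))
  slice <- concentration$data[, , it]
  thr <- config$edge_threshold_pct
  i <- cell_of(concentration$x, point[1])
  j <- cell_of(concentration$y, point[2])
  if (!is.na(i) && !is.na(j) && slice[j, i] >= thr) return(0)
  q <- which(slice >= thr, arr.ind = TRUE)
  if (nrow(q) == 0) return(NA_real_)
  dx <- concentration$x[q[, 2]] - point[1]
  dy <- concentration$y[q[, 1]] - point[2]
  sqrt(min(dx^2 + dy^2))
}

#' Daily edge distances over a set of dates
#'
#' @inheritParams edge_distance
#' @param dates vector of dates.
#' @return Numeric vector of distances (km), `NA` on ice-free days.
#' @export
edge_distance_series <- function(concentration, dates, point,
                                 config = edge_config()) {
  vapply(as.list(as.Date(dates)),
         function(d) edge_distance(concentration, d, point, config),
         numeric(1))
}

#' Mean ice cover at a point over a sampling interval
#'
#' Mean of the daily (bilinear) concentration at the point over the cup
#' interval `[start, end)` — i.e. the sea-ice coverage integrated into the
#' duration of the sampling period.
#'
#' @inheritParams edge_distance
#' @param start,end interval bounds (end exclusive), within the calendar.
#' @return Mean cover in %.
#' @export
integrate_cover <- function(concentration, point, start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (end <= start) stop("`end` must be after `start`")
  days <- seq(start, end - 1, by = "day")
  vals <- vapply(as.list(days), function(d)
    field_value(concentration, d, point[1], point[2]), numeric(1))
  mean(vals)
}

#' Mean edge distance and integrated cover per cup
#'
#' Computes, for every cup interval, the mean of the daily ice-edge
#' distances (ice-free days dropped; all-ice-free intervals get `NA`) and
#' the interval-integrated ice cover at a point.
#'
#' @param cups a `cup_table` (or data.frame with `start`, `end`).
#' @param concentration an `ice_field` of concentration.
#' @param point numeric length-2 (x, y) km, typically the mooring.
#' @param config an [edge_config()].
#' @return `cups` with columns `distance_km` and `cover_pct` added.
#' @export
cup_ice_conditions <- function(cups, concentration, point,
                               config = edge_config()) {
  n <- nrow(cups)
  dist <- cover <- numeric(n)
  for (k in seq_len(n)) {
    days <- seq(as.Date(cups$start[k]), as.Date(cups$end[k]) - 1, by = "day")
    dd <- edge_distance_series(concentration, days, point, config)
    dist[k] <- if (all(is.na(dd))) NA_real_ else mean(dd, na.rm = TRUE)
    cover[k] <- integrate_cover(concentration, point,
                                cups$start[k], cups$end[k])
  }
  cups$distance_km <- dist
  cups$cover_pct <- cover
  cups
}

#' Assign cups to ice-edge distance bins
#'
#' Bins are half-open `[lo, hi)` over the configured edges, the last bin
#' closing at the far-exclusion distance; cups at or beyond the exclusion
#' distance, and cups with no defined distance (no ice), are labelled
#' `"excluded"`.
#'
#' @param cups a cup data.frame.
#' @param distances one mean edge distance (km) per cup; defaults to the
#'   `distance_km` column (or, failing that, the generator's
#'   `edge_distance_km`).
#' @param config an [edge_config()].
#' @return `cups` with `distance_km` and factor column `bin` added; levels
#'   are e.g. `"0-40"`, `"40-80"`, `"80-150"`, `"excluded"`.
#' @export
classify_cups <- function(cups,
                          distances = if (!is.null(cups$distance_km))
                            cups$distance_km else cups$edge_distance_km,
                          config = edge_config()) {
  if (is.null(distances)) stop("no distances found or given")
  if (length(distances) != nrow(cups))
    stop("need one distance per cup")
  edges <- c(config$bin_edges_km, config$far_exclusion_km)
  labs <- paste0(edges[-length(edges)], "-", edges[-1])
  bin <- cut(distances, breaks = edges, labels = labs, right = FALSE)
  bin <- as.character(bin)
  bin[is.na(bin)] <- "excluded"
  cups$distance_km <- distances
  cups$bin <- factor(bin, levels = c(labs, "excluded"))
  cups
}

#' Restrict cups to the productive season
#'
#' Keeps cups whose interval midpoint falls in the given months (default
#' March-September). A cup belongs to the month of its midpoint date; cups
#' spanning month boundaries are not split. Idempotent.
#'
#' @param cups a cup data.frame with `start`, `end`.
#' @param months integer months to retain.
#' @return The filtered data.frame.
#' @export
seasonal_filter <- function(cups, months = 3:9) {
  cups[cup_month(cups) %in% months, , drop = FALSE]
}

# Month of the cup-interval midpoint.
cup_month <- function(cups) {
  mid <- as.Date(cups$start) +
    floor(as.numeric(as.Date(cups$end) - as.Date(cups$start)) / 2)
  month_of(mid)
}

# Year of the cup-interval midpoint.
cup_year <- function(cups) {
  mid <- as.Date(cups$start) +
    floor(as.numeric(as.Date(cups$end) - as.Date(cups$start)) / 2)
  year_of(mid)
}
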