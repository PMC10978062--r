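# CSV serialization of gridded fields, drift stacks, trajectories and cup
# tables. Gridded fields use a long format (date, y_km, x_km, value) with
# ISO-8601 dates; data.table does the heavy reading/writing.

#' Write / read a gridded daily field as long-format CSV
#'
#' @param field an `ice_field`.
#' @param path output CSV path.
#' @return `write_field_csv` returns `path` invisibly; `read_field_csv`
#'   returns an `ice_field`.
#' @export
write_field_csv <- function(field, path) {
  # array is y-by-x-by-date with y varying fastest; CJ's last key varies
  # fastest, hence the y_km-last ordering
  dt <- data.table::CJ(date = field$dates, x_km = field$x, y_km = field$y,
                       sorted = FALSE)
  dt$value <- as.vector(field$data)
  data.table::setcolorder(dt, c("date", "y_km", "x_km", "value"))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_field_csv
#' @param name,units field metadata to attach on read.
#' @export
read_field_csv <- function(path, name = "field", units = "") {
  dt <- data.table::fread(path)
  x <- sort(unique(dt$x_km)); y <- sort(unique(dt$y_km))
  dates <- sort(unique(as.Date(dt$date)))
  data.table::setorder(dt, date, x_km, y_km)
  arr <- array(dt$value, c(length(y), length(x), length(dates)))
  structure(list(x = x, y = y, dates = dates, data = arr,
                 name = name, units = units), class = "ice_field")
}

#' Write / read a drift stack as wide long-format CSV
#'
#' One row per (date, cell); per product `k`, columns `u_k`, `v_k`
#' (km/day) and logical `avail_k`.
#'
#' @param stack a `drift_stack`.
#' @param path CSV path.
#' @export
write_drift_csv <- function(stack, path) {
  dt <- data.table::CJ(date = stack$dates, x_km = stack$x, y_km = stack$y,
                       sorted = FALSE)
  for (k in seq_along(stack$products)) {
    p <- stack$products[[k]]
    dt[[paste0("u_", k)]] <- as.vector(p$u)
    dt[[paste0("v_", k)]] <- as.vector(p$v)
    dt[[paste0("avail_", k)]] <- as.vector(p$available)
  }
  data.table::setcolorder(dt, c("date", "y_km", "x_km"))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_drift_csv
#' @export
read_drift_csv <- function(path) {
  dt <- data.table::fread(path)
  x <- sort(unique(dt$x_km)); y <- sort(unique(dt$y_km))
  dates <- sort(unique(as.Date(dt$date)))
  data.table::setorder(dt, date, x_km, y_km)
  dims <- c(length(y), length(x), length(dates))
  nprod <- sum(grepl("^u_", names(dt)))
  products <- lapply(seq_len(nprod), function(k) {
    list(name = paste0("drift", k),
         u = array(dt[[paste0("u_", k)]], dims),
         v = array(dt[[paste0("v_", k)]], dims),
         available = array(dt[[paste0("avail_", k)]], dims))
  })
  structure(list(x = x, y = y, dates = dates, products = products),
            class = "drift_stack")
}

#' Write / read trajectories as CSV plus a JSON sidecar
#'
#' The CSV holds one row per trajectory sample (`trajectory_id`, `date`,
#' `x_km`, `y_km`, `concentration_pct`, `t2m_c`, `product_id`); the JSON
#' sidecar records per-trajectory metadata (termination reason, start, step).
#'
#' @param trajectories list of `ice_trajectory`.
#' @param csv_path,json_path output paths.
#' @export
write_trajectories_csv <- function(trajectories, csv_path, json_path) {
  rows <- lapply(seq_along(trajectories), function(i) {
    s <- trajectories[[i]]$samples
    s$trajectory_id <- i
    s
  })
  dt <- data.table::rbindlist(rows)
  data.table::setcolorder(dt, c("trajectory_id", "date"))
  data.table::fwrite(dt, csv_path)
  meta <- lapply(trajectories, function(tr)
    list(reason = tr$reason, start = as.numeric(tr$start),
         start_date = format(tr$start_date), step_days = tr$step_days))
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' @rdname write_trajectories_csv
#' @export
read_trajectories_csv <- function(csv_path, json_path) {
  dt <- data.table::fread(csv_path)
  dt$date <- as.Date(dt$date)
  meta <- jsonlite::read_json(json_path)
  lapply(seq_along(meta), function(i) {
    s <- as.data.frame(dt[dt$trajectory_id == i,
                          c("date", "x_km", "y_km", "concentration_pct",
                            "t2m_c", "product_id")])
    m <- meta[[i]]
    structure(list(samples = s, reason = m$reason,
                   start = unlist(m$start),
                   start_date = as.Date(m$start_date),
                   step_days = m$step_days),
              class = "ice_trajectory")
  })
}

#' Write / read a static bathymetry grid as CSV
#'
#' @param bathymetry a `depth_grid`.
#' @param path CSV path.
#' @export
write_bathymetry_csv <- function(bathymetry, path) {
  dt <- data.table::CJ(x_km = bathymetry$x, y_km = bathymetry$y,
                       sorted = FALSE)
  dt$depth_m <- as.vector(bathymetry$depth)
  data.table::setcolorder(dt, c("y_km", "x_km"))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_bathymetry_csv
#' @export
read_bathymetry_csv <- function(path) {
  dt <- data.table::fread(path)
  x <- sort(unique(dt$x_km)); y <- sort(unique(dt$y_km))
  data.table::setorder(dt, x_km, y_km)
  structure(list(x = x, y = y,
                 depth = matrix(dt$depth_m, length(y), length(x))),
            class = "depth_grid")
}

#' Write / read a sediment-trap cup table as CSV
#'
#' Dates are ISO-8601; all other columns pass through unchanged.
#'
#' @param cups a cup data.frame.
#' @param path CSV path.
#' @export
write_cups_csv <- function(cups, path) {
  data.table::fwrite(as.data.frame(cups), path)
  invisible(path)
}

#' @rdname write_cups_csv
#' @export
read_cups_csv <- function(path) {
  out <- as.data.frame(data.table::fread(path))
  out$start <- as.Date(out$start)
  out$end <- as.Date(out$end)
  class(out) <- c("cup_table", "data.frame")
  out
}
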