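# High-level analysis steps combining the flux-conditioning and stats
# modules; used by the orchestration stage and directly scriptable.

#' Monthly seasonal series from a cup table
#'
#' Collapses cup fluxes to one value per (year, month) — the mean over cups
#' whose interval midpoint falls in that month — in the layout
#' [seasonal_mann_kendall()] expects (seasons = calendar months).
#'
#' @param cups a cup data.frame.
#' @param column name of the value column (e.g. `"terr_flux"`).
#' @return data.frame with `year`, `season`, `value`.
#' @export
monthly_series <- function(cups, column) {
  stopifnot(column %in% names(cups))
  yr <- cup_year(cups); mo <- cup_month(cups)
  agg <- aggregate(cups[[column]], list(year = yr, season = mo),
                   mean, na.rm = TRUE)
  names(agg)[3] <- "value"
  agg[order(agg$year, agg$season), ]
}

#' Long-term trend tests on a conditioned cup table
#'
#' Seasonal Mann-Kendall trend tests of the monthly mean terrigenous marker
#' and POC fluxes across the years of the series.
#'
#' @param cups a cup data.frame with `terr_flux` and `poc_flux`.
#' @return data.frame with one row per tested variable: `variable`, `S`,
#'   `tau`, `z`, `p_value`, `n`.
#' @export
flux_trend_tests <- function(cups) {
  rows <- lapply(c(terrigenous = "terr_flux", poc = "poc_flux"),
                 function(col) {
                   r <- seasonal_mann_kendall(monthly_series(cups, col))
                   data.frame(S = r$S, tau = r$tau, z = r$z,
                              p_value = r$p_value, n = r$n)
                 })
  out <- do.call(rbind, rows)
  out <- cbind(variable = names(rows), out)
  rownames(out) <- NULL
  out
}

#' Ice-edge group and correlation tests on a conditioned cup table
#'
#' Productive-season (March-September) analysis of a classified cup table:
#' Wilcoxon rank-sum comparison of POC flux between the two nearest
#' ice-edge distance bins, and Spearman correlation of POC against
#' terrigenous marker flux.
#'
#' @param cups a cup data.frame with `bin` (see [classify_cups()]),
#'   `poc_flux`, `terr_flux`.
#' @param near_bin,far_bin bin labels to compare (defaults `"0-40"` vs
#'   `"40-80"`).
#' @param months productive-season months (default March-September).
#' @return A list: `wilcoxon` (a `rank_test` plus group means), `spearman`,
#'   `n_near`, `n_far`.
#' @export
flux_group_tests <- function(cups, near_bin = "0-40", far_bin = "40-80",
                             months = 3:9) {
  stopifnot("bin" %in% names(cups))
  season <- seasonal_filter(cups, months)
  near <- season$poc_flux[season$bin == near_bin]
  far <- season$poc_flux[season$bin == far_bin]
  if (length(near) == 0 || length(far) == 0)
    stop("no cups in one of the compared bins after seasonal filtering")
  w <- wilcoxon_two_sample(near, far)
  sp <- spearman_rank(season$poc_flux, season$terr_flux)
  list(wilcoxon = w, spearman = sp,
       n_near = length(near), n_far = length(far),
       mean_near = mean(near), mean_far = mean(far))
}
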