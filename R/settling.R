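#' Settling velocity of one particle track
#'
#' Ordinary least-squares slope of depth (mm, positive down) on time (s),
#' converted to m/day. Rising particles give negative velocities and are
#' returned signed rather than discarded (some phytoplankton aggregates,
#' e.g. *Phaeocystis*, can be positively buoyant); exclude non-positive
#' velocities before any log-scale analysis.
#'
#' @param track a data.frame with columns `t_s` (strictly increasing) and
#'   `z_mm`, >= 3 samples.
#' @return Velocity in m/day.
#' @examples
#' tr <- data.frame(t_s = 0:10, z_mm = 0:10 * 20 * 1000 / 86400)
#' track_to_velocity(tr)  # 20 m/day
#' @export
track_to_velocity <- function(track) {
  stopifnot(all(c("t_s", "z_mm") %in% names(track)))
  if (nrow(track) < 3) stop("a track needs at least 3 samples")
  if (any(diff(track$t_s) <= 0)) stop("track times must be strictly increasing")
  slope_mm_s <- coef(lm(z_mm ~ t_s, data = track))[["t_s"]]
  slope_mm_s * 86400 / 1000
}

#' Per-particle settling velocities of a track table
#'
#' @param tracks a `particle_tracks` long table (see
#'   [make_particle_tracks()]).
#' @return A data.frame with one row per particle: `particle_id`,
#'   `treatment`, `crystal_class`, `timepoint_h`, `diameter_um`,
#'   `velocity_m_day`.
#' @export
velocities_from_tracks <- function(tracks) {
  stopifnot(all(c("particle_id", "treatment", "crystal_class",
                  "timepoint_h", "t_s", "z_mm") %in% names(tracks)))
  ids <- unique(tracks$particle_id)
  do.call(rbind, lapply(ids, function(id) {
    tr <- tracks[tracks$particle_id == id, ]
    data.frame(particle_id = id,
               treatment = tr$treatment[1],
               crystal_class = tr$crystal_class[1],
               timepoint_h = tr$timepoint_h[1],
               diameter_um = if ("diameter_um" %in% names(tr))
                 tr$diameter_um[1] else NA_real_,
               velocity_m_day = track_to_velocity(tr))
  }))
}

#' Median and IQR of settling velocities per treatment and time point
#'
#' @param velocities a data.frame with `treatment`, `timepoint_h`,
#'   `velocity_m_day` (see [velocities_from_tracks()]).
#' @return A data.frame with one row per treatment-by-time-point
#'   combination over the full factor grid: `n`, `median_m_day`, `q25`,
#'   `q75`; combinations without particles are flagged by `n = 0` and `NA`
#'   summaries.
#' @export
summarize_timepoints <- function(velocities) {
  tr <- factor(velocities$treatment)
  tp <- factor(velocities$timepoint_h)
  grid <- expand.grid(treatment = levels(tr), timepoint_h = levels(tp),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(k) {
    v <- velocities$velocity_m_day[tr == grid$treatment[k] &
                                     tp == grid$timepoint_h[k]]
    data.frame(treatment = grid$treatment[k],
               timepoint_h = as.numeric(grid$timepoint_h[k]),
               n = length(v),
               median_m_day = if (length(v)) median(v) else NA_real_,
               q25 = if (length(v)) unname(quantile(v, 0.25)) else NA_real_,
               q75 = if (length(v)) unname(quantile(v, 0.75)) else NA_real_)
  }))
  out[order(out$treatment, out$timepoint_h), ]
}

#' Compare gypsum and control settling velocities
#'
#' Two-way Type II ANOVA with Tukey HSD (see [anova_settling()]) on log10
#' settling velocities with factors treatment and incubation time point.
#' Non-positive velocities (rising or stationary particles) cannot enter the
#' log transform; they are excluded here and their count reported.
#'
#' @param velocities a data.frame with `treatment`, `timepoint_h`,
#'   `velocity_m_day`; both treatments must be present.
#' @return A `settling_anova` with an added `n_excluded_nonpositive` field.
#' @export
compare_treatments <- function(velocities) {
  if (length(unique(velocities$treatment)) < 2)
    stop("both treatments must be present")
  pos <- velocities$velocity_m_day > 0
  n_excl <- sum(!pos)
  if (n_excl > 0)
    message(sprintf("excluding %d non-positive velocity(ies) from the log10 ANOVA",
                    n_excl))
  v <- velocities[pos, , drop = FALSE]
  res <- anova_settling(v$velocity_m_day, v$treatment, v$timepoint_h)
  res$n_excluded_nonpositive <- n_excl
  res
}
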