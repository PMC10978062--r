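STAGE_ORDER <- c("simulate", "track", "icestate", "fluxedge", "stats",
                 "settle")

STAGE_FILES <- list(
  simulate = c("drift.csv", "concentration.csv", "airtemp.csv",
               "bathymetry.csv", "cups.csv", "tracks.csv"),
  track = c("trajectories.csv", "terminations.json"),
  icestate = c("ice_records.csv", "export_summary.csv"),
  fluxedge = c("cups_classified.csv"),
  stats = c("trend_results.csv", "group_tests.csv"),
  settle = c("settling_velocities.csv", "settling_summary.csv",
             "settling_tests.csv"))

STAGE_DEPS <- list(simulate = character(0), track = "simulate",
                   icestate = c("simulate", "track"), fluxedge = "simulate",
                   stats = c("fluxedge", "icestate"), settle = "simulate")

#' Configuration of an end-to-end scenario run
#'
#' Either build the configuration in R or load it from a YAML/JSON file
#' with the same top-level keys.
#'
#' @param out_dir output directory (created if needed); every stage reads
#'   its inputs from and writes its outputs to this directory, so partial
#'   reruns are possible.
#' @param seed integer seed, required because the simulate and settle
#'   stages are stochastic.
#' @param stages character subset of
#'   `simulate, track, icestate, fluxedge, stats, settle` (any order;
#'   executed in dependency order).
#' @param domain,scenario,tracker,edge named lists of arguments forwarded
#'   to [domain_config()], [scenario_params()], [tracker_config()] and
#'   [edge_config()].
#' @param n_particles_per_group particles per treatment group in the
#'   simulated settling experiments.
#' @param verbose log stage progress to stderr.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed, stages = STAGE_ORDER,
                       domain = list(), scenario = list(),
                       tracker = list(), edge = list(),
                       n_particles_per_group = 50, verbose = TRUE) {
  stages <- match.arg(stages, STAGE_ORDER, several.ok = TRUE)
  if (missing(seed) || is.null(seed))
    stop("`seed` is required: the simulate and settle stages are stochastic")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = stages, domain = domain, scenario = scenario,
                 tracker = tracker, edge = edge,
                 n_particles_per_group = n_particles_per_group,
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML or JSON configuration file.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Run a scenario end to end
#'
#' Executes the enabled stages in dependency order, with file-based
#' handoffs between stages (so any stage can be rerun alone against an
#' existing output directory), and writes a `manifest.json` recording the
#' configuration, seed, package version and an md5 hash of every stage
#' output. Rerunning with an identical configuration reproduces identical
#' hashes. Progress is logged to stderr and to `run.log` (with timings);
#' nothing is written to stdout.
#'
#' @param config a [run_config()] or the path of a YAML/JSON config file.
#' @return The manifest, invisibly.
#' @export
run_scenario <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out, "run.log")
  logline <- function(...) {
    msg <- sprintf(...)
    if (config$verbose) message(msg)
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), msg, "\n",
        file = logfile, append = TRUE, sep = "")
  }
  pth <- function(f) file.path(out, f)
  stages <- STAGE_ORDER[STAGE_ORDER %in% config$stages]
  for (st in stages) {
    for (dep in setdiff(STAGE_DEPS[[st]], stages)) {
      missing <- STAGE_FILES[[dep]][!file.exists(pth(STAGE_FILES[[dep]]))]
      if (length(missing))
        stop(sprintf(paste0("stage '%s' requires outputs of stage '%s' ",
                            "(missing: %s); enable or run '%s' first"),
                     st, dep, paste(missing, collapse = ", "), dep))
    }
    t0 <- Sys.time()
    switch(st,
           simulate = stage_simulate(config, pth),
           track = stage_track(config, pth),
           icestate = stage_icestate(config, pth),
           fluxedge = stage_fluxedge(config, pth),
           stats = stage_stats(config, pth),
           settle = stage_settle(config, pth))
    logline("stage %-8s done in %.1f s", st,
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  produced <- unlist(STAGE_FILES[stages], use.names = FALSE)
  hashes <- as.list(tools::md5sum(pth(produced)))
  names(hashes) <- produced
  manifest <- list(
    package = "iceballast",
    version = as.character(utils::packageVersion("iceballast")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    stages = stages,
    domain = config$domain, scenario = config$scenario,
    files = hashes)
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

scenario_objects <- function(config) {
  dom_args <- config$domain
  dom_args$seed <- config$seed
  list(domain = do.call(domain_config, dom_args),
       scenario = do.call(scenario_params, config$scenario),
       edge = do.call(edge_config, config$edge))
}

stage_simulate <- function(config, pth) {
  so <- scenario_objects(config)
  dom <- so$domain; sc <- so$scenario
  stack <- make_drift_stack(dom, sc)
  conc <- make_concentration_field(dom, sc)
  temp <- make_airtemp_field(dom, sc)
  bathy <- make_bathymetry(dom)
  write_drift_csv(stack, pth("drift.csv"))
  write_field_csv(conc, pth("concentration.csv"))
  write_field_csv(temp, pth("airtemp.csv"))
  write_bathymetry_csv(bathy, pth("bathymetry.csv"))
  iv <- cup_intervals(dom)
  cond <- cup_ice_conditions(iv, conc, dom$mooring_xy_km, so$edge)
  cups <- make_flux_series(dom, sc, cond$distance_km)
  cups$cover_pct <- cond$cover_pct
  write_cups_csv(cups, pth("cups.csv"))
  n <- config$n_particles_per_group
  seeds <- config$seed + 11:14
  tracks <- rbind(
    cbind(make_particle_tracks(n, "control", "none", seeds[1]),
          experiment = "large"),
    cbind(make_particle_tracks(n, "gypsum", "large", seeds[2]),
          experiment = "large"),
    cbind(make_particle_tracks(n, "control", "none", seeds[3]),
          experiment = "small"),
    cbind(make_particle_tracks(n, "gypsum", "small", seeds[4]),
          experiment = "small"))
  data.table::fwrite(tracks, pth("tracks.csv"))
}

stage_track <- function(config, pth) {
  so <- scenario_objects(config)
  stack <- read_drift_csv(pth("drift.csv"))
  conc <- read_field_csv(pth("concentration.csv"), "concentration", "%")
  temp <- read_field_csv(pth("airtemp.csv"), "t2m", "degC")
  tr_args <- config$tracker
  if (is.null(tr_args$start_xy_km))
    tr_args$start_xy_km <- so$domain$gate_xy_km
  tracker <- do.call(tracker_config, tr_args)
  trajectories <- batch_backtrack(stack, conc, tracker, temp)
  write_trajectories_csv(trajectories, pth("trajectories.csv"),
                         pth("terminations.json"))
}

stage_icestate <- function(config, pth) {
  trajectories <- read_trajectories_csv(pth("trajectories.csv"),
                                        pth("terminations.json"))
  bathy <- read_bathymetry_csv(pth("bathymetry.csv"))
  records <- ice_export_records(trajectories, bathy)
  out <- records
  out$start_date <- format(out$start_date)
  out$formation_date <- format(out$formation_date)
  data.table::fwrite(out, pth("ice_records.csv"))
  data.table::fwrite(export_summary(records), pth("export_summary.csv"))
}

stage_fluxedge <- function(config, pth) {
  so <- scenario_objects(config)
  cups <- read_cups_csv(pth("cups.csv"))
  write_cups_csv(classify_cups(cups, config = so$edge),
                 pth("cups_classified.csv"))
}

stage_stats <- function(config, pth) {
  cups <- read_cups_csv(pth("cups_classified.csv"))
  summ <- as.data.frame(data.table::fread(pth("export_summary.csv")))
  trends <- flux_trend_tests(cups)
  ice_trend <- function(colname) {
    s <- data.frame(year = summ$year, season = summ$month,
                    value = summ[[colname]])
    tryCatch({
      r <- seasonal_mann_kendall(s)
      data.frame(variable = colname, S = r$S, tau = r$tau, z = r$z,
                 p_value = r$p_value, n = r$n)
    }, error = function(e)
      data.frame(variable = colname, S = NA, tau = NA, z = NA,
                 p_value = NA, n = sum(!is.na(s$value))))
  }
  trends <- rbind(trends, ice_trend("mean_age_days"),
                  ice_trend("mean_thickness_cm"),
                  ice_trend("shelf_fraction"))
  data.table::fwrite(trends, pth("trend_results.csv"))
  g <- flux_group_tests(cups)
  data.table::fwrite(data.frame(
    test = c("wilcoxon_poc_near_vs_far", "spearman_poc_terr"),
    statistic = c(g$wilcoxon$W, g$spearman$rho),
    p_value = c(g$wilcoxon$p_value, g$spearman$p_value),
    n = c(g$n_near + g$n_far, g$spearman$n)), pth("group_tests.csv"))
}

stage_settle <- function(config, pth) {
  tracks <- as.data.frame(data.table::fread(pth("tracks.csv")))
  vel <- do.call(rbind, lapply(unique(tracks$experiment), function(ex) {
    sub <- tracks[tracks$experiment == ex, ]
    # particle ids repeat across the four track sets; make them unique
    sub$particle_id <- paste(ex, sub$treatment, sub$particle_id, sep = "_")
    cbind(velocities_from_tracks(sub), experiment = ex)
  }))
  data.table::fwrite(vel, pth("settling_velocities.csv"))
  summ <- do.call(rbind, lapply(unique(vel$experiment), function(ex)
    cbind(summarize_timepoints(vel[vel$experiment == ex, ]),
          experiment = ex)))
  data.table::fwrite(summ, pth("settling_summary.csv"))
  tests <- do.call(rbind, lapply(unique(vel$experiment), function(ex) {
    res <- compare_treatments(vel[vel$experiment == ex, ])
    cbind(experiment = ex, res$table)
  }))
  data.table::fwrite(tests, pth("settling_tests.csv"))
}
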