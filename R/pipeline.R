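#' Run one pipeline stage from a configuration
#'
#' Orchestrates the analysis stages behind a single entry point driven by
#' a YAML (or in-memory list) configuration: synthetic-scene generation,
#' plain simulation, Sobol screening, MCMC calibration, point and regional
#' assimilation, and plot-level validation. Every stage writes its
#' artifacts plus a JSON run-manifest (stage, seed, package version,
#' configuration echo) into `output_dir`.
#'
#' @param stage One of `"synth"`, `"simulate"`, `"sobol"`, `"calibrate"`,
#'   `"assimilate-point"`, `"map-yield"`, `"validate"`.
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list. Common keys: `output_dir`, `seed`, `latitude`, `sowing_date`,
#'   `weather_file` (omit to use a generated series), `stage_doys`;
#'   stage-specific blocks `synth`, `sobol`, `mcmc`, `enkf` override
#'   module defaults.
#' @return (Invisibly) a named list of the paths written.
#' @export
run_stage <- function(stage, config) {
  stages <- c("synth", "simulate", "sobol", "calibrate",
              "assimilate-point", "map-yield", "validate")
  if (!stage %in% stages)
    stop("unknown stage '", stage, "'; expected one of: ",
         paste(stages, collapse = ", "))
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    yaml::read_yaml(config)
  } else config
  if (!is.list(cfg)) stop("config must be a YAML file path or a list")
  defaults <- list(output_dir = "maizecast-out", seed = 1, latitude = 38.9,
                   sowing_date = "2021-04-25", n_days = 170,
                   stage_doys = c(173, 218, 246))
  cfg <- utils::modifyList(defaults, cfg)
  bad <- c(seed = !is.numeric(cfg$seed),
           latitude = !is.numeric(cfg$latitude),
           stage_doys = length(cfg$stage_doys) != 3)
  if (any(bad))
    stop("invalid config key(s): ", paste(names(bad)[bad], collapse = ", "))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(cfg$output_dir, stage)
  dir.create(out, showWarnings = FALSE)
  sowing <- as.Date(cfg$sowing_date)
  year <- as.integer(strftime(sowing, "%Y"))
  stage_dates <- as.Date(cfg$stage_doys - 1,
                         origin = paste0(year, "-01-01"))
  weather <- if (!is.null(cfg$weather_file)) {
    if (!file.exists(cfg$weather_file))
      stop("weather file not found: ", cfg$weather_file)
    read_weather(cfg$weather_file, latitude = cfg$latitude)
  } else {
    generate_weather(cfg$latitude, sowing - 5, cfg$n_days, seed = cfg$seed)
  }
  params <- crop_parameters(inbred_optimized())
  written <- list()
  add <- function(path) written[[length(written) + 1]] <<- path

  if (stage == "synth") {
    sy <- utils::modifyList(list(nx = 20, ny = 20, spatial_cv = 0.1,
                                 obs_sd = 0.25), cfg$synth %||% list())
    scene <- generate_scene(sy$nx, sy$ny, base_params = params,
                            spatial_cv = sy$spatial_cv, obs_sd = sy$obs_sd,
                            seed = cfg$seed, stage_doys = cfg$stage_doys,
                            sowing_date = sowing, latitude = cfg$latitude,
                            n_days = cfg$n_days)
    utils::write.csv(scene$weather, file.path(out, "weather.csv"),
                     row.names = FALSE)
    add(file.path(out, "weather.csv"))
    for (s in names(scene$lai_obs)) {
      add(write_grid(scene$lai_obs[[s]], file.path(out, paste0("lai_obs_", s, ".txt"))))
      add(write_grid(scene$vi_obs[[s]], file.path(out, paste0("vi_obs_", s, ".txt"))))
    }
    add(write_grid(scene$truth_yield, file.path(out, "truth_yield.txt")))
    add(write_grid(scene$plot_id, file.path(out, "plot_id.txt")))
    utils::write.csv(scene$plots, file.path(out, "plots.csv"),
                     row.names = FALSE)
    add(file.path(out, "plots.csv"))
  } else if (stage == "simulate") {
    s <- simulate_crop(params, weather, sowing)
    utils::write.csv(s$trajectory[, c("date", "DVS", "LAI", "TWSO")],
                     file.path(out, "trajectory.csv"), row.names = FALSE)
    add(file.path(out, "trajectory.csv"))
    utils::write.csv(data.frame(LAIMAX = s$LAIMAX, TWSO = s$TWSO_maturity,
                                yield = s$yield),
                     file.path(out, "summary.csv"), row.names = FALSE)
    add(file.path(out, "summary.csv"))
  } else if (stage == "sobol") {
    so <- utils::modifyList(list(base_samples = 256, float = 0.30,
                                 threshold = 0.05), cfg$sobol %||% list())
    space <- crop_parameter_space(inbred_optimized(), float = so$float)
    res <- sobol_crop(space, weather, sowing,
                      base_samples = so$base_samples, seed = cfg$seed)
    tab <- do.call(rbind, lapply(res, function(r)
      data.frame(parameter = names(r$first_order), target = r$target,
                 S_i = unname(r$first_order), S_Ti = unname(r$total_order))))
    utils::write.csv(tab, file.path(out, "sobol_indices.csv"),
                     row.names = FALSE)
    add(file.path(out, "sobol_indices.csv"))
    writeLines(screen_sensitive(res, so$threshold),
               file.path(out, "sensitive_parameters.txt"))
    add(file.path(out, "sensitive_parameters.txt"))
  } else if (stage == "calibrate") {
    mc <- utils::modifyList(list(n_iter = 5000, n_burn = 1000, obs_sd = 0.25),
                            cfg$mcmc %||% list())
    if (is.null(cfg$lai_obs_file))
      stop("calibrate stage requires config key lai_obs_file ",
           "(CSV: date, lai[, sd])")
    ot <- utils::read.csv(cfg$lai_obs_file)
    obs <- lai_observations(ot$date, ot$lai, ot$sd %||% mc$obs_sd)
    pri <- prior_spec(hybrid_defaults())
    cal <- mcmc_calibrate(pri, obs, weather, sowing, n_iter = mc$n_iter,
                          n_burn = mc$n_burn, seed = cfg$seed)
    utils::write.csv(as.data.frame(cal$chains[, , 1]),
                     file.path(out, "chain.csv"), row.names = FALSE)
    add(file.path(out, "chain.csv"))
    summ <- data.frame(parameter = names(pri$means),
                       initial = unname(pri$means),
                       optimized = unname(cal$posterior_median[, 1]),
                       ci_lo = cal$ci95[1, , 1], ci_hi = cal$ci95[2, , 1])
    utils::write.csv(summ, file.path(out, "posterior_summary.csv"),
                     row.names = FALSE)
    add(file.path(out, "posterior_summary.csv"))
  } else if (stage %in% c("assimilate-point", "map-yield")) {
    ek <- utils::modifyList(list(n_members = 50, model_lai_sd = 0.20,
                                 obs_lai_sd = 0.25,
                                 parameter_sd_fraction = 0.05,
                                 mode = "parameter_set"),
                            cfg$enkf %||% list())
    ecfg <- ensemble_config(ek$n_members, ek$model_lai_sd, ek$obs_lai_sd,
                            ek$parameter_sd_fraction, ek$mode,
                            seed = cfg$seed)
    pmean <- if (ek$mode == "single_parameter")
      crop_parameters() else params
    if (stage == "assimilate-point") {
      if (is.null(cfg$lai_obs_file))
        stop("assimilate-point requires config key lai_obs_file")
      ot <- utils::read.csv(cfg$lai_obs_file)
      obs <- lai_observations(ot$date, ot$lai, ot$sd %||% ek$obs_lai_sd)
      r <- assimilate_point(pmean, weather, obs, ecfg, sowing)
      utils::write.csv(data.frame(yield = r$yield, yield_sd = r$yield_sd,
                                  lai_max = r$lai_max),
                       file.path(out, "point_yield.csv"), row.names = FALSE)
      add(file.path(out, "point_yield.csv"))
    } else {
      if (is.null(cfg$lai_map_files) || length(cfg$lai_map_files) != 3)
        stop("map-yield requires config key lai_map_files ",
             "(three stage grid paths)")
      maps <- lapply(cfg$lai_map_files, read_grid)
      ymap <- assimilate_region(maps, weather, pmean, ecfg, sowing,
                                stage_dates)
      add(write_grid(ymap$yield, file.path(out, "yield.txt")))
      add(write_grid(ymap$yield_sd, file.path(out, "yield_sd.txt")))
    }
  } else if (stage == "validate") {
    for (k in c("yield_map_file", "plot_id_file", "plots_file"))
      if (is.null(cfg[[k]])) stop("validate stage requires config key ", k)
    ymap <- read_grid(cfg$yield_map_file)
    pid <- read_grid(cfg$plot_id_file)
    plots <- utils::read.csv(cfg$plots_file)
    v <- validate_yield(ymap, plots$yield_measured, plot_id = pid)
    utils::write.csv(data.frame(r_squared = v$r_squared, rmse = v$rmse),
                     file.path(out, "validation.csv"), row.names = FALSE)
    add(file.path(out, "validation.csv"))
  }

  manifest <- list(stage = stage, seed = cfg$seed,
                   package = "maizecast",
                   version = as.character(utils::packageVersion("maizecast")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   config = cfg)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  add(file.path(out, "manifest.json"))
  invisible(stats::setNames(written, basename(unlist(written))))
}
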