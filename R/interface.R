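# Configuration schema and reproducible run commands. Config files are YAML
# with unit-suffixed keys; every run emits a manifest (config echo, seed,
# schema version, file checksums) so results are auditable and re-runnable.

CONFIG_SCHEMA <- "cflvisc-run/1"

#' Read and validate a run configuration
#'
#' Run configurations are YAML documents with explicit units in key names to
#' prevent unit drift. Recognised blocks: `fluid` (a preset name or inline
#' `mu_carrier_mPa_s`, `mu_rheo_mPa_s`, `phi_bulk`, `density_kg_m3`,
#' `label`), `geometry` (`H_um`, `W_um`, `L_um`), `development` (`a`,
#' `x0_um`, `h_cfl_ss_um`), `submodel`, `cfl_interpretation`,
#' `conditions` (`reynolds`: list), `grid` (`n_h`, `n_x_dev`,
#' `n_x_steady`), `scenario` (profile-generator block mirroring
#' [profile_scenario()] with `h_cfl_um`, `planes_um`) and `seed`.
#'
#' @param path Path to a YAML config, or a list already in that shape.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) .stopf("config must be a YAML mapping")
  if (!identical(cfg$schema, CONFIG_SCHEMA))
    .stopf("config schema must be '%s' (got '%s')", CONFIG_SCHEMA,
           if (is.null(cfg$schema)) "<missing>" else cfg$schema)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$geometry)) .stopf("config needs a 'geometry' block")
  for (k in c("H_um", "W_um", "L_um"))
    if (is.null(cfg$geometry[[k]]))
      .stopf("geometry block is missing '%s'", k)
  if (!is.null(cfg$conditions) &&
      (is.null(cfg$conditions$reynolds) ||
       length(cfg$conditions$reynolds) == 0))
    .stopf("conditions block needs a non-empty 'reynolds' list")
  class(cfg) <- c("run_config", "list")
  cfg
}

.config_fluid <- function(cfg) {
  fl <- cfg$fluid
  if (is.null(fl)) .stopf("config needs a 'fluid' block")
  if (!is.null(fl$preset)) {
    fluids <- fluid_presets()$fluids
    if (is.null(fluids[[fl$preset]]))
      .stopf("unknown fluid preset '%s' (known: %s)", fl$preset,
             paste(names(fluids), collapse = ", "))
    return(fluids[[fl$preset]])
  }
  fluid_spec(fl$mu_carrier_mPa_s, fl$mu_rheo_mPa_s, fl$phi_bulk,
             density = if (is.null(fl$density_kg_m3)) 1050
                       else fl$density_kg_m3,
             label = if (is.null(fl$label)) "" else fl$label,
             units = "mPa.s")
}

.config_geometry <- function(cfg) {
  g <- cfg$geometry
  channel_geometry(H = g$H_um, W = g$W_um, L = g$L_um)
}

.config_development <- function(cfg, geom) {
  d <- cfg$development
  if (is.null(d)) .stopf("config needs a 'development' block")
  cfl_development(a = d$a, x0 = if (is.null(d$x0_um)) 1 else d$x0_um,
                  h_cfl_ss = d$h_cfl_ss_um, H = geom$H)
}

.config_model <- function(cfg) {
  geom <- .config_geometry(cfg)
  grid <- if (is.null(cfg$grid)) list() else cfg$grid
  args <- list(fluid = .config_fluid(cfg), geometry = geom,
               development = .config_development(cfg, geom),
               submodel = if (is.null(cfg$submodel)) "step"
                          else cfg$submodel)
  if (!is.null(grid$n_h)) args$n_h <- grid$n_h
  if (!is.null(grid$n_x_dev)) args$n_x_dev <- grid$n_x_dev
  if (!is.null(grid$n_x_steady)) args$n_x_steady <- grid$n_x_steady
  if (!is.null(cfg$cfl_interpretation))
    args$cfl_interpretation <- cfg$cfl_interpretation
  do.call(cfl_model, args)
}

.write_manifest <- function(out_dir, cfg, files, extra = list()) {
  manifest <- c(list(schema = CONFIG_SCHEMA,
                     package_version = as.character(
                       utils::packageVersion("cflvisc")),
                     seed = cfg$seed,
                     config = unclass(cfg),
                     files = lapply(files, function(f)
                       list(name = basename(f),
                            md5 = unname(tools::md5sum(f))))),
                extra)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Build and export a viscosity field from a configuration
#'
#' Assembles the configured model, writes the field export
#' (`field.csv`), a human-readable summary (`field_summary.txt`) and a
#' manifest with checksums. Deterministic: identical configurations produce
#' byte-identical outputs.
#'
#' @param config Path to a YAML run configuration or a `run_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
run_build_field <- function(config, out_dir) {
  cfg <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- .config_model(cfg)
  field_path <- file.path(out_dir, "field.csv")
  write_field(model$field, field_path)
  summary_path <- file.path(out_dir, "field_summary.txt")
  lines <- c(
    sprintf("schema: %s", CONFIG_SCHEMA),
    sprintf("fluid: %s", model$fluid$label),
    sprintf("submodel: %s", model$submodel),
    sprintf("cfl_interpretation: %s (Eq. thickness read as %s)",
            model$field$cfl_interpretation,
            model$field$cfl_interpretation),
    sprintf("sections: homogeneous < %g um, development to x* = %.6g um, steady beyond",
            model$dev$x0, model$dev$x_star),
    sprintf("steady CFL height: %.6g um per wall", model$dev$h_cfl_ss),
    if (model$submodel == "step")
      sprintf("steady mu_STEP: %.6g mPa.s",
              step_viscosity_at(model$geom$L, model$fluid, model$geom,
                                model$dev,
                                model$field$cfl_interpretation) * 1e3)
    else
      sprintf("adjustment factor: %.6g", model$fit$adjustment_factor),
    if (model$dev$a == 0) "note: single-phase equivalent field (a = 0)")
  writeLines(lines, summary_path)
  manifest <- .write_manifest(out_dir, cfg, c(field_path, summary_path))
  invisible(manifest)
}

#' Solve configured flow cases and export result tables
#'
#' For every Reynolds number in the configuration, runs the model field, the
#' uniform single-phase field and the carrier-only reference, and writes a
#' per-station table (`stations_Re<...>.csv`: `x_um`, `G_Pa_m`,
#' `tau_w_bottom_Pa`, `tau_w_top_Pa`) plus a run summary
#' (`runs.csv`: `reynolds`, `bulk_velocity_m_s`, `delta_p_Pa`, `cp`,
#' `cp_ratio`, `cp_ratio_single`, `tau_w_model_Pa`, `tau_w_single_Pa`).
#'
#' @param config Path to a YAML run configuration or a `run_config`.
#' @param out_dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
run_solve <- function(config, out_dir) {
  cfg <- read_run_config(config)
  if (is.null(cfg$conditions)) .stopf("config needs a 'conditions' block")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- .config_model(cfg)
  files <- character(0)
  rows <- list()
  for (re in cfg$conditions$reynolds) {
    flow <- solve_flow(model, reynolds = re)
    st <- data.frame(x_um = flow$model_run$x_grid,
                     G_Pa_m = flow$model_run$G,
                     tau_w_bottom_Pa = flow$model_run$tau_w_bottom,
                     tau_w_top_Pa = flow$model_run$tau_w_top)
    st_path <- file.path(out_dir, sprintf("stations_Re%g.csv", re))
    utils::write.csv(format(st, digits = 12, trim = TRUE), st_path,
                     row.names = FALSE, quote = FALSE)
    files <- c(files, st_path)
    rows[[length(rows) + 1]] <- data.frame(
      reynolds = re, bulk_velocity_m_s = flow$bulk_velocity,
      delta_p_Pa = flow$model_run$delta_p, cp = flow$model_run$cp,
      cp_ratio = flow$cp_ratio, cp_ratio_single = flow$cp_ratio_single,
      tau_w_model_Pa = flow$tau_w_model, tau_w_single_Pa = flow$tau_w_single)
  }
  runs_path <- file.path(out_dir, "runs.csv")
  utils::write.csv(format(do.call(rbind, rows), digits = 12, trim = TRUE),
                   runs_path, row.names = FALSE, quote = FALSE)
  files <- c(files, runs_path)
  manifest <- .write_manifest(out_dir, cfg, files)
  invisible(manifest)
}

#' Generate a bundle of synthetic measurement profiles
#'
#' Emits the configured scenario's steady-state profile and its development
#' measurement planes as profile CSVs, with the seed recorded in the
#' manifest.
#'
#' @param config Path to a YAML run configuration or a `run_config`; needs a
#'   `scenario` block and (for the planes) a `development` block.
#' @param out_dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
run_synth <- function(config, out_dir) {
  cfg <- read_run_config(config)
  if (is.null(cfg$scenario)) .stopf("config needs a 'scenario' block")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- cfg$scenario
  geom <- .config_geometry(cfg)
  scen <- profile_scenario(
    phi_bulk = sc$phi_bulk,
    h_cfl = if (is.null(sc$h_cfl_um)) c(20, 20) else unlist(sc$h_cfl_um),
    core_shape = if (is.null(sc$core_shape)) "plateau" else sc$core_shape,
    noise_sd = if (is.null(sc$noise_sd)) 0 else sc$noise_sd,
    n_bins = if (is.null(sc$n_bins)) 128 else sc$n_bins,
    seed = cfg$seed,
    measurement_planes = if (is.null(sc$planes_um)) c(2000, 8000)
                         else unlist(sc$planes_um))
  files <- character(0)
  steady <- generate_profile(scen, geom, x_station = geom$L)
  steady_path <- file.path(out_dir, "profile_steady.csv")
  write_profile(steady, steady_path)
  files <- c(files, steady_path)
  if (!is.null(cfg$development)) {
    dev <- .config_development(cfg, geom)
    planes <- generate_development_planes(scen, dev, geom)
    for (nm in names(planes)) {
      p <- file.path(out_dir, sprintf("profile_%s.csv", nm))
      write_profile(planes[[nm]], p)
      files <- c(files, p)
    }
  }
  manifest <- .write_manifest(out_dir, cfg, files,
                              extra = list(seed_used = scen$seed))
  invisible(manifest)
}

#' Calibrate a development law from measurement-plane profiles
#'
#' Reads two or more profile CSVs, detects their cell-free layer heights and
#' fits the parabola coefficient.
#'
#' @param paths Character vector of profile CSV paths (>= 2).
#' @param x0 Homogeneous section length in um.
#' @param epsilon Detection threshold.
#' @return A [cfl_development].
#' @export
run_calibrate <- function(paths, x0 = 1, epsilon = 1e-4) {
  if (length(paths) < 2) .stopf("need at least two profile files")
  planes <- t(vapply(paths, function(p) {
    prof <- read_profile(p)
    c(attr(prof, "x_station"), mean(detect_cfl_height(prof, epsilon)))
  }, numeric(2)))
  calibrate_parabola(planes, x0 = x0)
}
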