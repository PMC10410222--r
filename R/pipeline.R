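## Configuration handling, end-to-end runs and result writing.
##
## Configs are YAML (or JSON) with unit-suffixed keys so that the mix of
## nm, um, cm^2/s and ns in the source literature cannot silently clash.

#' Validate and resolve a run configuration
#'
#' Reads a YAML (or JSON) configuration, checks the schema, resolves the
#' cell geometry (exactly one of `a_um` | `omega` may be given) and echoes
#' every derived quantity. Schema:
#' \preformatted{
#' model:    {kind: uniform|ccv|etv|free, phi, w_um, a_um | omega}
#' ensemble: {n_cells}
#' sim:      {n_molecules, dt_s, duration_s, d_cm2_s, seed,
#'            output_every, preset}
#' analysis: {rel_slope_tol, window_decades}
#' output:   {directory, mesh}
#' }
#'
#' @param file Path to a config file, or a list with the same structure.
#' @return Object of class `run_config`: the resolved configuration with
#'   `dims` (a [cell_dims()] object, unless `kind = "free"`) attached.
#' @export
validate_config <- function(file) {
  cfg <- if (is.list(file)) file
         else if (grepl("\\.json$", file)) jsonlite::read_json(file, simplifyVector = TRUE)
         else yaml::read_yaml(file)
  m <- cfg$model
  if (is.null(m$kind)) stop("config error: model.kind missing", call. = FALSE)
  if (m$kind == "free") {
    dims <- NULL
  } else {
    if (is.null(m$phi) || is.null(m$w_um))
      stop("config error: model.phi and model.w_um are required", call. = FALSE)
    if (!is.null(m$a_um) && !is.null(m$omega))
      stop("config error: supply exactly one of model.a_um | model.omega",
           call. = FALSE)
    dims <- cell_dims(m$kind, phi = m$phi, w = m$w_um,
                      a = m$a_um, omega = m$omega)
  }
  s <- cfg$sim
  simc <- sim_config(
    d_cm2_s = s$d_cm2_s %||% 7.71e-6,
    dt_s = s$dt_s %||% 2e-8,
    n_molecules = s$n_molecules %||% 25000L,
    duration_s = s$duration_s,
    seed = s$seed %||% 1L,
    output_every = s$output_every %||% 500L,
    preset = s$preset %||% "custom")
  if (!is.null(dims)) {
    lr <- mean_radial_step(simc$D, simc$dt)
    if (2 * dims$w / lr < simc$safety_factor)
      stop(sprintf(
        "config error: dt too large, mean radial step %.3g um exceeds (2w)/%g = %.3g um",
        lr, simc$safety_factor, 2 * dims$w / simc$safety_factor), call. = FALSE)
  }
  out <- list(model_kind = m$kind, dims = dims,
              n_cells = cfg$ensemble$n_cells %||% 32L,
              sim = simc,
              analysis = list(
                rel_slope_tol = cfg$analysis$rel_slope_tol %||% 0.01,
                window_decades = cfg$analysis$window_decades %||% 0.25),
              output = list(directory = cfg$output$directory %||% ".",
                            mesh = isTRUE(cfg$output$mesh)))
  class(out) <- "run_config"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full simulation pipeline for a configuration
#'
#' Builds the ensemble, runs the walker, detects the steady state and
#' writes the artifact directory: `geometry.json`, `timecourse.csv`,
#' `steady_state.json`, `manifest.json` and optionally `cell.obj`.
#'
#' @param cfg A `run_config` (or path handed to [validate_config()]).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `time_course`, `steady_state`,
#'   `ensemble` and `directory`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  if (!inherits(cfg, "run_config")) cfg <- validate_config(cfg)
  ens <- if (cfg$model_kind == "free") free_space() else
    build_ensemble(build_cell(cfg$dims), cfg$n_cells)
  if (!quiet) message("running walker: ", cfg$sim$n_steps, " steps x ",
                      cfg$sim$n_molecules, " molecules (seed ", cfg$sim$seed, ")")
  tc <- run_walk(ens, cfg$sim)
  ss <- tryCatch(
    detect_steady_state(tc, cfg$analysis$rel_slope_tol,
                        cfg$analysis$window_decades),
    error = function(e) e)
  write_results(tc, ss, ens, cfg, cfg$output$directory)
  invisible(list(time_course = tc,
                 steady_state = if (inherits(ss, "error")) NULL else ss,
                 ensemble = ens, directory = cfg$output$directory))
}

#' Write simulation artifacts to a directory
#'
#' File naming is deterministic and the manifest echoes the seed and the
#' walker counters, so a run can be reproduced from its output directory
#' alone.
#'
#' @param tc A `time_course`.
#' @param ss A `steady_state` (or an error condition when no plateau was
#'   reached; recorded as such in the manifest).
#' @param ens The `ensemble` simulated.
#' @param cfg The `run_config`.
#' @param directory Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_results <- function(tc, ss, ens, cfg, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  scfg <- attr(tc, "config")
  utils::write.csv(
    data.frame(t_s = tc$t_s, msd_um2 = tc$msd_um2,
               d_star_cm2_s = tc$d_star_cm2_s, tau_g = tc$tau_g,
               r_2rms_um = tc$r_2rms_um),
    file.path(directory, "timecourse.csv"), row.names = FALSE)
  pos <- attr(tc, "positions")
  utils::write.csv(data.frame(x_um = pos[, 1], y_um = pos[, 2],
                              z_um = pos[, 3]),
                   file.path(directory, "positions.csv"), row.names = FALSE)
  jsonlite::write_json(geometry_summary(ens),
                       file.path(directory, "geometry.json"),
                       auto_unbox = TRUE, digits = NA)
  ss_rec <- if (inherits(ss, "error"))
    list(converged = FALSE, message = conditionMessage(ss))
  else list(converged = TRUE, t_onset_s = ss$t_onset, t_end_s = ss$t_end,
            tau_mean = ss$tau_mean, tau_sd = ss$tau_sd,
            n_window = ss$n_window)
  jsonlite::write_json(ss_rec, file.path(directory, "steady_state.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    model = if (is.null(ens$cell)) "free" else ens$cell$dims$model,
    seed = scfg$seed, d_cm2_s = scfg$d_cm2_s, dt_s = scfg$dt,
    n_molecules = scfg$n_molecules, duration_s = scfg$duration,
    n_cells = if (is.null(ens$cell)) NA else cfg$n_cells,
    left_count = attr(tc, "left_count"),
    resample_count = attr(tc, "resample_count"),
    total_reflections = attr(tc, "total_reflections"))
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (isTRUE(cfg$output$mesh) && !is.null(ens$cell))
    export_mesh(ens$cell, file.path(directory, "cell.obj"))
  invisible(directory)
}

#' Preset configurations with their expectation records
#'
#' Small, fast configurations for each canonical scenario, together with
#' the steady-state tortuosity each is expected to produce and the
#' tolerance appropriate to its scale.
#'
#' @param name One of `"free_space"`, `"uniform_phi02"`,
#'   `"ccv_visc_phi02"`, `"ccv_tau16_phi02"`, `"etv_visc_phi02"`,
#'   `"sleepwake"`.
#' @return List with `config` (a list accepted by [validate_config()])
#'   and `expected` (`tau_g`, `tol`).
#' @export
generate_fixture <- function(name = c("free_space", "uniform_phi02",
                                      "ccv_visc_phi02", "ccv_tau16_phi02",
                                      "etv_visc_phi02", "sleepwake")) {
  name <- match.arg(name)
  desk <- function(duration_s, extra_model, n_cells = 16L,
                   d_cm2_s = 7.71e-6)
    list(model = extra_model,
         ensemble = list(n_cells = n_cells),
         sim = list(preset = "desk", duration_s = duration_s,
                    d_cm2_s = d_cm2_s, dt_s = 2e-8, seed = 1L),
         output = list(directory = tempfile("sheetvoid_run_")))
  switch(name,
    free_space = list(
      config = list(model = list(kind = "free"),
                    sim = list(preset = "desk", duration_s = 2e-4,
                               d_cm2_s = 7.71e-6, dt_s = 2e-8, seed = 1L),
                    output = list(directory = tempfile("sheetvoid_run_"))),
      expected = list(tau_g = 1.0, tol = 0.01)),
    uniform_phi02 = list(
      config = desk(2e-3, list(kind = "uniform", phi = 0.2, w_um = 0.020)),
      expected = list(tau_g = sqrt(1.427), tol = 0.02)),
    ccv_visc_phi02 = list(
      config = desk(3e-3, list(kind = "ccv", phi = 0.2, w_um = 0.020,
                               a_um = 0.416), n_cells = 32L),
      expected = list(tau_g = 1.328, tol = 0.03)),
    ccv_tau16_phi02 = list(
      config = desk(8e-3, list(kind = "ccv", phi = 0.2, w_um = 0.020,
                               omega = 1.608), n_cells = 32L,
                    d_cm2_s = 1.11e-5),
      expected = list(tau_g = 1.6, tol = 0.05)),
    etv_visc_phi02 = list(
      config = desk(2e-2, list(kind = "etv", phi = 0.2, w_um = 0.020,
                               a_um = 0.935), n_cells = 32L,
                    d_cm2_s = 7.71e-6),
      expected = list(tau_g = 1.333, tol = 0.05)),
    sleepwake = list(
      config = list(phi_sleep = 0.234, phi_awake = 0.141, tau_sw = 1.55,
                    trial_sleep = c(omega = 4.0, tau = 2.013),
                    trial_awake = c(omega = 3.0, tau = 1.981)),
      expected = list(omega_sleep = 1.500, omega_awake = 1.154,
                      tol = 0.002)))
}
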