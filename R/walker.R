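## R-side interface to the reflecting Brownian walker.

#' Simulation configuration for the random walker
#'
#' Collects and validates the physical and numerical parameters of a
#' point-source diffusion run. Diffusivity is given in cm^2/s (the unit in
#' which experimental values are reported) and converted internally to
#' um^2/s. The time step must keep the mean radial displacement per step,
#' \eqn{\bar{l}_r = \sqrt{4 D \Delta t / \pi}}, well below the full sheet
#' width 2w; the ratio `2w / l_r` must be at least `safety_factor`
#' (checked against the ensemble at run time).
#'
#' Two presets bundle standard parameter sets: `"paper"` uses 25000
#' molecules and a 20 ns step (the full-fidelity protocol), `"desk"` uses
#' 2000 molecules for scaled runs with ~1% stochastic error on tau.
#'
#' @param d_cm2_s Free diffusivity in cm^2/s. Default 7.71e-6 (the value
#'   for TMA at 37C once a viscous tortuosity of 1.2 is factored in);
#'   1.11e-5 is the free value without viscosity.
#' @param dt_s Time step in seconds (default 20 ns).
#' @param n_molecules Number of molecules released at the point source.
#' @param duration_s Simulated duration in seconds; must be an integer
#'   multiple of `dt_s`.
#' @param seed Integer RNG seed (recorded in all outputs).
#' @param output_every Output cadence in steps.
#' @param safety_factor Minimum allowed ratio of sheet width 2w to mean
#'   radial step (>= 4).
#' @param max_reflections Per-step reflection cap; steps exceeding it are
#'   resampled and counted.
#' @param preset `"custom"`, `"desk"` or `"paper"`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(d_cm2_s = 7.71e-6, dt_s = 2e-8, n_molecules = 25000L,
                       duration_s, seed = 1L, output_every = 500L,
                       safety_factor = 4, max_reflections = 32L,
                       preset = c("custom", "desk", "paper")) {
  preset <- match.arg(preset)
  if (preset == "paper") { n_molecules <- 25000L; dt_s <- 2e-8 }
  if (preset == "desk") n_molecules <- 2000L
  .check_scalar(d_cm2_s, "d_cm2_s", 0, open_lower = TRUE)
  .check_scalar(dt_s, "dt_s", 0, open_lower = TRUE)
  .check_scalar(duration_s, "duration_s", dt_s)
  if (safety_factor < 4)
    stop("`safety_factor` must be >= 4", call. = FALSE)
  n_steps <- duration_s / dt_s
  if (abs(n_steps - round(n_steps)) > 1e-6)
    stop("`duration_s` must be an integer number of time steps", call. = FALSE)
  structure(list(d_cm2_s = d_cm2_s, D = d_cm2_s * 1e8, dt = dt_s,
                 n_molecules = as.integer(n_molecules),
                 duration = duration_s, n_steps = as.integer(round(n_steps)),
                 seed = as.integer(seed),
                 output_every = as.integer(output_every),
                 safety_factor = safety_factor,
                 max_reflections = as.integer(max_reflections),
                 preset = preset),
            class = "sim_config")
}

#' Mean radial displacement per step
#'
#' \eqn{\bar{l}_r = \sqrt{4 D \Delta t / \pi}} for an isotropic Gaussian
#' step of per-axis variance \eqn{2 D \Delta t}.
#'
#' @param D Diffusivity in um^2/s.
#' @param dt Time step in seconds.
#' @return Mean radial step in micrometres.
#' @export
mean_radial_step <- function(D, dt) sqrt(4 * D * dt / pi)

#' Run a point-source diffusion simulation in an ensemble
#'
#' Releases `n_molecules` at the central lattice vertex cavity and advances
#' them with isotropic Gaussian displacements (per-axis variance
#' \eqn{2D\Delta t}), ray-tracing every step against the solid faces and
#' reflecting specularly; this realises impermeable cell membranes. The
#' mean squared radial displacement is recorded at the output cadence and
#' reduced to the time-dependent effective diffusivity
#' \eqn{D^*(t) = \langle r^2\rangle / 6t} and tortuosity
#' \eqn{\tau_g(t) = \sqrt{D/D^*}}.
#'
#' Molecules are not reflected at the outer ensemble bounds: a molecule
#' leaving the ensemble invalidates the run (the geometry it would see is
#' undefined), so the function then raises a containment error naming the
#' earliest escape time; choose the ensemble large enough.
#'
#' @param ens An `ensemble` (possibly [free_space()]).
#' @param cfg A `sim_config`.
#' @return An object of class `time_course`: a data frame with columns
#'   `t_s`, `msd_um2`, `d_star_um2_s`, `d_star_cm2_s`, `tau_g`,
#'   `r_2rms_um`, with the final molecule positions, the configuration and
#'   walker counters in attributes (`positions`, `config`, `left_count`,
#'   `resample_count`, `total_reflections`, `geometry`).
#' @export
run_walk <- function(ens, cfg) {
  stopifnot(inherits(ens, "ensemble"), inherits(cfg, "sim_config"))
  if (!is.null(ens$cell)) {
    d <- ens$cell$dims
    lr <- mean_radial_step(cfg$D, cfg$dt)
    if (2 * d$w / lr < cfg$safety_factor)
      stop(sprintf(
        "time step too large: mean radial step %.3g um vs sheet width %.3g um (ratio %.2f < safety factor %g)",
        lr, 2 * d$w, 2 * d$w / lr, cfg$safety_factor), call. = FALSE)
    origin_class <- classify_points(ens, ens$release_origin)
    if (origin_class == "solid")
      stop("release origin classifies as solid; invalid geometry", call. = FALSE)
    boxes <- ens$cell$solid_boxes
    p <- d$p
  } else {
    boxes <- matrix(numeric(0), 0, 6)
    p <- 1
  }
  res <- .walk_cpp(boxes, p, ens$bounds, ens$release_origin,
                   cfg$n_molecules, cfg$D, cfg$dt, cfg$n_steps,
                   cfg$output_every, cfg$max_reflections,
                   as.double(cfg$seed))
  if (res$left_count > 0)
    stop(sprintf(
      "containment failure: %d molecule(s) left the ensemble, earliest at t = %.3g s; enlarge the ensemble",
      as.integer(res$left_count), res$first_escape_step * cfg$dt),
      call. = FALSE)
  d_star <- res$msd / (6 * res$t)
  tc <- data.frame(t_s = res$t, msd_um2 = res$msd, d_star_um2_s = d_star,
                   d_star_cm2_s = d_star / 1e8,
                   tau_g = sqrt(cfg$D / d_star),
                   r_2rms_um = 2 * sqrt(res$msd))
  attr(tc, "positions") <- res$positions
  attr(tc, "config") <- cfg
  attr(tc, "geometry") <- if (is.null(ens$cell)) list(model = "free") else
    geometry_summary(ens)
  attr(tc, "left_count") <- as.integer(res$left_count)
  attr(tc, "resample_count") <- as.integer(res$resample_count)
  attr(tc, "total_reflections") <- res$total_reflections
  class(tc) <- c("time_course", "data.frame")
  tc
}

#' @export
print.time_course <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<time_course> %d molecules, dt = %.3g s, %d output points, seed %d\n",
              cfg$n_molecules, cfg$dt, nrow(x), cfg$seed))
  cat(sprintf("  final t = %.4g s, tau_g = %.4f, r_2rms = %.3g um\n",
              x$t_s[nrow(x)], x$tau_g[nrow(x)], x$r_2rms_um[nrow(x)]))
  invisible(x)
}

#' Radial statistics of a molecule population
#'
#' @param positions m x 3 matrix of positions, micrometres.
#' @param origin Release point (default the global origin).
#' @return List with `msd` (mean squared radial distance, um^2) and
#'   `r_2rms` (twice the RMS radial distance, um).
#' @export
radial_stats <- function(positions, origin = c(0, 0, 0)) {
  stopifnot(is.matrix(positions), ncol(positions) == 3, nrow(positions) >= 1)
  dd <- sweep(positions, 2, origin)
  msd <- mean(rowSums(dd^2))
  list(msd = msd, r_2rms = 2 * sqrt(msd))
}

#' Project molecules in a slab around the x-y plane
#'
#' Selects molecules with `|z| <= half_thickness` and returns their x-y
#' coordinates, the standard visualisation slice through the ensemble
#' centre.
#'
#' @param positions m x 3 matrix of positions, micrometres.
#' @param half_thickness Slab half-thickness in micrometres (conventionally
#'   the bounding-cube half-width p).
#' @return m' x 2 matrix of x-y coordinates.
#' @export
snapshot_slice <- function(positions, half_thickness) {
  stopifnot(is.matrix(positions), ncol(positions) == 3, half_thickness > 0)
  positions[abs(positions[, 3]) <= half_thickness, 1:2, drop = FALSE]
}

#' Deterministic single-step reflection (testing aid)
#'
#' Advances one point by a prescribed displacement with the same specular
#' reflection logic as the walker, returning the endpoint, number of
#' reflections and total path length travelled.
#'
#' @param ens An `ensemble`.
#' @param from Length-3 start point, micrometres.
#' @param disp Length-3 displacement, micrometres.
#' @param max_reflections Reflection cap.
#' @return List with `end`, `n_reflections`, `path_length`.
#' @export
reflect_step <- function(ens, from, disp, max_reflections = 64L) {
  stopifnot(inherits(ens, "ensemble"))
  boxes <- if (is.null(ens$cell)) matrix(numeric(0), 0, 6) else
    ens$cell$solid_boxes
  p <- if (is.null(ens$cell)) 1 else ens$cell$dims$p
  .reflect_step_cpp(boxes, p, as.double(from), as.double(disp),
                    as.integer(max_reflections))
}
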