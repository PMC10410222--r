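# Shared fixtures and independent oracles, built in code at test time.

# Printed fitting coefficients of the tau^2-Omega laws (linear CCV at
# normal porosity, cubic CCV at high porosity, quartic ETV), used as
# inputs to the inversion machinery.
ccv_linear_fits <- function() {
  list(
    tau_omega_fit(1.437, 0.941, phi = 0.1),
    tau_omega_fit(1.399, 0.722, phi = 0.2),
    tau_omega_fit(1.345, 0.463, phi = 0.4))
}

ccv_cubic_fit_phi09 <- function() {
  tau_omega_fit(1.069, c(0.236, -0.0132, 0.000328), phi = 0.9)
}

etv_quartic_fit_phi02 <- function() {
  tau_omega_fit(1.422, c(0.270, -0.0668, 0.00862, -0.000430), phi = 0.2)
}

# Brute-force point classifier: explicit loop over every cell of the
# ensemble, direct box-membership tests, no period folding. Slow but
# independent of the production classifier.
classify_brute <- function(ens, xyz) {
  d <- ens$cell$dims
  p <- d$p
  k <- ens$n / 2
  centres <- as.matrix(expand.grid(x = (2 * seq(-k, k - 1) + 1) * p,
                                   y = (2 * seq(-k, k - 1) + 1) * p,
                                   z = (2 * seq(-k, k - 1) + 1) * p))
  solid <- ens$cell$solid_boxes
  cuts <- ens$cell$cut_boxes
  in_any_box <- function(u, boxes) {
    for (bi in seq_len(nrow(boxes))) {
      if (all(u >= boxes[bi, 1:3]) && all(u <= boxes[bi, 4:6])) return(TRUE)
    }
    FALSE
  }
  out <- character(nrow(xyz))
  for (i in seq_len(nrow(xyz))) {
    x <- xyz[i, ]
    if (any(abs(x) > ens$bounds)) { out[i] <- "outside"; next }
    cls <- "sheet"
    for (ci in seq_len(nrow(centres))) {
      u <- x - centres[ci, ]
      if (any(abs(u) > d$a)) next   # not inside this basic cube
      cls <- if (nrow(cuts) && in_any_box(u, cuts)) "void" else "solid"
      break
    }
    out[i] <- cls
  }
  out
}

# Study-scale walker runs reused across test files (computed once per
# test session). 2000 molecules give ~1% stochastic error on tau; output
# cadence 500 steps (10 us).
walker_cache <- new.env(parent = emptyenv())

cached_run <- function(key, maker) {
  if (is.null(walker_cache[[key]])) walker_cache[[key]] <- maker()
  walker_cache[[key]]
}

# Reference phi = 0.2 CCV run (a = 0.416 um, b = 0.1785 um, w = 20 nm,
# Omega = 0.522): 5000 molecules, dt = 20 ns, 4 ms; plateau onset 2 ms.
ccv_reference_run <- function() {
  dims <- cell_dims("ccv", 0.2, 0.020, a = 0.416)
  ens <- build_ensemble(build_cell(dims), 32)
  cfg <- sim_config(d_cm2_s = 7.71e-6, dt_s = 2e-8, duration_s = 4e-3,
                    n_molecules = 5000L, output_every = 500L, seed = 1,
                    preset = "custom")
  run_walk(ens, cfg)
}
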