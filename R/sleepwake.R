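## Two-state (asleep / awake) porosity inference on the CCV model.
##
## In the normal porosity range the squared tortuosity is linear in the
## void-to-sheet ratio, so one simulated trial point per state plus the
## zero-void anchor from the corrected cubic-lattice relation pins the
## whole line; inverting it at the shared measured tortuosity gives the
## void ratio of each state, and the scale factors A and B then resolve
## the full cell geometry for any sheet half-width.

#' Asleep/awake two-state inference on the CCV model
#'
#' For each brain state (characterised by its measured porosity) a line
#' \eqn{\tau^2 = \tau_0^2 + m\Omega} is anchored at \eqn{\Omega = 0} with
#' \eqn{\tau_0} from the corrected uniform-lattice relation and at one
#' simulated trial point \eqn{(\Omega_1, \tau_1)}. Solving each line at
#' the shared target tortuosity `tau_sw` yields the state's void ratio
#' \eqn{\Omega}; scale factors \eqn{A = a/w} and \eqn{B = b/a} then give
#' the cell geometry for every requested sheet half-width. A final row
#' imposes a constant bounding cube across the transition
#' (\eqn{p_{awake} = p_{sleep}} at the reference sheet width), which fixes
#' the awake sheet half-width as \eqn{w = p_s/(1 + A_w)}.
#'
#' @param phi_sleep,phi_awake Porosities of the two states.
#' @param tau_sw Shared target geometrical tortuosity (apply any viscous
#'   factorisation before calling, see [tortuosity_target()]).
#' @param trial_sleep,trial_awake Length-2 vectors `c(omega, tau)`: the
#'   trial void ratio and the simulated tortuosity there.
#' @param w_um Sheet half-widths (micrometres) for the geometry rows.
#' @param reference_w_um Sleep-state sheet half-width defining the
#'   reference bounding cube for the constant-volume row.
#' @return Object of class `sleepwake`: per-state anchors, slopes,
#'   omegas, scale factors, geometry tables (data frames with `w_um`,
#'   `a_um`, `b_um`, `p_um`) and the constant-bounding-cube row.
#' @examples
#' sw <- sleepwake_analysis()
#' sw$sleep$omega   # 1.500 at tau_sw = 1.55
#' @export
sleepwake_analysis <- function(phi_sleep = 0.234, phi_awake = 0.141,
                               tau_sw = 1.55,
                               trial_sleep = c(omega = 4.0, tau = 2.013),
                               trial_awake = c(omega = 3.0, tau = 1.981),
                               w_um = c(0.010, 0.020, 0.040),
                               reference_w_um = 0.020) {
  .check_scalar(tau_sw, "tau_sw", 1)
  one_state <- function(phi, trial) {
    tau0 <- tau_uniform_lattice(phi)
    m <- (trial[["tau"]]^2 - tau0^2) / trial[["omega"]]
    fit <- tau_omega_fit(tau0^2, m, phi = phi,
                         omega_range = c(0, trial[["omega"]]))
    omega <- omega_at_tau(fit, tau_sw)
    A <- scale_factor_A(omega, phi)
    B <- void_ratio_B(omega, phi)
    geom <- data.frame(w_um = w_um, a_um = A * w_um, b_um = A * B * w_um,
                       p_um = (1 + A) * w_um)
    list(phi = phi, tau0 = tau0, m = m, fit = fit, omega = omega,
         A = A, B = B, geometry = geom)
  }
  sleep <- one_state(phi_sleep, trial_sleep)
  awake <- one_state(phi_awake, trial_awake)
  p_ref <- (1 + sleep$A) * reference_w_um
  w_const <- constant_bounding_w(p_ref, awake$A)
  const_row <- data.frame(w_um = w_const, a_um = awake$A * w_const,
                          b_um = awake$A * awake$B * w_const,
                          p_um = (1 + awake$A) * w_const)
  structure(list(sleep = sleep, awake = awake, tau_sw = tau_sw,
                 reference_w_um = reference_w_um, p_ref = p_ref,
                 constant_p = const_row),
            class = "sleepwake")
}

#' @export
print.sleepwake <- function(x, ...) {
  fmt_state <- function(name, s) {
    cat(sprintf("  %s: phi = %.3f, tau0 = %.4f, m = %.4f, Omega = %.4f, A = %.4g, B = %.4f\n",
                name, s$phi, s$tau0, s$m, s$omega, s$A, s$B))
  }
  cat(sprintf("<sleepwake> shared tau = %.4g\n", x$tau_sw))
  fmt_state("sleep", x$sleep)
  fmt_state("awake", x$awake)
  cat(sprintf("  constant bounding cube (p = %.4f um): awake w = %.4f nm, a = %.4f, b = %.4f um\n",
              x$p_ref, 1e3 * x$constant_p$w_um, x$constant_p$a_um,
              x$constant_p$b_um))
  invisible(x)
}

#' Flatten a sleepwake analysis to a table
#'
#' @param x A `sleepwake` object.
#' @return Data frame with one row per state and sheet width plus the
#'   constant-bounding-cube row (`state`, `w_um`, `a_um`, `b_um`, `p_um`,
#'   `omega`).
#' @export
sleepwake_table <- function(x) {
  stopifnot(inherits(x, "sleepwake"))
  rows <- rbind(
    cbind(state = "sleep", x$sleep$geometry, omega = x$sleep$omega),
    cbind(state = "awake", x$awake$geometry, omega = x$awake$omega),
    cbind(state = "awake_const_p", x$constant_p, omega = x$awake$omega))
  rownames(rows) <- NULL
  rows
}
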