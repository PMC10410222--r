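## Reduction of time courses to steady-state tortuosity and the
## tortuosity-versus-void-ratio fitting / inversion machinery.

#' Effective diffusivity from mean squared displacement
#'
#' \eqn{D^* = \langle r^2 \rangle / 6t} for three-dimensional diffusion
#' from a point source. Only at steady state (Gaussian displacement
#' distribution) is this a classic diffusivity.
#'
#' @param msd Mean squared radial displacement, um^2.
#' @param t Time, seconds (> 0).
#' @return Effective diffusivity in um^2/s.
#' @export
effective_diffusivity <- function(msd, t) {
  if (any(t <= 0)) stop("`t` must be positive", call. = FALSE)
  msd / (6 * t)
}

#' Geometrical tortuosity from free and effective diffusivity
#'
#' \eqn{\tau_g = \sqrt{D / D^*}}; both diffusivities must be in the same
#' units.
#'
#' @param D Free diffusivity (> 0).
#' @param D_star Effective diffusivity (> 0).
#' @return Tortuosity (dimensionless, >= 1 for a hindering medium).
#' @export
tortuosity_of <- function(D, D_star) {
  if (any(D <= 0) || any(D_star <= 0))
    stop("diffusivities must be positive", call. = FALSE)
  sqrt(D / D_star)
}

#' Factor a measured tortuosity into geometric and viscous components
#'
#' Tortuosity components multiply: if part of the measured hindrance is
#' attributed to interstitial viscosity (literature value 1.2), the
#' geometrical target becomes
#' \eqn{\tau_g = \tau_{measured} / \tau_{viscous}}. With the typical
#' measured 1.6 this gives 1.333.
#'
#' @param tau_measured Measured tortuosity (>= 1).
#' @param tau_viscous Viscous component (default 1 = no viscosity;
#'   use 1.2 for the literature estimate).
#' @return List with `tau_measured`, `tau_viscous`, `tau_g`.
#' @export
tortuosity_target <- function(tau_measured, tau_viscous = 1) {
  .check_scalar(tau_measured, "tau_measured", 1)
  .check_scalar(tau_viscous, "tau_viscous", 1)
  tau_g <- tau_measured / tau_viscous
  if (tau_g < 1)
    stop("geometric tortuosity below 1: viscous component too large", call. = FALSE)
  list(tau_measured = tau_measured, tau_viscous = tau_viscous, tau_g = tau_g)
}

#' Detect the steady-state plateau of a tortuosity time course
#'
#' The tortuosity of a point-source run rises to an early peak (molecules
#' meeting the first walls), declines, and settles on a plateau once the
#' molecule distribution is Gaussian. The plateau onset is found as the
#' earliest time after the peak at which the log-log slope of
#' \eqn{\tau_g^2(t)}, estimated by regression over a trailing window of
#' `window_decades` decades, falls below `rel_slope_tol` in magnitude;
#' the tortuosity is then averaged from the onset to the end of the run.
#'
#' @param tc A `time_course` (or data frame with `t_s` and `tau_g`).
#' @param rel_slope_tol Slope tolerance on the log-log curve (default
#'   0.01).
#' @param window_decades Width of the trailing regression window in
#'   decades of time (default 0.25).
#' @return List of class `steady_state`: `t_onset`, `t_end`, `tau_mean`,
#'   `tau_sd`, `n_window`.
#' @export
detect_steady_state <- function(tc, rel_slope_tol = 0.01,
                                window_decades = 0.25) {
  t <- tc$t_s; tau <- tc$tau_g
  stopifnot(length(t) >= 10, all(diff(t) > 0))
  lt <- log(t); ly <- log(tau^2)
  i_peak <- which.max(tau)
  if (i_peak >= length(t) - 4L)
    stop("no steady state found: tortuosity still rising at the end of the run",
         call. = FALSE)
  wd <- window_decades * log(10)
  onset <- NA_real_; i_onset <- NA_integer_
  for (i in seq(i_peak + 1L, length(t))) {
    j <- which(lt >= lt[i] - wd & lt <= lt[i])
    # the regression window must lie entirely past the peak, otherwise the
    # near-zero average slope across the peak top mimics a plateau
    if (length(j) < 4 || lt[min(j)] <= lt[i_peak]) next
    slope <- stats::coef(stats::lm.fit(cbind(1, lt[j]), ly[j]))[2]
    if (abs(slope) < rel_slope_tol) { onset <- t[i]; i_onset <- i; break }
  }
  if (is.na(onset))
    stop("no steady state found: tortuosity still drifting; run the simulation longer",
         call. = FALSE)
  idx <- seq(i_onset, length(t))
  structure(list(t_onset = onset, t_end = t[length(t)],
                 tau_mean = mean(tau[idx]), tau_sd = stats::sd(tau[idx]),
                 n_window = length(idx)),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("<steady_state> tau_g = %.4f +/- %.4f over [%.3g, %.3g] s (%d points)\n",
              x$tau_mean, x$tau_sd, x$t_onset, x$t_end, x$n_window))
  invisible(x)
}

#' Gaussianity check of the molecule distribution
#'
#' Histograms each coordinate axis of the molecule positions and compares
#' the counts against the Gaussian expected at steady state
#' (zero mean, variance \eqn{2 D^* t}), scaled to the total count; the
#' agreement is summarised per axis by
#' \eqn{R^2 = 1 - (\lVert residuals\rVert / \lVert Y - \bar Y\rVert)^2}.
#'
#' @param positions m x 3 matrix of positions (m >= 1000), micrometres.
#' @param d_star Effective diffusivity at time `t`, um^2/s.
#' @param t Time of the snapshot, seconds.
#' @param bin_width Histogram bin width in micrometres (conventionally 4p).
#' @return List of class `gaussianity_report`: per-axis histograms,
#'   reference curves and `r_squared` (length-3 vector).
#' @export
gaussianity_r2 <- function(positions, d_star, t, bin_width) {
  stopifnot(is.matrix(positions), ncol(positions) == 3,
            nrow(positions) >= 1000, d_star > 0, t > 0, bin_width > 0)
  sigma <- sqrt(2 * d_star * t)
  if (sigma == 0 || any(apply(positions, 2, stats::sd) == 0))
    stop("degenerate (zero-variance) molecule distribution", call. = FALSE)
  n <- nrow(positions)
  axes <- lapply(1:3, function(k) {
    x <- positions[, k]
    lim <- max(abs(x)) + bin_width
    breaks <- seq(-ceiling(lim / bin_width), ceiling(lim / bin_width)) * bin_width
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    expected <- n * bin_width * stats::dnorm(h$mids, 0, sigma)
    resid <- h$counts - expected
    r2 <- 1 - (sqrt(sum(resid^2)) / sqrt(sum((h$counts - mean(h$counts))^2)))^2
    list(mids = h$mids, counts = h$counts, expected = expected, r_squared = r2)
  })
  structure(list(axes = axes, sigma = sigma, bin_width = bin_width,
                 r_squared = vapply(axes, `[[`, numeric(1), "r_squared")),
            class = "gaussianity_report")
}

#' Construct tortuosity-vs-void-ratio fit coefficients
#'
#' Represents \eqn{\tau_g^2 = \tau_{g0}^2 + m_1\Omega + m_2\Omega^2 +
#' m_3\Omega^3 + m_4\Omega^4} truncated at the given order. Order 1 is the
#' linear law of the CCV model at normal porosity, order 3 the CCV law at
#' high porosity, order 4 the ETV law.
#'
#' @param tau_g0_sq Constant term (squared zero-void tortuosity).
#' @param m Numeric vector of polynomial coefficients `m1..m_order`.
#' @param phi Porosity the fit belongs to (metadata, optional).
#' @param omega_range Omega interval over which the fit was made
#'   (optional; inversion outside it is flagged).
#' @param r_squared Coefficient of determination (metadata, optional).
#' @return Object of class `tau_omega_fit`.
#' @export
tau_omega_fit <- function(tau_g0_sq, m, phi = NULL, omega_range = NULL,
                          r_squared = NA_real_) {
  order <- length(m)
  if (!order %in% c(1L, 3L, 4L))
    stop("fit order must be 1, 3 or 4", call. = FALSE)
  structure(list(order = order, tau_g0_sq = tau_g0_sq, m = m, phi = phi,
                 omega_range = omega_range, r_squared = r_squared),
            class = "tau_omega_fit")
}

#' @export
print.tau_omega_fit <- function(x, ...) {
  terms <- paste(sprintf("%+.4g*Omega^%d", x$m, seq_along(x$m)), collapse = " ")
  cat(sprintf("<tau_omega_fit> order %d%s: tau_g^2 = %.4g %s\n", x$order,
              if (!is.null(x$phi)) sprintf(" (phi = %g)", x$phi) else "",
              x$tau_g0_sq, terms))
  if (!is.na(x$r_squared)) cat(sprintf("  R^2 = %.6g\n", x$r_squared))
  if (!is.null(x$omega_range))
    cat(sprintf("  fitted on Omega in [%g, %g]\n",
                x$omega_range[1], x$omega_range[2]))
  invisible(x)
}

#' Evaluate a tau-omega fit
#'
#' @param fit A `tau_omega_fit`.
#' @param omega Omega values.
#' @return \eqn{\tau_g^2} at each omega.
#' @export
eval_fit <- function(fit, omega) {
  stopifnot(inherits(fit, "tau_omega_fit"))
  drop(outer(omega, seq_len(fit$order), `^`) %*% fit$m) + fit$tau_g0_sq
}

#' Least-squares polynomial fit of squared tortuosity against Omega
#'
#' Fits \eqn{\tau_g^2} as a polynomial in \eqn{\Omega} of the given order
#' by ordinary least squares and reports
#' \eqn{R^2 = 1 - (\lVert residuals\rVert/\lVert Y - \bar Y\rVert)^2}.
#'
#' @param omega Omega values (length >= order + 2).
#' @param tau_sq Squared tortuosities.
#' @param order Polynomial order: 1, 3 or 4.
#' @param phi Porosity metadata attached to the fit.
#' @return A `tau_omega_fit` with the fitted coefficients, R^2 and the
#'   Omega range of the data.
#' @export
fit_tau_omega <- function(omega, tau_sq, order = 1L, phi = NULL) {
  order <- as.integer(order)
  if (length(omega) < order + 2)
    stop("need at least order + 2 points", call. = FALSE)
  X <- outer(omega, 0:order, `^`)
  qr_X <- qr(X)
  if (qr_X$rank < order + 1)
    stop("rank-deficient design: omega values do not support this order",
         call. = FALSE)
  beta <- qr.coef(qr_X, tau_sq)
  resid <- tau_sq - drop(X %*% beta)
  r2 <- 1 - (sqrt(sum(resid^2)) / sqrt(sum((tau_sq - mean(tau_sq))^2)))^2
  tau_omega_fit(beta[1], beta[-1], phi = phi,
                omega_range = range(omega), r_squared = r2)
}

#' Invert a tau-omega fit for the void ratio at a target tortuosity
#'
#' For the linear law the solution is closed-form,
#' \eqn{\Omega = (\tau_g^2 - \tau_{g0}^2)/m_1}; for cubic and quartic fits
#' the real roots of the polynomial are computed and the smallest
#' non-negative one inside the fitted Omega range is returned (the fitted
#' curve has no physical meaning beyond its data, so roots outside the
#' range are reported in the error message but not returned).
#'
#' @param fit A `tau_omega_fit`.
#' @param tau_g Target geometrical tortuosity (after any viscous
#'   factorisation, see [tortuosity_target()]).
#' @return Omega (>= 0).
#' @export
omega_at_tau <- function(fit, tau_g) {
  stopifnot(inherits(fit, "tau_omega_fit"))
  .check_scalar(tau_g, "tau_g", 0, open_lower = TRUE)
  target <- tau_g^2
  if (fit$order == 1L) {
    omega <- (target - fit$tau_g0_sq) / fit$m[1]
    if (omega < 0) {
      if (omega > -1e-10) return(0)
      stop(sprintf("tortuosity unreachable: target below the zero-void anchor (Omega = %g)",
                   omega), call. = FALSE)
    }
  } else {
    roots <- polyroot(c(fit$tau_g0_sq - target, fit$m))
    real <- Re(roots[abs(Im(roots)) < 1e-8 * (1 + Mod(roots))])
    real[real > -1e-10 & real < 0] <- 0
    cand <- sort(real[real >= 0])
    if (!is.null(fit$omega_range)) {
      inside <- cand[cand <= fit$omega_range[2] * (1 + 1e-9)]
      if (length(inside) == 0)
        stop(sprintf(
          "tortuosity unreachable within the fitted range [%g, %g]%s",
          fit$omega_range[1], fit$omega_range[2],
          if (length(cand)) sprintf(" (roots outside range: %s)",
                                    paste(signif(cand, 6), collapse = ", "))
          else " (no non-negative real root)"), call. = FALSE)
      cand <- inside
    }
    if (length(cand) == 0)
      stop("tortuosity unreachable: no non-negative real root", call. = FALSE)
    omega <- cand[1]
  }
  omega
}

#' Geometry tables from fitted tortuosity laws
#'
#' For each porosity (with its fit), target tortuosity and sheet
#' half-width, inverts the fit for Omega and resolves the CCV cell
#' geometry `a = A w`, `b = B a`.
#'
#' @param fits Named list of `tau_omega_fit` objects; names are porosities
#'   (e.g. `"0.2"`), or fits carrying `phi` metadata.
#' @param tau_targets Target geometrical tortuosities.
#' @param w_um Sheet half-widths in micrometres.
#' @return Data frame with columns `phi`, `tau_g`, `omega`, `w_um`,
#'   `a_um`, `b_um`, `p_um`.
#' @export
solve_geometry_table <- function(fits, tau_targets, w_um) {
  rows <- list()
  for (fit in fits) {
    phi <- fit$phi
    if (is.null(phi)) stop("each fit needs `phi` metadata", call. = FALSE)
    for (tau in tau_targets) {
      omega <- omega_at_tau(fit, tau)
      A <- scale_factor_A(omega, phi)
      B <- void_ratio_B(omega, phi)
      for (w in w_um) {
        a <- A * w
        rows[[length(rows) + 1L]] <- data.frame(
          phi = phi, tau_g = tau, omega = omega, w_um = w,
          a_um = a, b_um = B * a, p_um = a + w)
      }
    }
  }
  do.call(rbind, rows)
}
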