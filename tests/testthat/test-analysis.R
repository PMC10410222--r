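# Time-course reduction, polynomial fitting and inversion.

test_that("effective diffusivity and tortuosity follow their definitions", {
  expect_equal(effective_diffusivity(6, 1), 1)
  expect_equal(effective_diffusivity(6 * 771 * 0.01, 0.01), 771)
  expect_error(effective_diffusivity(1, 0), "positive")
  expect_equal(tortuosity_of(1, 1), 1)
  # the experimental range: D = 1.11e-5, D* in [3.84e-6, 4.93e-6] cm^2/s
  # spans tau in [1.5, 1.7]
  expect_equal(tortuosity_of(1.11e-5, 4.93e-6), 1.5, tolerance = 1e-2)
  expect_equal(tortuosity_of(1.11e-5, 3.84e-6), 1.7, tolerance = 1e-2)
  expect_equal(tortuosity_of(1, 1 / 2.56), 1.6, tolerance = 1e-12)
  expect_error(tortuosity_of(1, 0), "positive")
})

test_that("viscous factorisation of the measured tortuosity is exact", {
  tt <- tortuosity_target(1.6, 1.2)
  expect_equal(tt$tau_g, 1.6 / 1.2)
  expect_equal(round(tt$tau_g, 3), 1.333)
  expect_equal(tortuosity_target(1.6)$tau_g, 1.6)
  expect_error(tortuosity_target(1.1, 1.2), "viscous component too large")
})

test_that("steady-state detection finds the plateau of synthetic curves", {
  t <- exp(seq(log(1e-5), log(2e-2), length.out = 400))
  # constant curve: onset at the first admissible window, exact mean
  tc_const <- data.frame(t_s = t, tau_g = rep(1.42, length(t)))
  ss <- detect_steady_state(tc_const)
  expect_equal(ss$tau_mean, 1.42, tolerance = 1e-12)
  expect_identical(ss$tau_sd, 0)
  expect_lt(ss$t_onset, 5e-5)
  # peaked curve relaxing onto a plateau (the shape of real runs):
  # tau^2 = y0 + c (t/t2) exp(1 - t/t2) peaks at t2 and decays to y0
  t2 <- 2e-4; y0 <- 1.69; cc <- 0.3
  tc_peak <- data.frame(t_s = t,
                        tau_g = sqrt(y0 + cc * (t / t2) * exp(1 - t / t2)))
  ss2 <- detect_steady_state(tc_peak, rel_slope_tol = 0.01)
  # closed-form log-log slope of the synthetic curve at the onset
  slope <- function(tt) {
    ex <- cc * (tt / t2) * exp(1 - tt / t2)
    abs(ex * (1 - tt / t2)) / (y0 + ex)
  }
  expect_gt(ss2$t_onset, t2)             # cannot converge before the peak
  expect_lt(slope(ss2$t_onset), 0.02)
  expect_equal(ss2$tau_mean, sqrt(y0), tolerance = 5e-3)
  # a curve still rising at the end has no plateau
  tc_rise <- data.frame(t_s = t, tau_g = 1 + t / max(t))
  expect_error(detect_steady_state(tc_rise), "no steady state")
})

test_that("gaussianity R^2 separates Gaussian from uniform populations", {
  set.seed(21)
  d_star <- 300; t <- 2e-3
  sigma <- sqrt(2 * d_star * t)
  n <- 20000
  gauss <- matrix(rnorm(3 * n, sd = sigma), ncol = 3)
  rep_g <- gaussianity_r2(gauss, d_star, t, bin_width = sigma / 2)
  expect_true(all(rep_g$r_squared > 0.99))
  unif <- matrix(runif(3 * n, -2 * sigma, 2 * sigma), ncol = 3)
  rep_u <- gaussianity_r2(unif, d_star, t, bin_width = sigma / 2)
  expect_true(all(rep_u$r_squared < 0.9))
  # zero residuals give R^2 = 1 by the norm formula
  y <- c(1, 4, 9, 4, 1)
  expect_equal(1 - (0 / sqrt(sum((y - mean(y))^2)))^2, 1)
})

test_that("polynomial fits recover noiseless coefficients to 10 digits", {
  omega <- seq(0, 8, length.out = 12)
  # linear law
  f1 <- fit_tau_omega(omega, 1.4 + 0.7 * omega, order = 1)
  expect_equal(f1$tau_g0_sq, 1.4, tolerance = 1e-12)
  expect_equal(unname(f1$m), 0.7, tolerance = 1e-12)
  expect_equal(f1$r_squared, 1, tolerance = 1e-12)
  # cubic and quartic with table-scale coefficients
  cub <- c(0.236, -0.0132, 0.000328)
  y3 <- 1.069 + drop(outer(omega, 1:3, `^`) %*% cub)
  f3 <- fit_tau_omega(omega, y3, order = 3)
  expect_equal(unname(f3$m), cub, tolerance = 1e-10)
  qua <- c(0.270, -0.0668, 0.00862, -0.000430)
  y4 <- 1.422 + drop(outer(omega, 1:4, `^`) %*% qua)
  f4 <- fit_tau_omega(omega, y4, order = 4)
  expect_equal(unname(f4$m), qua, tolerance = 1e-10)
  expect_equal(f4$tau_g0_sq, 1.422, tolerance = 1e-10)
  # evaluation at omega = 0 returns the constant term
  expect_equal(eval_fit(f4, 0), 1.422, tolerance = 1e-10)
  # degenerate designs are rejected
  expect_error(fit_tau_omega(c(1, 2), c(1, 2), order = 1), "at least")
  expect_error(fit_tau_omega(rep(1, 6), rnorm(6), order = 3), "rank")
})

test_that("inversion returns the printed roots of the fitted laws", {
  # linear CCV law at phi = 0.2: tau = 1.6 -> Omega = 1.608
  f02 <- tau_omega_fit(1.399, 0.722, phi = 0.2)
  expect_equal(omega_at_tau(f02, 1.6), 1.608, tolerance = 5e-4)
  expect_equal(omega_at_tau(f02, 1.333), 0.523, tolerance = 2e-3)
  # at the anchor the root is 0
  expect_equal(omega_at_tau(f02, sqrt(1.399)), 0)
  expect_error(omega_at_tau(f02, 1.0), "unreachable")
  # cubic CCV law at phi = 0.9: tau^2 = 2.56 -> Omega = 11.886
  f09 <- ccv_cubic_fit_phi09()
  expect_equal(omega_at_tau(f09, 1.6), 11.886, tolerance = 5e-4)
  expect_equal(omega_at_tau(f09, 1.333), 3.692, tolerance = 5e-3)
  # quartic ETV law at phi = 0.2: tau = 1.333 -> Omega = 2.25; with the
  # 3-significant-figure published coefficients the root lands at 2.230,
  # within 1% of the published solution of the unrounded fit
  fe <- etv_quartic_fit_phi02()
  expect_equal(omega_at_tau(fe, 1.333), 2.25, tolerance = 1e-2)
  expect_equal(omega_at_tau(fe, 1.333), 2.2302, tolerance = 1e-4)
  # the ETV curves never reach tau = 1.6 within their fitted range
  fe_ranged <- tau_omega_fit(1.422, c(0.270, -0.0668, 0.00862, -0.000430),
                             phi = 0.2, omega_range = c(0, 7))
  expect_error(omega_at_tau(fe_ranged, 1.6), "unreachable")
})

test_that("inversion is the exact inverse of evaluation", {
  fits <- list(tau_omega_fit(1.399, 0.722, phi = 0.2),
               ccv_cubic_fit_phi09(), etv_quartic_fit_phi02())
  for (fit in fits) {
    for (om in c(0.2, 0.9, 2.1)) {
      tau <- sqrt(eval_fit(fit, om))
      expect_equal(eval_fit(fit, omega_at_tau(fit, tau)), tau^2,
                   tolerance = 1e-10)
    }
  }
})

test_that("fitted CCV laws are increasing over their range at phi <= 0.4", {
  for (fit in ccv_linear_fits()) {
    om <- seq(0, 3, length.out = 50)
    expect_true(all(diff(eval_fit(fit, om)) > 0))
  }
})

test_that("geometry tables reproduce the printed solutions", {
  tab <- solve_geometry_table(ccv_linear_fits(), c(1.6, 1.333),
                              c(0.010, 0.020, 0.040))
  # spot checks across the three sheet widths (printed to 3 decimals)
  g <- function(phi, tau, w) tab[tab$phi == phi & tab$tau_g == tau &
                                 tab$w_um == w, ]
  r <- g(0.2, 1.6, 0.010)
  expect_equal(r$omega, 1.608, tolerance = 5e-4)
  expect_equal(r$a_um, 0.371, tolerance = 2e-3)
  expect_equal(r$b_um, 0.190, tolerance = 3e-3)
  r <- g(0.2, 1.6, 0.020)
  expect_equal(r$a_um, 0.742, tolerance = 2e-3)
  expect_equal(r$b_um, 0.379, tolerance = 3e-3)
  r <- g(0.2, 1.6, 0.040)
  expect_equal(r$a_um, 1.484, tolerance = 2e-3)
  expect_equal(r$b_um, 0.759, tolerance = 3e-3)
  r <- g(0.1, 1.333, 0.020)
  expect_equal(r$omega, 0.361, tolerance = 2e-3)
  expect_equal(r$a_um, 0.776, tolerance = 3e-3)
  expect_equal(r$b_um, 0.238, tolerance = 5e-3)
  r <- g(0.4, 1.6, 0.020)
  expect_equal(r$omega, 2.624, tolerance = 5e-4)
  expect_equal(r$a_um, 0.503, tolerance = 3e-3)
  expect_equal(r$b_um, 0.346, tolerance = 3e-3)
  # scale invariance: same omega at different w gives identical ratios
  r10 <- g(0.2, 1.6, 0.010); r40 <- g(0.2, 1.6, 0.040)
  expect_equal(r10$a_um / 0.010, r40$a_um / 0.040, tolerance = 1e-12)
  expect_equal(r10$b_um / r10$a_um, r40$b_um / r40$a_um, tolerance = 1e-12)
})
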