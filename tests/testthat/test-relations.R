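# Closed-form geometry relations: printed-value checks, limits and
# round-trip properties.

test_that("uniform-lattice tortuosity matches its limits and anchors", {
  # phi -> 0 limit, both forms
  expect_equal(tau_uniform_lattice(0, corrected = FALSE), sqrt(1.5),
               tolerance = 1e-12)
  expect_equal(tau_uniform_lattice(0, corrected = TRUE), sqrt(1.5),
               tolerance = 1e-12)
  # free medium
  expect_equal(tau_uniform_lattice(1, corrected = FALSE), 1)
  # corrected anchors at the study porosities (3-decimal table entries)
  anchors <- c(`0.1` = 1.465, `0.2` = 1.427, `0.4` = 1.339,
               `0.6` = 1.237, `0.8` = 1.124, `0.9` = 1.063)
  for (nm in names(anchors)) {
    expect_equal(round(tau_uniform_lattice(as.numeric(nm))^2, 3),
                 unname(anchors[nm]))
  }
  # two-state anchors
  expect_equal(round(tau_uniform_lattice(0.234), 3), 1.189)
  expect_equal(round(tau_uniform_lattice(0.141), 3), 1.204)
  expect_error(tau_uniform_lattice(1.2), "outside the valid range")
})

test_that("uniform cell half-width inverts the porosity relation", {
  expect_equal(uniform_cell_halfwidth(0.2, 0.020), 0.259, tolerance = 5e-4)
  # gamma = 0.8 forces a/w = 4 exactly
  expect_equal(uniform_cell_halfwidth(1 - 0.8^3, 0.013), 4 * 0.013,
               tolerance = 1e-12)
  # phi -> 1 collapses the cell
  expect_lt(uniform_cell_halfwidth(0.999999, 0.02), 1e-3)
  expect_error(uniform_cell_halfwidth(0, 0.02), "outside the valid range")
  # round trip through porosity_of_dims
  for (phi in c(0.05, 0.2, 0.5, 0.9)) {
    a <- uniform_cell_halfwidth(phi, 0.02)
    expect_equal(porosity_of_dims(a, 0, 0.02, "uniform"), phi,
                 tolerance = 1e-12)
  }
})

test_that("omega of geometry: exact form, approximation, and no-void error", {
  expect_equal(omega_of_geometry(0.742, 0.020, 0.2), 1.608, tolerance = 5e-4)
  expect_equal(omega_of_geometry(0.742, 0.020, 0.2, exact = FALSE), 1.673,
               tolerance = 5e-4)
  # uniform-lattice dims have no voids
  a0 <- uniform_cell_halfwidth(0.2, 0.02)
  expect_equal(omega_of_geometry(a0, 0.02, 0.2), 0, tolerance = 1e-10)
  expect_error(omega_of_geometry(0.5 * a0, 0.02, 0.2), "no voids")
  # the linear approximation converges as a/w grows at fixed phi
  rel_err <- sapply(c(10, 100, 1000), function(r) {
    ex <- omega_of_geometry(r * 0.02, 0.02, 0.3)
    ap <- omega_of_geometry(r * 0.02, 0.02, 0.3, exact = FALSE)
    abs(ap - ex) / ex
  })
  expect_true(all(diff(rel_err) < 0))
  expect_lt(rel_err[3], 2e-3)
})

test_that("scale factor A matches printed two-state values and the zero-void limit", {
  expect_equal(round(scale_factor_A(1.500, 0.234), 2), 30.03)
  # the printed awake Omega is itself rounded, so match to ~1e-4 relative
  expect_equal(scale_factor_A(1.154, 0.141), 43.82, tolerance = 2e-4)
  # at Omega = 0 reduces to gamma/(1-gamma)
  gam <- 0.8^(1 / 3)
  expect_equal(scale_factor_A(0, 0.2), gam / (1 - gam), tolerance = 1e-12)
  expect_equal(round(scale_factor_A(0, 0.2), 2), 12.95)
  expect_error(scale_factor_A(0.1, 1.2), "smaller than 1 \\+ omega")
})

test_that("A is strictly increasing in Omega and round-trips with omega_of_geometry", {
  for (phi in c(0.06, 0.2, 0.5, 0.94)) {
    omegas <- c(0, 0.3, 1, 2.5, 6, 12)
    A <- sapply(omegas, scale_factor_A, phi = phi)
    expect_true(all(diff(A) > 0))
    for (om in omegas) {
      w <- 0.017
      a <- scale_factor_A(om, phi) * w
      expect_equal(omega_of_geometry(a, w, phi), om, tolerance = 1e-10)
    }
  }
})

test_that("CCV void width reproduces printed geometries and round-trips", {
  expect_equal(ccv_void_width(0.742, 0.020, 0.2), 0.379, tolerance = 2e-3)
  expect_equal(ccv_void_width(0.416, 0.020, 0.2), 0.1785, tolerance = 5e-4)
  # B = b/a from the (Omega, phi) pair, two-state values
  expect_equal(round(void_ratio_B(1.500, 0.234), 4), 0.5371)
  expect_equal(round(void_ratio_B(1.154, 0.141), 4), 0.4324)
  # uniform dims give b ~ 0 (the cube root amplifies the last-bit residual)
  a0 <- uniform_cell_halfwidth(0.2, 0.02)
  expect_lt(ccv_void_width(a0, 0.02, 0.2), 1e-4)
  # round trip through porosity_of_dims to 1e-10, for cells above the
  # uniform-lattice size (smaller cells have no void solution)
  for (phi in c(0.1, 0.2, 0.4, 0.9)) {
    for (a in uniform_cell_halfwidth(phi, 0.02) * c(1.5, 3, 10)) {
      b <- ccv_void_width(a, 0.02, phi)
      expect_equal(porosity_of_dims(a, b, 0.02, "ccv"), phi,
                   tolerance = 1e-10)
    }
  }
  expect_error(ccv_void_width(0.05, 0.02, 0.2), "no CCV solution")
})

test_that("ETV void width is the admissible cubic root and round-trips", {
  b <- etv_void_width(0.935, 0.020, 0.2)
  expect_equal(b, 0.226, tolerance = 2e-3)
  # residual of the cubic at the returned root is ~0
  cc <- 0.935^3 - 0.8 * 0.955^3
  expect_lt(abs(2 * b^3 - 3 * 0.935 * b^2 + cc), 1e-12)
  expect_true(b > 0 && b < 0.935)
  # c = 0 (uniform dims) gives b = 0
  a0 <- uniform_cell_halfwidth(0.2, 0.02)
  expect_equal(etv_void_width(a0, 0.02, 0.2), 0)
  # round trip to 1e-8
  for (phi in c(0.1, 0.2, 0.4)) {
    for (a in uniform_cell_halfwidth(phi, 0.02) * c(1.5, 3, 10)) {
      b <- etv_void_width(a, 0.02, phi)
      expect_equal(porosity_of_dims(a, b, 0.02, "etv"), phi,
                   tolerance = 1e-8)
    }
  }
  expect_error(etv_void_width(0.1, 0.02, 0.2), "no ETV solution")
})

test_that("porosity_of_dims evaluates the explicit volume budgets", {
  expect_equal(porosity_of_dims(0.742, 0.379, 0.020, "ccv"), 0.2,
               tolerance = 2e-3)
  # printed-rounding residual: the rounded (a, b) give ~0.1995, not 0.2000
  expect_equal(porosity_of_dims(0.935, 0.226, 0.020, "etv"), 0.199,
               tolerance = 5e-3)
  expect_error(porosity_of_dims(0.5, 0.6, 0.02, "ccv"), "b")
  expect_error(porosity_of_dims(0.5, 0.1, 0.02, "uniform"), "no voids")
})

test_that("constant-bounding-cube sheet width follows p/(1+A)", {
  expect_equal(round(1e3 * constant_bounding_w(0.6206, 43.82), 2), 13.85)
  expect_equal(constant_bounding_w(0, 30), 0)
  # unchanged A and p leave w unchanged
  w <- 0.02; A <- 25; p <- (1 + A) * w
  expect_equal(constant_bounding_w(p, A), w, tolerance = 1e-12)
})

test_that("cell_dims resolves consistent geometry from either a or omega", {
  d1 <- cell_dims("ccv", 0.2, 0.020, omega = 1.608)
  expect_equal(d1$a, 0.742, tolerance = 5e-4)
  expect_equal(d1$b, 0.379, tolerance = 2e-3)
  expect_equal(d1$p, d1$a + d1$w)
  d2 <- cell_dims("ccv", 0.2, 0.020, a = d1$a)
  expect_equal(d2$omega, d1$omega, tolerance = 1e-9)
  # volume budget identities
  expect_equal(d1$V_s, d1$V_p - d1$V_a)
  expect_equal(d1$omega, d1$V_v / d1$V_s, tolerance = 1e-9)
  expect_equal(d1$phi, (d1$V_s + d1$V_v) / d1$V_p, tolerance = 1e-9)
  # uniform needs neither a nor omega
  du <- cell_dims("uniform", 0.2, 0.020)
  expect_equal(du$omega, 0)
  expect_equal(du$b, 0)
  expect_error(cell_dims("ccv", 0.2, 0.020), "exactly one")
  expect_error(cell_dims("ccv", 0.2, 0.020, a = 1, omega = 1), "exactly one")
})
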