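## Closed-form geometry calculus for sheet-and-void cubic-cell models.
##
## Lengths are in micrometres throughout; porosity and Omega are
## dimensionless. A basic cubic cell of half-width a sits inside a bounding
## cube of half-width p = a + w, where w is the sheet half-width (two
## adjacent cells are 2w apart). Voids of width b are cut into the cell:
## at the 8 corners (CCV) or along the 12 edges plus corners (ETV).

.check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                          open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop(sprintf("`%s` = %g is outside the valid range %s%g, %g%s", name, x,
                 if (open_lower) "(" else "[", lower, upper,
                 if (open_upper) ")" else "]"), call. = FALSE)
  invisible(x)
}

#' Geometrical tortuosity of a uniform cubic-cell lattice
#'
#' For an ensemble of equal cubic cells separated by uniform sheets of
#' interstitial space the geometrical tortuosity depends only on the
#' porosity: \eqn{\tau_g = \sqrt{(3-\phi)/2}}. A small empirical correction
#' term, \eqn{+\,0.07\,\phi(1-\phi)}, refines this to the value measured by
#' high-precision Monte Carlo simulation; the corrected form is the default
#' and is the zero-void anchor used everywhere else in the package.
#'
#' The maximum is \eqn{\sqrt{3/2} \approx 1.225} as \eqn{\phi \to 0}: a
#' uniformly spaced cubic lattice cannot produce the tortuosity of about
#' 1.6 measured in brain tissue, which is what motivates the void models.
#'
#' @param phi Porosity (volume fraction of interstitial space), in
#'   \eqn{[0, 1]}.
#' @param corrected Use the corrected relation (default) or the plain
#'   \eqn{\sqrt{(3-\phi)/2}} form.
#' @return Geometrical tortuosity \eqn{\tau_g} (dimensionless).
#' @examples
#' tau_uniform_lattice(0)            # sqrt(3/2) = 1.2247
#' tau_uniform_lattice(0.2)^2        # 1.427, the phi = 0.2 anchor
#' @export
tau_uniform_lattice <- function(phi, corrected = TRUE) {
  vapply(phi, .check_scalar, numeric(1), name = "phi", lower = 0, upper = 1)
  tau <- sqrt((3 - phi) / 2)
  if (corrected) tau <- tau + 0.07 * phi * (1 - phi)
  tau
}

#' Cell half-width of a uniform lattice at given porosity and sheet width
#'
#' Inverts the porosity of a zero-void cubic lattice for the cell size:
#' \eqn{a/w = \gamma/(1-\gamma)} with \eqn{\gamma = (1-\phi)^{1/3}}.
#'
#' @param phi Porosity, in the open interval (0, 1).
#' @param w Sheet half-width in micrometres (> 0).
#' @return Basic cell half-width `a` in micrometres.
#' @examples
#' uniform_cell_halfwidth(0.2, 0.020)  # 0.259 um for a 40 nm sheet
#' @export
uniform_cell_halfwidth <- function(phi, w) {
  .check_scalar(phi, "phi", 0, 1, open_lower = TRUE, open_upper = TRUE)
  .check_scalar(w, "w", 0, open_lower = TRUE)
  gamma <- (1 - phi)^(1 / 3)
  w * gamma / (1 - gamma)
}

#' Void-to-sheet volume ratio of a cell geometry
#'
#' \eqn{\Omega = V_v/V_s} is the ratio of total void volume to total sheet
#' volume in one bounding cube. Given the cell half-width `a`, sheet
#' half-width `w` and porosity `phi` it follows from volume bookkeeping
#' alone, independent of the void shape:
#' \deqn{\Omega = \frac{a^3 - (1-\phi)p^3}{p^3 - a^3}, \quad p = a + w.}
#' The linearised form \eqn{\Omega \approx (a/w)(\phi/3) - (1-\phi)},
#' valid for \eqn{a/w \gg 1}, is available with `exact = FALSE`.
#'
#' @param a Basic cell half-width, micrometres.
#' @param w Sheet half-width, micrometres.
#' @param phi Porosity.
#' @param exact Evaluate the exact expression (default) or the linear
#'   approximation.
#' @return Omega (dimensionless, >= 0).
#' @seealso [scale_factor_A()] for the inverse map Omega -> a/w.
#' @export
omega_of_geometry <- function(a, w, phi, exact = TRUE) {
  .check_scalar(a, "a", 0, open_lower = TRUE)
  .check_scalar(w, "w", 0, open_lower = TRUE)
  .check_scalar(phi, "phi", 0, 1, open_lower = TRUE, open_upper = TRUE)
  omega <- if (exact) {
    p <- a + w
    (a^3 - (1 - phi) * p^3) / (p^3 - a^3)
  } else {
    (a / w) * (phi / 3) - (1 - phi)
  }
  if (omega < 0) {
    if (omega > -1e-9) return(0)
    stop(structure(
      class = c("sheetvoid_no_void", "error", "condition"),
      list(message = sprintf(
             "geometry has no voids at this porosity (Omega = %g): a/w is at or below the uniform-lattice value",
             omega),
           call = sys.call(-1), omega = omega)))
  }
  omega
}

#' Scale factor A = a/w from porosity and void ratio
#'
#' The dimensionless cell size that realises a given \eqn{\Omega} at
#' porosity \eqn{\phi}, for any sheet half-width:
#' \deqn{A = \left\{\left[\frac{1+\Omega}{1+\Omega-\phi}\right]^{1/3} - 1\right\}^{-1},
#'       \qquad a = A\,w.}
#' At \eqn{\Omega = 0} this reduces to the uniform-lattice relation
#' \eqn{\gamma/(1-\gamma)}.
#'
#' @param omega Void-to-sheet volume ratio (>= 0).
#' @param phi Porosity, with `phi < 1 + omega` required.
#' @return The scale factor A (> 0).
#' @examples
#' scale_factor_A(1.500, 0.234)  # 30.03, sleep state
#' scale_factor_A(1.154, 0.141)  # 43.82, awake state
#' @export
scale_factor_A <- function(omega, phi) {
  .check_scalar(omega, "omega", 0)
  .check_scalar(phi, "phi", 0, open_lower = TRUE)
  if (1 + omega - phi <= 0)
    stop("`phi` must be smaller than 1 + omega", call. = FALSE)
  1 / (((1 + omega) / (1 + omega - phi))^(1 / 3) - 1)
}

#' Void-width ratio B = b/a for the corner-cubic-void model
#'
#' For the CCV model the corner void side is \eqn{b = Ba = ABw} with
#' \deqn{B = \left\{\frac{\Omega\phi}{1+\Omega-\phi}\right\}^{1/3}.}
#'
#' @inheritParams scale_factor_A
#' @return B in `[0, 1)` for physically valid solutions.
#' @export
void_ratio_B <- function(omega, phi) {
  .check_scalar(omega, "omega", 0)
  .check_scalar(phi, "phi", 0, 1, open_lower = TRUE, open_upper = TRUE)
  if (1 + omega - phi <= 0)
    stop("`phi` must be smaller than 1 + omega", call. = FALSE)
  (omega * phi / (1 + omega - phi))^(1 / 3)
}

#' Corner void width for the CCV model
#'
#' Solves the CCV volume budget for the corner-cube side:
#' \deqn{b = a\left\{1 - (1-\phi)\left[1 + w/a\right]^3\right\}^{1/3}.}
#'
#' @inheritParams omega_of_geometry
#' @return Void width `b` in micrometres (`0 <= b < a`).
#' @export
ccv_void_width <- function(a, w, phi) {
  .check_scalar(a, "a", 0, open_lower = TRUE)
  .check_scalar(w, "w", 0, open_lower = TRUE)
  .check_scalar(phi, "phi", 0, 1, open_lower = TRUE, open_upper = TRUE)
  brace <- 1 - (1 - phi) * (1 + w / a)^3
  if (brace < 0) {
    if (brace > -1e-12) brace <- 0
    else stop(sprintf(
      "no CCV solution: porosity %g cannot be reached with a = %g, w = %g (cell too small)",
      phi, a, w), call. = FALSE)
  }
  a * brace^(1 / 3)
}

#' Edge-tunnel void width for the ETV model
#'
#' The ETV void volume (12 edge tunnels of volume \eqn{2(a-b)b^2} plus 8
#' corner cubes of volume \eqn{b^3}) leads to the depressed cubic
#' \deqn{2b^3 - 3ab^2 + \left\{a^3 - (1-\phi)(a+w)^3\right\} = 0.}
#' On (0, a) the left side is strictly decreasing, so when the constant
#' term `c` satisfies `0 < c < a^3` there is exactly one physically
#' admissible root, which is returned; `c = 0` gives `b = 0` (uniform
#' lattice).
#'
#' @inheritParams omega_of_geometry
#' @return Void width `b` in micrometres, the unique root in `[0, a)`.
#' @export
etv_void_width <- function(a, w, phi) {
  .check_scalar(a, "a", 0, open_lower = TRUE)
  .check_scalar(w, "w", 0, open_lower = TRUE)
  .check_scalar(phi, "phi", 0, 1, open_lower = TRUE, open_upper = TRUE)
  cc <- a^3 - (1 - phi) * (a + w)^3
  if (cc < 0) {
    if (cc > -1e-12 * a^3) return(0)
    stop(sprintf("no ETV solution: constant term %g < 0 (geometry has no voids)", cc),
         call. = FALSE)
  }
  if (cc >= a^3)
    stop("no ETV solution: voids would consume the whole cell", call. = FALSE)
  if (cc == 0) return(0)
  f <- function(b) 2 * b^3 - 3 * a * b^2 + cc
  uniroot(f, lower = 0, upper = a, tol = .Machine$double.eps^0.75,
          f.lower = cc, f.upper = cc - a^3)$root
}

#' Porosity implied by explicit cell dimensions
#'
#' Round-trip check for the void-width solvers: evaluates the porosity of a
#' bounding cube of half-width `p = a + w` containing a basic cell of
#' half-width `a` with voids of width `b`.
#'
#' @param a Basic cell half-width, micrometres.
#' @param b Void width, micrometres (0 for a uniform lattice).
#' @param w Sheet half-width, micrometres.
#' @param model One of `"uniform"`, `"ccv"`, `"etv"`.
#' @return Porosity in (0, 1).
#' @export
porosity_of_dims <- function(a, b = 0, w, model = c("uniform", "ccv", "etv")) {
  model <- match.arg(model)
  .check_scalar(a, "a", 0, open_lower = TRUE)
  .check_scalar(b, "b", 0)
  .check_scalar(w, "w", 0, open_lower = TRUE)
  if (b >= a && b > 0) stop("`b` must satisfy 0 <= b < a", call. = FALSE)
  if (model == "uniform" && b != 0)
    stop("uniform model has no voids: `b` must be 0", call. = FALSE)
  p3 <- (a + w)^3
  solid <- switch(model,
    uniform = a^3,
    ccv     = a^3 - b^3,
    etv     = 2 * b^3 - 3 * a * b^2 + a^3)
  1 - solid / p3
}

#' Sheet half-width preserving the bounding cube across a state change
#'
#' When the tissue must keep its bounding-cube half-width `p_ref` while the
#' cell scale factor changes to `A`, the sheet half-width becomes
#' \eqn{w = p_{ref}/(1 + A)} (since \eqn{p = a + w = (1+A)w}).
#'
#' @param p_ref Reference bounding-cube half-width, micrometres (>= 0).
#' @param A Scale factor a/w in the new state (> 0).
#' @return Sheet half-width `w` in micrometres.
#' @examples
#' constant_bounding_w(0.6206, 43.82) * 1e3  # 13.85 nm
#' @export
constant_bounding_w <- function(p_ref, A) {
  .check_scalar(p_ref, "p_ref", 0)
  .check_scalar(A, "A", 0, open_lower = TRUE)
  p_ref / (1 + A)
}

#' Fully resolved cell dimensions for a sheet-and-void model
#'
#' Resolves a model specification (kind, porosity, sheet half-width, and
#' exactly one of the cell half-width `a` or the void ratio `omega`) into
#' the complete length quartet and volume budget of one bounding cube.
#' For the uniform model neither `a` nor `omega` is needed (`a` follows
#' from the porosity; `omega` is identically 0).
#'
#' @param model `"uniform"`, `"ccv"` or `"etv"`.
#' @param phi Porosity in (0, 1).
#' @param w Sheet half-width, micrometres.
#' @param a Basic cell half-width, micrometres (alternative to `omega`).
#' @param omega Void-to-sheet volume ratio (alternative to `a`).
#' @return An object of class `cell_dims`: a list with `model`, `phi`,
#'   `w`, `a`, `b`, `p`, `omega`, the scale factors `A` (and `B` for CCV),
#'   and the volume budget `V_a`, `V_p`, `V_s`, `V_v` in cubic
#'   micrometres.
#' @examples
#' cell_dims("ccv", phi = 0.2, w = 0.020, omega = 1.608)  # tau_g = 1.6 cell
#' @export
cell_dims <- function(model = c("uniform", "ccv", "etv"), phi, w,
                      a = NULL, omega = NULL) {
  model <- match.arg(model)
  .check_scalar(phi, "phi", 0, 1, open_lower = TRUE, open_upper = TRUE)
  .check_scalar(w, "w", 0, open_lower = TRUE)
  if (model == "uniform") {
    if (!is.null(omega) && omega != 0)
      stop("uniform model has omega = 0 by construction", call. = FALSE)
    if (is.null(a)) a <- uniform_cell_halfwidth(phi, w)
    omega <- 0
  } else {
    if (is.null(a) == is.null(omega))
      stop("supply exactly one of `a` or `omega`", call. = FALSE)
    if (is.null(a)) a <- scale_factor_A(omega, phi) * w
  }
  omega <- omega_of_geometry(a, w, phi, exact = TRUE)
  b <- switch(model,
    uniform = 0,
    ccv     = ccv_void_width(a, w, phi),
    etv     = etv_void_width(a, w, phi))
  p <- a + w
  V_a <- 8 * a^3
  V_p <- 8 * p^3
  V_s <- V_p - V_a
  V_v <- max(0, V_a - (1 - phi) * V_p)
  out <- list(model = model, phi = phi, w = w, a = a, b = b, p = p,
              omega = omega, A = a / w,
              B = if (model == "ccv") b / a else NA_real_,
              V_a = V_a, V_p = V_p, V_s = V_s, V_v = V_v)
  ## consistency: porosity must round-trip through the explicit void shape
  phi_back <- porosity_of_dims(a, b, w, model)
  if (abs(phi_back - phi) > 1e-6)
    stop(sprintf("inconsistent dimensions: porosity_of_dims gives %g, expected %g",
                 phi_back, phi), call. = FALSE)
  class(out) <- "cell_dims"
  out
}

#' @export
print.cell_dims <- function(x, ...) {
  cat(sprintf("<cell_dims> %s model, phi = %.4g\n", toupper(x$model), x$phi))
  cat(sprintf("  a = %.4g um, b = %.4g um, w = %.4g um, p = %.4g um\n",
              x$a, x$b, x$w, x$p))
  cat(sprintf("  Omega = %.4g  (A = a/w = %.4g%s)\n", x$omega, x$A,
              if (!is.na(x$B)) sprintf(", B = b/a = %.4g", x$B) else ""))
  cat(sprintf("  volumes [um^3]: V_a = %.4g, V_p = %.4g, V_s = %.4g, V_v = %.4g\n",
              x$V_a, x$V_p, x$V_s, x$V_v))
  invisible(x)
}
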