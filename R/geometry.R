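## Periodic 3-D ensembles of solid cells with an interstitial complement.
##
## One cell is stored in its local frame (origin at the cell centre); all
## spatial queries fold coordinates by the lattice period 2p, so memory is
## O(1) in ensemble size. The ensemble is centred on a lattice VERTEX
## (where the corners of 8 cells meet), because molecules are released in
## the vertex cavity; cell centres sit at odd multiples of p.

## Disjoint axis-aligned box decomposition of the solid (basic cube minus
## voids), rows (xlo, ylo, zlo, xhi, yhi, zhi) in the local cell frame.
.solid_boxes <- function(a, b, model) {
  box <- function(xlo, xhi, ylo, yhi, zlo, zhi)
    c(xlo, ylo, zlo, xhi, yhi, zhi)
  if (model == "uniform" || b == 0) {
    m <- rbind(box(-a, a, -a, a, -a, a))
  } else if (model == "ccv") {
    c0 <- a - b
    m <- rbind(
      box(-a, a, -a, a, -c0, c0),                 # middle slab, full square
      ## two corner-notched slabs, 3 boxes each (a cross)
      box(-c0, c0, -a, a,  c0, a),
      box( c0, a, -c0, c0, c0, a),
      box(-a, -c0, -c0, c0, c0, a),
      box(-c0, c0, -a, a, -a, -c0),
      box( c0, a, -c0, c0, -a, -c0),
      box(-a, -c0, -c0, c0, -a, -c0))
  } else { # etv: central core + 6 face slabs
    c0 <- a - b
    m <- rbind(
      box(-c0, c0, -c0, c0, -c0, c0),
      box( c0, a, -c0, c0, -c0, c0),
      box(-a, -c0, -c0, c0, -c0, c0),
      box(-c0, c0,  c0, a, -c0, c0),
      box(-c0, c0, -a, -c0, -c0, c0),
      box(-c0, c0, -c0, c0,  c0, a),
      box(-c0, c0, -c0, c0, -a, -c0))
  }
  colnames(m) <- c("xlo", "ylo", "zlo", "xhi", "yhi", "zhi")
  m
}

## Void cut-out boxes in the local cell frame.
.cut_boxes <- function(a, b, model) {
  if (model == "uniform" || b == 0) {
    m <- matrix(numeric(0), 0, 6)
  } else {
    c0 <- a - b
    signs <- as.matrix(expand.grid(sx = c(-1, 1), sy = c(-1, 1), sz = c(-1, 1)))
    corners <- t(apply(signs, 1, function(s) {
      lo <- pmin(s * c0, s * a); hi <- pmax(s * c0, s * a)
      c(lo[1], lo[2], lo[3], hi[1], hi[2], hi[3])
    }))
    if (model == "ccv") {
      m <- corners
    } else {
      prisms <- NULL
      for (axis in 1:3) {
        others <- setdiff(1:3, axis)
        for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) {
          lo <- hi <- numeric(3)
          lo[axis] <- -c0; hi[axis] <- c0
          lo[others[1]] <- min(s1 * c0, s1 * a); hi[others[1]] <- max(s1 * c0, s1 * a)
          lo[others[2]] <- min(s2 * c0, s2 * a); hi[others[2]] <- max(s2 * c0, s2 * a)
          prisms <- rbind(prisms, c(lo, hi))
        }
      }
      m <- rbind(corners, prisms)
    }
  }
  colnames(m) <- c("xlo", "ylo", "zlo", "xhi", "yhi", "zhi")
  m
}

#' Build the solid geometry of one sheet-and-void cell
#'
#' Turns resolved [cell_dims()] into an explicit constructive-solid
#' geometry: the void cut boxes (8 corner cubes for CCV; those plus 12
#' edge prisms for ETV) and a disjoint axis-aligned box decomposition of
#' the remaining solid, both in the local frame of the cell centre. The
#' box decomposition is what the point classifier, the random-walk
#' reflector and the mesh exporter all consume.
#'
#' @param dims A `cell_dims` object.
#' @return An object of class `cell_geometry`: `dims`, `cut_boxes`
#'   (k x 6 matrix), `solid_boxes` (k x 6 matrix) and `solid_volume`
#'   (\eqn{8a^3 - V_v}, cubic micrometres).
#' @export
build_cell <- function(dims) {
  stopifnot(inherits(dims, "cell_dims"))
  solid <- .solid_boxes(dims$a, dims$b, dims$model)
  cuts <- .cut_boxes(dims$a, dims$b, dims$model)
  vol <- sum(apply(solid, 1, function(r) prod(r[4:6] - r[1:3])))
  expected <- 8 * dims$a^3 - dims$V_v
  if (abs(vol - expected) > 1e-9 * max(expected, 1))
    stop(sprintf("solid decomposition volume %g disagrees with budget %g", vol, expected),
         call. = FALSE)
  structure(list(dims = dims, cut_boxes = cuts, solid_boxes = solid,
                 solid_volume = vol),
            class = "cell_geometry")
}

#' Build a periodic ensemble of cells around a central release vertex
#'
#' Tiles `n` x `n` x `n` bounding cubes of period \eqn{2p = 2(a+w)} so
#' that the ensemble centre (the origin) is a lattice vertex where the
#' corners of 8 cells meet -- the cavity from which molecules are
#' released. `n` must be even so that this vertex exists.
#'
#' @param cell A `cell_geometry` from [build_cell()], or a `cell_dims`
#'   object (built on the fly).
#' @param n Number of cells per axis (even).
#' @return An object of class `ensemble`: the cell, the lattice period,
#'   cell count, outer bounds (half-width `n * p`) and the release origin
#'   `c(0, 0, 0)`.
#' @export
build_ensemble <- function(cell, n = 32L) {
  if (inherits(cell, "cell_dims")) cell <- build_cell(cell)
  stopifnot(inherits(cell, "cell_geometry"))
  n <- as.integer(n)
  if (n < 2L || n %% 2L != 0L)
    stop("`n` must be an even integer >= 2 (the release point must be a lattice vertex)",
         call. = FALSE)
  p <- cell$dims$p
  structure(list(cell = cell, period = 2 * p, n = n,
                 bounds = n * p, release_origin = c(0, 0, 0)),
            class = "ensemble")
}

#' An unbounded free medium (no solid cells)
#'
#' Used for free-diffusion oracle runs: the walker sees no walls and
#' molecules never reflect.
#'
#' @param bounds Half-width of the containment check box, micrometres.
#' @return An `ensemble` object with no solid.
#' @export
free_space <- function(bounds = 1e6) {
  structure(list(cell = NULL, period = 2, n = NA_integer_,
                 bounds = bounds, release_origin = c(0, 0, 0)),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  if (is.null(x$cell)) {
    cat(sprintf("<ensemble> free medium, bounds +/- %g um\n", x$bounds))
  } else {
    d <- x$cell$dims
    cat(sprintf("<ensemble> %d^3 %s cells, period %.4g um, bounds +/- %.4g um\n",
                x$n, toupper(d$model), x$period, x$bounds))
    cat(sprintf("  phi = %.4g, a = %.4g, b = %.4g, w = %.4g um; release at lattice vertex\n",
                d$phi, d$a, d$b, d$w))
  }
  invisible(x)
}

#' Classify points of an ensemble as solid, void, sheet or outside
#'
#' Coordinates are folded by the lattice period into the local frame of
#' the nearest cell; a point is `solid` if it lies in the basic cube and
#' not in a void cut box, `void` if inside a cut box, `sheet` if in the
#' interstitial gap between cells, and `outside` beyond the ensemble
#' bounds.
#'
#' @param ens An `ensemble`.
#' @param xyz Numeric matrix (m x 3) of coordinates in micrometres, or a
#'   length-3 vector.
#' @return Character vector of `"solid"`, `"void"`, `"sheet"`,
#'   `"outside"`.
#' @export
classify_points <- function(ens, xyz) {
  stopifnot(inherits(ens, "ensemble"))
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  stopifnot(ncol(xyz) == 3)
  out <- rep("sheet", nrow(xyz))
  outside <- apply(abs(xyz) > ens$bounds, 1, any)
  out[outside] <- "outside"
  if (is.null(ens$cell)) return(out)
  d <- ens$cell$dims
  p <- d$p; a <- d$a; b <- d$b
  ## fold into the local frame of the nearest cell centre (odd multiples of p)
  u <- abs(xyz - (2 * floor(xyz / (2 * p)) + 1) * p)
  inside_cube <- rowSums(u <= a) == 3L
  n_band <- rowSums(u > a - b)   # coords in the corner band [a-b, a]
  in_void <- inside_cube & switch(d$model,
    uniform = FALSE,
    ccv     = n_band == 3L,
    etv     = n_band >= 2L)
  out[!outside & inside_cube] <- "solid"
  out[!outside & in_void] <- "void"
  out
}

#' Monte Carlo estimate of the porosity of a constructed ensemble
#'
#' Samples points uniformly in one period cube and reports the fraction
#' classified as interstitial (void or sheet), with a 95% binomial
#' confidence interval. By periodicity this estimates the porosity of the
#' whole ensemble and validates the analytic volume budget of the
#' constructed geometry.
#'
#' @param ens An `ensemble` built from a `cell_geometry`.
#' @param n_samples Number of sample points (>= 1e5 recommended).
#' @param seed Optional integer seed for reproducibility.
#' @return List with `phi_hat`, `se`, `ci` (95%), `n_samples`.
#' @export
estimate_porosity_mc <- function(ens, n_samples = 2e5, seed = NULL) {
  stopifnot(inherits(ens, "ensemble"), !is.null(ens$cell))
  if (!is.null(seed)) set.seed(seed)
  p <- ens$cell$dims$p
  xyz <- matrix(runif(3 * n_samples, -p, p), ncol = 3)
  cls <- classify_points(ens, xyz)
  k <- sum(cls %in% c("void", "sheet"))
  phi_hat <- k / n_samples
  se <- sqrt(phi_hat * (1 - phi_hat) / n_samples)
  list(phi_hat = phi_hat, se = se,
       ci = phi_hat + c(-1, 1) * 1.96 * se, n_samples = n_samples)
}

## Emit the 12 triangles of one axis-aligned box with outward winding.
.box_triangles <- function(lo, hi) {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  ## vertex index = 1 + (x_hi) + 2*(y_hi) + 4*(z_hi)
  faces <- rbind(  # CCW seen from outside
    c(1, 3, 2), c(2, 3, 4),   # z = lo (normal -z)
    c(5, 6, 7), c(6, 8, 7),   # z = hi (+z)
    c(1, 2, 5), c(2, 6, 5),   # y = lo (-y)
    c(3, 7, 4), c(4, 7, 8),   # y = hi (+y)
    c(1, 5, 3), c(3, 5, 7),   # x = lo (-x)
    c(2, 4, 6), c(4, 8, 6))   # x = hi (+x)
  list(vertices = v, faces = faces)
}

#' Export a cell or ensemble solid as an ASCII OBJ triangle mesh
#'
#' Each box of the disjoint solid decomposition is written as a closed
#' 12-triangle cuboid with outward-facing winding, so the signed
#' (divergence-theorem) volume of the mesh equals the analytic solid
#' volume exactly; for an ensemble, translated copies of every cell are
#' concatenated. Coordinates are micrometres.
#'
#' @param x A `cell_geometry` or `ensemble`.
#' @param path Output file path (`.obj`).
#' @return Invisibly, the path.
#' @seealso [mesh_volume()] to check the enclosed volume of a written
#'   mesh.
#' @export
export_mesh <- function(x, path) {
  if (inherits(x, "ensemble")) {
    if (is.null(x$cell)) stop("free space has no mesh", call. = FALSE)
    cellgeo <- x$cell
    k <- x$n / 2
    centres <- as.matrix(expand.grid(
      x = (2 * seq(-k, k - 1) + 1) * cellgeo$dims$p,
      y = (2 * seq(-k, k - 1) + 1) * cellgeo$dims$p,
      z = (2 * seq(-k, k - 1) + 1) * cellgeo$dims$p))
  } else if (inherits(x, "cell_geometry")) {
    cellgeo <- x
    centres <- matrix(0, 1, 3)
  } else stop("`x` must be a cell_geometry or ensemble", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# sheetvoid solid mesh (units: um)", con)
  offset <- 0L
  for (ci in seq_len(nrow(centres))) {
    for (bi in seq_len(nrow(cellgeo$solid_boxes))) {
      r <- cellgeo$solid_boxes[bi, ]
      tri <- .box_triangles(r[1:3] + centres[ci, ], r[4:6] + centres[ci, ])
      writeLines(sprintf("v %.17g %.17g %.17g",
                         tri$vertices[, 1], tri$vertices[, 2], tri$vertices[, 3]), con)
      writeLines(sprintf("f %d %d %d",
                         tri$faces[, 1] + offset, tri$faces[, 2] + offset,
                         tri$faces[, 3] + offset), con)
      offset <- offset + 8L
    }
  }
  invisible(path)
}

#' Signed enclosed volume of an OBJ triangle mesh
#'
#' Sums signed tetrahedron volumes over the triangles (divergence
#' theorem); for a consistently outward-wound closed mesh this is the
#' enclosed volume.
#'
#' @param path Path to an ASCII OBJ file with `v` and triangular `f`
#'   records.
#' @return Volume in cubic micrometres.
#' @export
mesh_volume <- function(path) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  v <- matrix(as.numeric(unlist(strsplit(sub("^v ", "", vl), " "))),
              ncol = 3, byrow = TRUE)
  f <- matrix(as.integer(unlist(strsplit(sub("^f ", "", fl), " "))),
              ncol = 3, byrow = TRUE)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  cross <- cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
                 b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
                 b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  sum(rowSums(a * cross)) / 6
}

#' Geometry summary of an ensemble as a plain list
#'
#' @param ens An `ensemble`.
#' @return List suitable for JSON serialisation: model, phi, lengths in
#'   micrometres, cell count and solid volume.
#' @export
geometry_summary <- function(ens) {
  stopifnot(inherits(ens, "ensemble"))
  if (is.null(ens$cell))
    return(list(model = "free", bounds_um = ens$bounds))
  d <- ens$cell$dims
  list(model = d$model, phi = d$phi, w_um = d$w, a_um = d$a, b_um = d$b,
       p_um = d$p, omega = d$omega, n_cells = ens$n^3,
       solid_volume_um3 = ens$cell$solid_volume)
}
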