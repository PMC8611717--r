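#' Construct a volumetric grid
#'
#' A `volumetric_grid` is a scalar field sampled on a regular voxel lattice,
#' with the geometry conventions of Gaussian cube files: an origin, three
#' voxel step vectors and per-node values. Geometry is in bohr at this layer;
#' conversion to angstrom happens where surfaces are built. Electron-density
#' grids carry values in e bohr^-3, electrostatic-potential grids in
#' hartree e^-1.
#'
#' @param origin numeric length-3, lattice origin in bohr.
#' @param axes 3x3 numeric matrix; row `i` is the step vector (bohr) along
#'   grid direction `i`. Must be non-singular.
#' @param values 3-d numeric array, `values[ix, iy, iz]` the field at node
#'   `origin + (ix-1) axes[1,] + (iy-1) axes[2,] + (iz-1) axes[3,]`.
#' @param atoms data frame with columns `number` (atomic number), `charge`
#'   (nuclear charge) and `x`, `y`, `z` (bohr), or `NULL` for none.
#' @param nonnegative if `TRUE`, reject negative values (density grids).
#'
#' @return an object of class `volumetric_grid`.
#' @export
volumetric_grid <- function(origin, axes, values, atoms = NULL,
                            nonnegative = FALSE) {
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L, all(is.finite(origin)))
  axes <- matrix(as.numeric(axes), 3L, 3L)
  if (abs(det(axes)) < 1e-12) {
    stop("grid axis vectors are linearly dependent", call. = FALSE)
  }
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3-d array", call. = FALSE)
  }
  if (any(dim(values) < 2L)) {
    stop("each grid dimension needs at least 2 nodes", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("grid values must be finite", call. = FALSE)
  }
  if (nonnegative && any(values < 0)) {
    stop("density grid contains negative values", call. = FALSE)
  }
  if (is.null(atoms)) {
    atoms <- data.frame(number = integer(), charge = numeric(),
                        x = numeric(), y = numeric(), z = numeric())
  }
  structure(
    list(origin = origin, axes = axes, counts = dim(values),
         values = values, atoms = atoms),
    class = "volumetric_grid"
  )
}

#' @export
print.volumetric_grid <- function(x, ...) {
  cat("<volumetric_grid> ", paste(x$counts, collapse = " x "),
      " nodes, ", nrow(x$atoms), " atoms\n", sep = "")
  cat("  origin (bohr): ", paste(signif(x$origin, 6), collapse = ", "), "\n",
      sep = "")
  cat("  value range:   [", signif(min(x$values), 6), ", ",
      signif(max(x$values), 6), "]\n", sep = "")
  invisible(x)
}

# Cartesian (bohr) -> fractional 0-based grid coordinates.
grid_fractional <- function(grid, points_bohr) {
  shifted <- sweep(points_bohr, 2L, grid$origin)
  # rows of `axes` are step vectors: r = origin + frac %*% axes
  t(solve(t(grid$axes), t(shifted)))
}

grid_cartesian <- function(grid, frac) {
  sweep(frac %*% grid$axes, 2L, grid$origin, `+`)
}
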