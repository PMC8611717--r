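#' Extract an electron-density isosurface
#'
#' Triangulates the level set of a density grid by marching tetrahedra with
#' linear interpolation along cell edges (each voxel split into six
#' tetrahedra, shared edge vertices merged so the mesh is connected). The
#' default level, 0.002 e bohr^-3, is the conventional definition of the
#' molecular van der Waals surface for this coarse-graining.
#'
#' @param density a [volumetric_grid()] of electron density (e bohr^-3,
#'   geometry in bohr).
#' @param level isosurface level in e bohr^-3; must lie strictly between the
#'   grid minimum and maximum.
#' @return a list of class `iso_surface` with `vertices` (n x 3 matrix,
#'   angstrom) and `triangles` (m x 3 integer matrix, 1-based vertex rows).
#' @export
extract_isosurface <- function(density, level = 0.002) {
  stopifnot(inherits(density, "volumetric_grid"))
  rng <- range(density$values)
  if (level <= rng[1] || level >= rng[2]) {
    stop("isosurface level ", level, " is outside the grid value range [",
         signif(rng[1], 6), ", ", signif(rng[2], 6), "]", call. = FALSE)
  }
  mesh <- .marching_tetrahedra(as.numeric(density$values), density$counts,
                               level)
  if (nrow(mesh$vertices) == 0L) {
    stop("isosurface at level ", level, " is empty", call. = FALSE)
  }
  verts_bohr <- grid_cartesian(density, mesh$vertices)
  structure(list(vertices = verts_bohr * BOHR_TO_ANGSTROM,
                 triangles = mesh$triangles,
                 iso_level = level),
            class = "iso_surface")
}

#' Per-vertex surface areas of a triangulated surface
#'
#' Each triangle's area is split equally among its three vertices, so the
#' per-vertex areas sum exactly to the total mesh area. Degenerate
#' (zero-area) triangles contribute nothing; their count is attached as the
#' `n_degenerate` attribute.
#'
#' @param surface an `iso_surface` (or any list with `vertices` and
#'   `triangles` in the same layout).
#' @return numeric vector of per-vertex areas (angstrom^2), with attribute
#'   `n_degenerate`.
#' @export
vertex_areas <- function(surface) {
  v <- surface$vertices
  tr <- surface$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c_ <- v[tr[, 3], , drop = FALSE]
  ab <- b - a
  ac <- c_ - a
  cx <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  tri_area <- 0.5 * sqrt(rowSums(cx^2))
  n_degenerate <- sum(tri_area == 0)
  share <- tri_area / 3
  areas <- numeric(nrow(v))
  for (col in 1:3) {
    acc <- tapply(share, tr[, col], sum)
    idx <- as.integer(names(acc))
    areas[idx] <- areas[idx] + as.numeric(acc)
  }
  attr(areas, "n_degenerate") <- n_degenerate
  areas
}

#' Sample an electrostatic potential grid at arbitrary points
#'
#' Trilinear interpolation of a potential grid (hartree e^-1, bohr geometry)
#' at cartesian points given in angstrom, returning kJ mol^-1. Non-axis-
#' aligned voxel axes are handled by transforming points into fractional
#' grid coordinates first.
#'
#' @param esp a [volumetric_grid()] of electrostatic potential.
#' @param points n x 3 matrix of positions in angstrom.
#' @return numeric vector of potentials in kJ mol^-1.
#' @export
sample_potential <- function(esp, points) {
  stopifnot(inherits(esp, "volumetric_grid"))
  points <- matrix(as.numeric(points), ncol = 3L)
  frac <- grid_fractional(esp, points / BOHR_TO_ANGSTROM)
  hi <- esp$counts - 1L
  eps <- 1e-9
  outside <- frac[, 1] < -eps | frac[, 1] > hi[1] + eps |
             frac[, 2] < -eps | frac[, 2] > hi[2] + eps |
             frac[, 3] < -eps | frac[, 3] > hi[3] + eps
  if (any(outside)) {
    stop("point(s) outside the potential grid: index ",
         paste(utils::head(which(outside), 5L), collapse = ", "),
         if (sum(outside) > 5L) ", ...", call. = FALSE)
  }
  frac <- pmin(pmax(frac, 0), matrix(hi, nrow(frac), 3L, byrow = TRUE))
  i0 <- pmin(floor(frac[, 1]), hi[1] - 1L); tx <- frac[, 1] - i0
  j0 <- pmin(floor(frac[, 2]), hi[2] - 1L); ty <- frac[, 2] - j0
  k0 <- pmin(floor(frac[, 3]), hi[3] - 1L); tz <- frac[, 3] - k0
  val <- function(di, dj, dk) {
    esp$values[cbind(i0 + di + 1L, j0 + dj + 1L, k0 + dk + 1L)]
  }
  hartree <-
    val(0, 0, 0) * (1 - tx) * (1 - ty) * (1 - tz) +
    val(1, 0, 0) * tx * (1 - ty) * (1 - tz) +
    val(0, 1, 0) * (1 - tx) * ty * (1 - tz) +
    val(0, 0, 1) * (1 - tx) * (1 - ty) * tz +
    val(1, 1, 0) * tx * ty * (1 - tz) +
    val(1, 0, 1) * tx * (1 - ty) * tz +
    val(0, 1, 1) * (1 - tx) * ty * tz +
    val(1, 1, 1) * tx * ty * tz
  hartree * HARTREE_TO_KJ_MOL
}

#' Construct a surface sample
#'
#' The footprinting substrate: surface points with per-point areas and the
#' molecular electrostatic potential (MEPS) sampled there.
#'
#' @param points n x 3 matrix, angstrom.
#' @param areas per-point areas, angstrom^2, all positive.
#' @param meps per-point potential, kJ mol^-1.
#' @param iso_level the density level the points sit on, e bohr^-3.
#' @return an object of class `surface_sample`.
#' @export
surface_sample <- function(points, areas, meps, iso_level = 0.002) {
  points <- matrix(as.numeric(points), ncol = 3L)
  areas <- as.numeric(areas)
  meps <- as.numeric(meps)
  stopifnot(nrow(points) == length(areas), length(areas) == length(meps))
  if (length(areas) == 0L) stop("surface sample is empty", call. = FALSE)
  if (any(areas <= 0)) stop("per-point areas must be positive", call. = FALSE)
  structure(list(points = points, areas = areas, meps = meps,
                 total_area = sum(areas), iso_level = iso_level),
            class = "surface_sample")
}

#' @export
print.surface_sample <- function(x, ...) {
  cat("<surface_sample> ", nrow(x$points), " points, total area ",
      signif(x$total_area, 5), " angstrom^2\n", sep = "")
  cat("  MEPS range (kJ/mol): [", signif(min(x$meps), 4), ", ",
      signif(max(x$meps), 4), "]\n", sep = "")
  invisible(x)
}

#' Build a surface sample from density and potential grids
#'
#' Composition of [extract_isosurface()], [vertex_areas()] and
#' [sample_potential()]: the per-vertex mesh of the density isosurface,
#' with the potential interpolated at each vertex. Vertices that receive
#' zero area (from degenerate triangles only) are dropped.
#'
#' @inheritParams extract_isosurface
#' @param esp electrostatic potential grid covering the same region.
#' @return a [surface_sample()].
#' @export
build_surface_sample <- function(density, esp, level = 0.002) {
  surf <- extract_isosurface(density, level)
  areas <- vertex_areas(surf)
  keep <- areas > 0
  surface_sample(surf$vertices[keep, , drop = FALSE], areas[keep],
                 sample_potential(esp, surf$vertices[keep, , drop = FALSE]),
                 iso_level = level)
}

#' Connected components of a triangulated surface
#'
#' Union-find over shared triangle vertices; used to verify that well-
#' separated density blobs yield separate shells.
#'
#' @param surface an `iso_surface`.
#' @return integer vector of component labels (1-based), one per vertex.
#' @export
surface_components <- function(surface) {
  n <- nrow(surface$vertices)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  tr <- surface$triangles
  for (r in seq_len(nrow(tr))) {
    a <- find(tr[r, 1]); b <- find(tr[r, 2]); c_ <- find(tr[r, 3])
    parent[b] <- a
    parent[find(c_)] <- find(a)
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}
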