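#' Analytic Gaussian density and point-charge potential cubes
#'
#' Builds a matched pair of volumetric grids from closed-form fields, so
#' every downstream quantity has an analytic oracle: the density is a sum of
#' isotropic Gaussians `sum_c A_c exp(-|r - c|^2 / sigma_c^2)` (e bohr^-3)
#' and the potential a sum of softened point-charge terms
#' `sum_c q_c / max(|r - c|, 0.1)` (hartree e^-1). The 0.1 bohr softening
#' radius only guards nodes that coincide with a charge; points inside it
#' are not meaningful for surface work. A single unit Gaussian has its
#' 0.002 e bohr^-3 level set at radius `sqrt(log(1/0.002))`, about 2.4929
#' bohr.
#'
#' @param centers n x 3 matrix of centers, bohr.
#' @param amplitudes density amplitudes (recycled).
#' @param sigmas Gaussian widths, bohr (recycled).
#' @param charges point charges, e (recycled).
#' @param origin grid origin, bohr; default 4 bohr beyond the centers.
#' @param extent grid edge lengths, bohr; default to cover centers + 4 bohr.
#' @param counts nodes per axis (length 1 or 3), default 48.
#' @return list with `density` and `esp` [volumetric_grid()]s.
#' @export
make_gaussian_cubes <- function(centers, amplitudes = 1, sigmas = 1,
                                charges = 0, origin = NULL, extent = NULL,
                                counts = 48L) {
  centers <- matrix(as.numeric(centers), ncol = 3L)
  n <- nrow(centers)
  if (n < 1L) stop("need at least one center", call. = FALSE)
  amplitudes <- rep_len(amplitudes, n)
  sigmas <- rep_len(sigmas, n)
  charges <- rep_len(charges, n)
  counts <- rep_len(as.integer(counts), 3L)
  if (is.null(origin)) origin <- apply(centers, 2L, min) - 4
  if (is.null(extent)) {
    extent <- (apply(centers, 2L, max) + 4) - origin
  }
  extent <- rep_len(as.numeric(extent), 3L)
  if (any(extent <= 0)) stop("grid extent must be positive", call. = FALSE)
  step <- extent / (counts - 1L)
  xs <- origin[1] + (seq_len(counts[1]) - 1L) * step[1]
  ys <- origin[2] + (seq_len(counts[2]) - 1L) * step[2]
  zs <- origin[3] + (seq_len(counts[3]) - 1L) * step[3]

  density <- array(0, dim = counts)
  esp <- array(0, dim = counts)
  for (c_i in seq_len(n)) {
    dx2 <- (xs - centers[c_i, 1])^2
    dy2 <- (ys - centers[c_i, 2])^2
    dz2 <- (zs - centers[c_i, 3])^2
    r2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    density <- density + amplitudes[c_i] * exp(-r2 / sigmas[c_i]^2)
    if (charges[c_i] != 0) {
      esp <- esp + charges[c_i] / pmax(sqrt(r2), 0.1)
    }
  }
  axes <- diag(step, 3L, 3L)
  list(density = volumetric_grid(origin, axes, density, nonnegative = FALSE),
       esp = volumetric_grid(origin, axes, esp))
}

# Deterministic quasi-uniform points on a unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Water-like surface fixture
#'
#' A spherical point cloud with the surface pattern of a small tetrahedral
#' hydrogen-bonding molecule: two strong positive potential lobes (the O-H
#' donors) and two strong negative lobes (the lone pairs), on a surface
#' whose default area (37.4 angstrom^2) coarse-grains to exactly four
#' sites at the default 9.35 angstrom^2 footprint. Lobe potentials default
#' to +280 and -230 kJ mol^-1, realistic extrema for the water van der
#' Waals surface, so the default linear calibration yields epsilon values
#' of the magnitude of water's experimental hydrogen-bond parameters.
#'
#' @param total_area sphere area, angstrom^2.
#' @param n_points number of surface points.
#' @param lobe_meps length-4 vector: potentials of the two donor and two
#'   acceptor lobes, kJ mol^-1 (first two positive, last two negative).
#' @param lobe_width angular width of each lobe, radians.
#' @return a [surface_sample()].
#' @export
make_water_like_sample <- function(total_area = 37.4, n_points = 1000L,
                                   lobe_meps = c(280, 280, -230, -230),
                                   lobe_width = 0.7) {
  stopifnot(total_area > 0, n_points >= 8L, length(lobe_meps) == 4L)
  radius <- sqrt(total_area / (4 * pi))
  pts <- fibonacci_sphere(n_points) # unit vectors
  axes <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
    sqrt(3)
  meps <- numeric(n_points)
  for (l in 1:4) {
    ang <- acos(pmin(pmax(pts %*% axes[l, ], -1), 1))
    meps <- meps + lobe_meps[l] * exp(-(ang / lobe_width)^2)
  }
  surface_sample(pts * radius, rep(total_area / n_points, n_points), meps)
}

#' Random SSIP set
#'
#' Reproducible fixture: `n` sites on a unit sphere with epsilon drawn
#' uniformly over `eps_range`. The caller's random-number state is left
#' untouched.
#'
#' @param n number of sites (0 allowed).
#' @param eps_range length-2 range for epsilon.
#' @param seed integer seed.
#' @return a [ssip_set()]; each site carries the default 9.35 angstrom^2
#'   footprint.
#' @export
make_random_ssip_set <- function(n, eps_range = c(-5, 5), seed = 1L) {
  stopifnot(n >= 0L, length(eps_range) == 2L)
  if (n == 0L) {
    return(ssip_set(data.frame(x = numeric(), y = numeric(), z = numeric(),
                               epsilon = numeric()),
                    title = "random", total_surface_area = 0))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  dir <- matrix(stats::rnorm(3 * n), ncol = 3L)
  dir <- dir / sqrt(rowSums(dir^2))
  ssip_set(data.frame(x = dir[, 1], y = dir[, 2], z = dir[, 3],
                      epsilon = runif(n, eps_range[1], eps_range[2]),
                      area = 9.35, meps = NA_real_),
           title = "random", total_surface_area = n * 9.35)
}

#' Write the canonical two-phase example file
#'
#' Emits the standard worked example of the phase dialect: a pure-water
#' phase at 298 K, then a water/ethanol 0.75/0.25 mixture at 298 K.
#'
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_example_phase_tsv <- function(path) {
  writeLines(c("298\twater\t1.0",
               "298\twater\t0.75\tethanol\t0.25"),
             path, useBytes = TRUE)
  invisible(path)
}
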