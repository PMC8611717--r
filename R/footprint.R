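#' Calibration curve mapping surface potential to epsilon
#'
#' Footprinting assigns each site an interaction parameter epsilon from the
#' extremal surface potential of its patch. The mapping is a pair of
#' polynomial branches, one for positive potentials (donor side) and one for
#' negative (acceptor side); both map 0 to 0 and are odd-extended, i.e.
#' `epsilon(V) = sign(V) * sum(coef_k * |V|^k)`. The default is linear with
#' coefficient 0.01 (kJ mol^-1)^(1/2) per (kJ mol^-1) on both branches,
#' which places the extremes of a small polar molecule's 0.002 e bohr^-3
#' surface potential (a few hundred kJ mol^-1) in the experimentally
#' familiar range of hydrogen-bond parameters (alpha, beta of a few units).
#' Quadratic or higher fits can be supplied as longer coefficient vectors.
#'
#' @param positive coefficients (powers 1, 2, ...) for V > 0.
#' @param negative coefficients for V < 0, applied to |V|.
#' @return an object of class `calibration_curve`.
#' @export
calibration_curve <- function(positive = 0.01, negative = 0.01) {
  positive <- as.numeric(positive)
  negative <- as.numeric(negative)
  stopifnot(length(positive) >= 1L, length(negative) >= 1L,
            all(is.finite(positive)), all(is.finite(negative)))
  structure(list(positive = positive, negative = negative),
            class = "calibration_curve")
}

#' Convert surface potentials to interaction parameters
#'
#' @param meps surface potential(s), kJ mol^-1.
#' @param curve a [calibration_curve()].
#' @return epsilon value(s), (kJ mol^-1)^(1/2), with the sign of `meps`.
#' @export
calibrate_epsilon <- function(meps, curve = calibration_curve()) {
  stopifnot(inherits(curve, "calibration_curve"), all(is.finite(meps)))
  polyval <- function(coefs, v) {
    out <- 0
    for (k in seq_along(coefs)) out <- out + coefs[k] * v^k
    out
  }
  out <- numeric(length(meps))
  pos <- meps > 0
  neg <- meps < 0
  out[pos] <- polyval(curve$positive, meps[pos])
  out[neg] <- -polyval(curve$negative, -meps[neg])
  out
}

#' Footprinting configuration
#'
#' @param ssip_area target footprint area per site, angstrom^2. The default,
#'   9.35, makes a water-sized van der Waals surface (about 37.4 angstrom^2)
#'   coarse-grain to exactly four sites, matching the canonical four-site
#'   description of water.
#' @param iso_level electron-density level defining the surface, e bohr^-3.
#' @param calibration a [calibration_curve()].
#' @return an object of class `footprint_config`.
#' @export
footprint_config <- function(ssip_area = 9.35, iso_level = 0.002,
                             calibration = calibration_curve()) {
  stopifnot(is.numeric(ssip_area), ssip_area > 0,
            is.numeric(iso_level), iso_level > 0,
            inherits(calibration, "calibration_curve"))
  structure(list(ssip_area = ssip_area, iso_level = iso_level,
                 calibration = calibration),
            class = "footprint_config")
}

#' Number of equal-area sites for a surface
#'
#' `max(1, round(total_area / ssip_area))`, with half-integers rounded to
#' even; every molecule gets at least one site.
#'
#' @param total_area total surface area, angstrom^2.
#' @param ssip_area per-site footprint area, angstrom^2.
#' @return positive integer.
#' @export
ssip_count <- function(total_area, ssip_area = 9.35) {
  if (!is.numeric(total_area) || total_area <= 0 ||
      !is.numeric(ssip_area) || ssip_area <= 0) {
    stop("areas must be positive", call. = FALSE)
  }
  max(1L, as.integer(round(total_area / ssip_area)))
}

# Deterministic candidate ordering: strongest |MEPS| first, ties broken by
# coordinates so identical inputs always partition identically.
meps_order <- function(sample) {
  order(-abs(sample$meps), sample$points[, 1], sample$points[, 2],
        sample$points[, 3])
}

# Split n sites between the positive-MEPS and negative-MEPS point classes in
# proportion to their surface areas, largest-remainder rounding (positive
# class wins exact ties). Zero-potential points count as positive.
allocate_signs <- function(n, area_pos, area_neg) {
  total <- area_pos + area_neg
  q_pos <- n * area_pos / total
  q_neg <- n * area_neg / total
  n_pos <- floor(q_pos)
  n_neg <- floor(q_neg)
  if (n_pos + n_neg < n) {
    if ((q_pos - n_pos) >= (q_neg - n_neg)) n_pos <- n_pos + 1L
    else n_neg <- n_neg + 1L
  }
  c(pos = as.integer(n_pos), neg = as.integer(n_neg))
}

#' Partition a surface sample into equal-area footprint patches
#'
#' Greedy accretion: the site budget `n = ssip_count(...)` is first split
#' between the positive- and negative-potential regions in proportion to
#' their areas (largest-remainder rounding). Patches are then grown one at a
#' time: the seed is the unclaimed point with the largest |MEPS| among the
#' classes that still have quota; the patch claims the nearest unclaimed
#' points (Euclidean distance to the seed) until its cumulative area reaches
#' the per-site footprint area, never consuming points a later seed of the
#' other class will need. Points left over after the last patch are attached
#' to the patch with the nearest seed, so patch areas sum exactly to the
#' sampled surface area.
#'
#' @param sample a [surface_sample()].
#' @param config a [footprint_config()].
#' @return list of patches, each with `extremum` (point index), `members`
#'   (point indices, extremum included), `area` (angstrom^2) and `sign`.
#' @export
partition_surface <- function(sample, config = footprint_config()) {
  stopifnot(inherits(sample, "surface_sample"),
            inherits(config, "footprint_config"))
  npts <- nrow(sample$points)
  n <- ssip_count(sample$total_area, config$ssip_area)
  if (n > npts) {
    stop("surface has ", npts, " points but ", n, " sites are required; ",
         "use a finer grid", call. = FALSE)
  }
  is_pos <- sample$meps >= 0
  quota <- allocate_signs(n, sum(sample$areas[is_pos]),
                          sum(sample$areas[!is_pos]))
  # a class with quota but no points: fold its quota into the other class
  if (quota["pos"] > sum(is_pos)) {
    quota["neg"] <- quota["neg"] + quota["pos"] - sum(is_pos)
    quota["pos"] <- sum(is_pos)
  }
  if (quota["neg"] > sum(!is_pos)) {
    quota["pos"] <- quota["pos"] + quota["neg"] - sum(!is_pos)
    quota["neg"] <- sum(!is_pos)
  }

  ord <- meps_order(sample)
  unclaimed <- rep(TRUE, npts)
  free_count <- c(pos = sum(is_pos), neg = sum(!is_pos))
  patches <- vector("list", n)

  for (p in seq_len(n)) {
    # seed: strongest unclaimed point in a class that still has quota
    seed <- NA_integer_
    for (idx in ord) {
      if (!unclaimed[idx]) next
      cls <- if (is_pos[idx]) "pos" else "neg"
      if (quota[cls] > 0L) { seed <- idx; break }
    }
    seed_cls <- if (is_pos[seed]) "pos" else "neg"
    quota[seed_cls] <- quota[seed_cls] - 1L
    unclaimed[seed] <- FALSE
    free_count[seed_cls] <- free_count[seed_cls] - 1L

    members <- seed
    area <- sample$areas[seed]
    if (area < config$ssip_area) {
      cand <- which(unclaimed)
      d2 <- rowSums(sweep(sample$points[cand, , drop = FALSE], 2L,
                          sample$points[seed, ])^2)
      for (ci in cand[order(d2)]) {
        if (area >= config$ssip_area) break
        cls <- if (is_pos[ci]) "pos" else "neg"
        # keep enough points of each class for the remaining seeds
        if (free_count[cls] <= quota[cls]) next
        unclaimed[ci] <- FALSE
        free_count[cls] <- free_count[cls] - 1L
        members <- c(members, ci)
        area <- area + sample$areas[ci]
      }
    }
    patches[[p]] <- list(extremum = seed, members = members, area = area,
                         sign = sign(sample$meps[seed]))
  }

  # attach leftovers to the nearest seed so areas sum to the total
  left <- which(unclaimed)
  if (length(left) > 0L) {
    seeds <- vapply(patches, `[[`, 1L, "extremum")
    seed_pts <- sample$points[seeds, , drop = FALSE]
    for (ci in left) {
      d2 <- rowSums(sweep(seed_pts, 2L, sample$points[ci, ])^2)
      p <- which.min(d2)
      patches[[p]]$members <- c(patches[[p]]$members, ci)
      patches[[p]]$area <- patches[[p]]$area + sample$areas[ci]
    }
  }
  patches
}

#' Footprint a surface sample into an SSIP set
#'
#' One site per patch from [partition_surface()], positioned at the patch's
#' extremal surface point (the interaction site), with epsilon calibrated
#' from the extremal potential.
#'
#' @param sample a [surface_sample()].
#' @param config a [footprint_config()].
#' @param title molecule label carried into the output.
#' @return a [ssip_set()].
#' @export
footprint <- function(sample, config = footprint_config(), title = "") {
  patches <- partition_surface(sample, config)
  idx <- vapply(patches, `[[`, 1L, "extremum")
  sites <- data.frame(
    x = sample$points[idx, 1],
    y = sample$points[idx, 2],
    z = sample$points[idx, 3],
    epsilon = calibrate_epsilon(sample$meps[idx], config$calibration),
    area = vapply(patches, `[[`, numeric(1L), "area"),
    meps = sample$meps[idx]
  )
  out <- ssip_set(sites, title = title,
                  total_surface_area = sample$total_area, config = config)
  stopifnot(abs(sum(sites$area) - sample$total_area) <=
              0.01 * sample$total_area)
  out
}
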