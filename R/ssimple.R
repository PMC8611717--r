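#' Model constants for the pairwise equilibrium engine
#'
#' @param e_vdw van der Waals contact energy between two equal-area sites,
#'   kJ mol^-1. Default -5.6.
#' @param c_max standard-state concentration, mol L^-1: the maximum
#'   theoretical density of sites, 300 M, derived from the 5 angstrom^3
#'   reference volume per site (the van der Waals volume of water divided by
#'   its four sites). All concentrations are normalized by `c_max`, which
#'   makes the association constants dimensionless.
#' @param v_ssip reference volume per site, angstrom^3 (documentation only).
#' @param gas_constant kJ mol^-1 K^-1.
#' @return an object of class `model_constants`.
#' @export
model_constants <- function(e_vdw = -5.6, c_max = 300, v_ssip = 5,
                            gas_constant = GAS_CONSTANT_KJ) {
  stopifnot(is.numeric(e_vdw), is.numeric(c_max), c_max > 0,
            gas_constant > 0)
  structure(list(e_vdw = e_vdw, c_max = c_max, v_ssip = v_ssip,
                 gas_constant = gas_constant),
            class = "model_constants")
}

#' Association constant between two interaction sites
#'
#' `K = exp(-(E_vdW + min(eps_i * eps_j, 0)) / RT)`, dimensionless under the
#' `c_max` standard state. The polar term `eps_i * eps_j` contributes only
#' for complementary (opposite-sign) sites: for a repulsive same-sign pair
#' the sites are assumed to misalign so that only the nondirectional van der
#' Waals contact remains, and the polar term is set to zero.
#'
#' @param eps_i,eps_j interaction parameters, (kJ mol^-1)^(1/2); vectors are
#'   paired elementwise.
#' @param temperature kelvin.
#' @param constants a [model_constants()].
#' @return dimensionless association constant(s), symmetric in (i, j).
#' @export
association_constant <- function(eps_i, eps_j, temperature,
                                 constants = model_constants()) {
  stopifnot(temperature > 0)
  dg <- constants$e_vdw + pmin(eps_i * eps_j, 0)
  exp(-dg / (constants$gas_constant * temperature))
}

# Full symmetric K matrix for a vector of epsilon values.
association_matrix <- function(eps, temperature,
                               constants = model_constants()) {
  dg <- constants$e_vdw + pmin(outer(eps, eps), 0)
  exp(-dg / (constants$gas_constant * temperature))
}

#' Define a solvent component
#'
#' @param name component name as used in phase files.
#' @param ssips a [ssip_set()], or a bare numeric vector of epsilon values.
#' @param molar_volume liquid molar volume, L mol^-1.
#' @return an object of class `phase_component`.
#' @export
phase_component <- function(name, ssips, molar_volume) {
  if (is.numeric(ssips)) {
    ssips <- ssip_set(data.frame(x = 0, y = 0, z = 0, epsilon = ssips),
                      title = name)
  }
  stopifnot(inherits(ssips, "ssip_set"), is.numeric(molar_volume),
            molar_volume > 0)
  structure(list(name = name, ssips = ssips, molar_volume = molar_volume),
            class = "phase_component")
}

#' Load a solvent component library from a directory
#'
#' The directory holds one SSIP XML file per component plus a tab-separated
#' `components.tsv` index with columns `name`, `file` and `molar_volume`
#' (L mol^-1).
#'
#' @param dir directory path.
#' @return named list of [phase_component()] objects.
#' @export
read_ssip_library <- function(dir) {
  index_path <- file.path(dir, "components.tsv")
  if (!file.exists(index_path)) {
    stop("no components.tsv index in ", dir, call. = FALSE)
  }
  idx <- utils::read.delim(index_path, comment.char = "#",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("name", "file", "molar_volume") %in% names(idx)))
  comps <- lapply(seq_len(nrow(idx)), function(i) {
    phase_component(idx$name[i],
                    read_ssip_xml(file.path(dir, idx$file[i])),
                    idx$molar_volume[i])
  })
  stats::setNames(comps, idx$name)
}

#' Assemble a phase state from a specification and a component library
#'
#' Ideal-mixing molarity: the mixture concentration is
#' `c_mix = 1 / sum_k chi_k V_m,k`. Every site of component k is present at
#' concentration `chi_k * c_mix`, normalized by `c_max` into an occupancy
#' `theta`; the remaining `theta_E = 1 - sum(theta)` is the void fraction,
#' the unoccupied-volume reference state. The pairwise association matrix is
#' filled from [association_constant()] at the phase temperature.
#'
#' @param spec a [phase_spec()].
#' @param library named list of [phase_component()] objects resolving every
#'   component name in `spec`.
#' @param constants a [model_constants()].
#' @return an unsolved `phase_state`; pass to [solve_speciation()].
#' @export
build_phase_state <- function(spec, library, constants = model_constants()) {
  stopifnot(inherits(spec, "phase_spec"))
  missing <- setdiff(names(spec$components), names(library))
  if (length(missing) > 0L) {
    stop("unknown component(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vm <- vapply(names(spec$components),
               function(nm) library[[nm]]$molar_volume, numeric(1L))
  c_mix <- 1 / sum(spec$components * vm) # mol / L
  species <- do.call(rbind, lapply(names(spec$components), function(nm) {
    eps <- library[[nm]]$ssips$sites$epsilon
    data.frame(component = nm, epsilon = eps,
               theta = rep(spec$components[[nm]] * c_mix / constants$c_max,
                           length(eps)))
  }))
  if (is.null(species)) {
    species <- data.frame(component = character(), epsilon = numeric(),
                          theta = numeric())
  }
  total <- sum(species$theta)
  if (total > 1 + 1e-12) {
    stop("composition over-packs the phase: total site occupancy ",
         format(total, digits = 6), " > 1 for ",
         paste0(names(spec$components), " (",
                format(spec$components, digits = 4), ")", collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(temperature = spec$temperature,
         species = species,
         epsilon = species$epsilon,
         theta = species$theta,
         theta_void = 1 - total,
         K = association_matrix(species$epsilon, spec$temperature, constants),
         f = NULL, converged = FALSE, iterations = 0L,
         constants = constants,
         descriptor = paste0(names(spec$components), ":",
                             format(spec$components, digits = 4,
                                    trim = TRUE), collapse = "+")),
    class = "phase_state"
  )
}

#' An empty (gas / vacuum) phase
#'
#' No solvent sites, void fraction 1; the zero of the solvation energy
#' scale.
#'
#' @param temperature kelvin.
#' @param constants a [model_constants()].
#' @return a solved `phase_state` with no species.
#' @export
gas_phase <- function(temperature = 298, constants = model_constants()) {
  structure(
    list(temperature = temperature,
         species = data.frame(component = character(), epsilon = numeric(),
                              theta = numeric()),
         epsilon = numeric(), theta = numeric(), theta_void = 1,
         K = matrix(numeric(), 0L, 0L),
         f = numeric(), converged = TRUE, iterations = 0L,
         constants = constants, descriptor = "gas"),
    class = "phase_state"
  )
}

#' @export
print.phase_state <- function(x, ...) {
  cat("<phase_state> ", x$descriptor, " at ", x$temperature, " K: ",
      length(x$theta), " site species, void fraction ",
      signif(x$theta_void, 4), "\n", sep = "")
  cat("  ", if (x$converged) paste0("solved in ", x$iterations, " iterations")
      else "not yet solved", "\n", sep = "")
  invisible(x)
}

#' Solve the speciation of free and bound sites
#'
#' Every pair of sites can form a 1:1 contact with association constant
#' `K_ij`. At equilibrium the free fractions `f` obey the mass balance
#' `theta_i = f_i * (1 + sum_j K_ij f_j)` (an i-i contact consumes two
#' copies of site i, which is exactly the `j = i` term). Solved by damped
#' fixed-point iteration `f <- theta / (1 + K f)`, which is a contraction
#' for the occupancies and association strengths of molecular liquids. The
#' void is excluded: unoccupied volume is an inert reference that binds
#' nothing.
#'
#' @param state a `phase_state` from [build_phase_state()].
#' @param tol convergence tolerance on the mass-balance residual.
#' @param max_iter iteration cap.
#' @param damping step fraction in (0, 1]; the converged fixed point does
#'   not depend on it.
#' @return the state with `f`, `converged` and `iterations` filled in.
#' @export
solve_speciation <- function(state, tol = 1e-12, max_iter = 1e4,
                             damping = 0.5) {
  stopifnot(inherits(state, "phase_state"), damping > 0, damping <= 1)
  n <- length(state$theta)
  if (n == 0L) {
    state$f <- numeric()
    state$converged <- TRUE
    return(state)
  }
  th <- state$theta
  K <- state$K
  f <- th / (1 + K %*% th)
  resid_hist <- numeric(0)
  for (it in seq_len(max_iter)) {
    bound <- K %*% f
    resid <- max(abs(th - f * (1 + bound)))
    resid_hist <- c(resid_hist, resid)
    if (resid <= tol) {
      state$f <- as.numeric(f)
      state$converged <- TRUE
      state$iterations <- it
      return(state)
    }
    f <- (1 - damping) * f + damping * th / (1 + bound)
  }
  stop("speciation did not converge in ", max_iter,
       " iterations; last residuals: ",
       paste(signif(utils::tail(resid_hist, 5L), 3), collapse = ", "),
       call. = FALSE)
}

#' Equilibrium concentrations of pairwise contacts
#'
#' `theta_ij = K_ij f_i f_j` for distinct sites and
#' `theta_ii = K_ii f_i^2 / 2` on the diagonal (each i-i contact consumes
#' two copies of i), so that `f_i + sum_{j != i} theta_ij + 2 theta_ii`
#' recovers `theta_i` exactly.
#'
#' @param state a solved `phase_state`.
#' @return symmetric matrix of contact occupancies (units of theta).
#' @export
contact_matrix <- function(state) {
  stopifnot(inherits(state, "phase_state"))
  if (!state$converged || is.null(state$f)) {
    stop("phase state is not solved; run solve_speciation() first",
         call. = FALSE)
  }
  cm <- state$K * outer(state$f, state$f)
  diag(cm) <- diag(cm) / 2
  cm
}

#' Solvation free energy of an ideal probe site
#'
#' At infinite dilution a probe site with parameter `eps` partitions over
#' the phase's free sites and its void. The void is the zero-energy
#' reference (K = 1, no van der Waals term), so
#' `dG = -RT log(theta_E + sum_j K(eps, eps_j) f_j)`, which is exactly zero
#' in vacuum. The probe does not perturb the solvent speciation.
#'
#' @param eps probe parameter(s), (kJ mol^-1)^(1/2); vectorized.
#' @param state a solved `phase_state`.
#' @return solvation free energies, kJ mol^-1.
#' @export
solvation_energy <- function(eps, state) {
  stopifnot(inherits(state, "phase_state"))
  if (!state$converged) {
    stop("phase state is not solved; run solve_speciation() first",
         call. = FALSE)
  }
  cst <- state$constants
  rt <- cst$gas_constant * state$temperature
  if (length(state$f) == 0L) {
    return(rep(0, length(eps)))
  }
  kp <- exp(-(cst$e_vdw + pmin(outer(eps, state$epsilon), 0)) / rt)
  w <- state$theta_void + as.numeric(kp %*% state$f)
  -rt * log(w)
}

#' Phase-transfer free energy of a probe site
#'
#' Difference of solvation energies between two phases at the same
#' temperature; antisymmetric under swapping them.
#'
#' @param eps probe parameter(s).
#' @param from,to solved `phase_state`s at the same temperature.
#' @return transfer free energies, kJ mol^-1.
#' @export
transfer_energy <- function(eps, from, to) {
  if (abs(from$temperature - to$temperature) > 1e-9) {
    stop("phases are at different temperatures (", from$temperature,
         " vs ", to$temperature, " K)", call. = FALSE)
  }
  solvation_energy(eps, to) - solvation_energy(eps, from)
}
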