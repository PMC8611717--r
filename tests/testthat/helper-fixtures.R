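# Shared fixtures, built once per test run. Everything is generated in code;
# analytic oracles live next to the generators they check.

# Radius (bohr) of the 0.002 level set of a unit Gaussian density.
SPHERE_RADIUS_BOHR <- sqrt(log(1 / 0.002))
BOHR <- 0.529177210903

# Unit-Gaussian density + unit point charge on a 64^3 grid; used by the
# surface tests and the acceptance checks.
sphere_cubes <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_gaussian_cubes(rbind(c(0, 0, 0)), charges = 1,
                                    counts = 64L, origin = c(-4, -4, -4),
                                    extent = c(8, 8, 8))
    }
    cache
  }
})

# Solvent library resolving the worked two-phase example.
example_library <- function() {
  read_ssip_library(system.file("extdata", package = "ssipr"))
}

# A solved pure-water phase at 298 K from the bundled synthetic library.
solved_water_phase <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- phase_spec(298, c(water = 1))
      cache <<- solve_speciation(build_phase_state(spec, example_library()))
    }
    cache
  }
})

# Single-species phase built directly from an epsilon value; bypasses the
# library so solver properties can be probed at arbitrary occupancies.
single_species_state <- function(eps, theta, temperature = 298,
                                 constants = model_constants()) {
  state <- structure(
    list(temperature = temperature,
         species = data.frame(component = "x", epsilon = eps, theta = theta),
         epsilon = eps, theta = theta, theta_void = 1 - theta,
         K = matrix(association_constant(eps, eps, temperature, constants),
                    1L, 1L),
         f = NULL, converged = FALSE, iterations = 0L,
         constants = constants, descriptor = "synthetic"),
    class = "phase_state")
  state
}

# General hand-built phase state from epsilon/theta vectors.
manual_state <- function(eps, theta, temperature = 298,
                         constants = model_constants(), K = NULL) {
  if (is.null(K)) {
    K <- exp(-(constants$e_vdw + pmin(outer(eps, eps), 0)) /
               (constants$gas_constant * temperature))
  }
  structure(
    list(temperature = temperature,
         species = data.frame(component = "x", epsilon = eps, theta = theta),
         epsilon = eps, theta = theta, theta_void = 1 - sum(theta),
         K = K, f = NULL, converged = FALSE, iterations = 0L,
         constants = constants, descriptor = "synthetic"),
    class = "phase_state")
}

# Closed-form free fraction for one self-associating species:
# theta = f (1 + K f)  =>  f = (-1 + sqrt(1 + 4 K theta)) / (2 K).
single_species_oracle <- function(theta, K) {
  (-1 + sqrt(1 + 4 * K * theta)) / (2 * K)
}

fibonacci_sphere_points <- ssipr:::fibonacci_sphere

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s <- sin(angle); t <- 1 - c_
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  matrix(c(t * x * x + c_, t * x * y - s * z, t * x * z + s * y,
           t * x * y + s * z, t * y * y + c_, t * y * z - s * x,
           t * x * z - s * y, t * y * z + s * x, t * z * z + c_),
         3L, 3L, byrow = TRUE)
}
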