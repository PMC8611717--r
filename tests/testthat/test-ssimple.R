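RT298 <- 8.3145e-3 * 298

test_that("association constants follow the contact model and the same-sign rule", {
  # nonpolar contact: K = exp(-E_vdW / RT), written out independently here
  k00 <- exp(5.6 / RT298)
  expect_equal(association_constant(0, 0, 298), k00)
  expect_equal(k00, 9.585, tolerance = 2e-4)

  # repulsive same-sign pairs fall back to the van der Waals contact
  expect_equal(association_constant(2, 3, 298), k00)
  expect_equal(association_constant(-1.5, -4, 298), k00)

  # complementary pair: polar term adds to the contact energy
  expect_equal(association_constant(2, -3, 298), exp((5.6 + 6.0) / RT298))
  expect_equal(exp((5.6 + 6.0) / RT298), 107.9, tolerance = 1e-3)

  # symmetry and magnitude-independence of same-sign values
  set.seed(3)
  eps <- stats::runif(20, -6, 6)
  K <- ssipr:::association_matrix(eps, 298)
  expect_equal(K, t(K))
  same <- outer(eps, eps) > 0
  expect_true(all(abs(K[same] - k00) < 1e-12))
})

test_that("phase assembly reproduces ideal-mixing occupancies", {
  lib <- example_library()
  st <- build_phase_state(phase_spec(298, c(water = 1)), lib)
  # 1 / 0.01807 L/mol = 55.34 M; per-site theta = 55.34 / 300
  theta <- (1 / 0.01807) / 300
  expect_equal(st$theta, rep(theta, 4))
  expect_equal(st$theta_void, 1 - 4 * theta)
  expect_equal(st$theta_void, 1 - sum(st$theta), tolerance = 1e-12)

  # two-component mixture: theta proportional to chi_k * c_mix
  mix <- build_phase_state(phase_spec(298, c(water = 0.75, ethanol = 0.25)),
                           lib)
  c_mix <- 1 / (0.75 * 0.01807 + 0.25 * 0.05847)
  expect_equal(mix$theta[mix$species$component == "water"],
               rep(0.75 * c_mix / 300, 4))
  expect_equal(mix$theta[mix$species$component == "ethanol"],
               rep(0.25 * c_mix / 300, 7))

  # a near-ideal-gas component occupies nothing
  gaslike <- list(x = phase_component("x", c(1, -1), molar_volume = 1e6))
  dilute <- build_phase_state(phase_spec(298, c(x = 1)), gaslike)
  expect_lt(sum(dilute$theta), 1e-5)
  expect_equal(dilute$theta_void, 1, tolerance = 1e-5)

  expect_error(build_phase_state(phase_spec(298, c(brine = 1)), lib),
               "unknown component")
  packed <- list(x = phase_component("x", rep(0, 40), molar_volume = 0.01807))
  expect_error(build_phase_state(phase_spec(298, c(x = 1)), packed),
               "over-packs")
})

test_that("single-species speciation matches the quadratic closed form", {
  set.seed(2024)
  for (i in 1:50) {
    theta <- stats::runif(1, 0.01, 0.95)
    eps <- stats::runif(1, -6, 6)
    st <- solve_speciation(single_species_state(eps, theta))
    K <- st$K[1, 1]
    expect_equal(st$f, single_species_oracle(theta, K), tolerance = 1e-8)
    expect_true(st$f > 0 && st$f <= theta)
  }
})

test_that("without binding the free fractions equal the occupancies", {
  st <- manual_state(c(1, -2, 0), c(0.2, 0.3, 0.1), K = matrix(0, 3, 3))
  st <- solve_speciation(st)
  expect_equal(st$f, st$theta)
  expect_equal(contact_matrix(st), matrix(0, 3, 3))
})

test_that("two-species speciation agrees with an independent dense root-finder", {
  skip_if_not_installed("pracma")
  set.seed(77)
  for (i in 1:10) {
    eps <- stats::runif(2, -5, 5)
    theta <- stats::runif(2, 0.05, 0.45)
    st <- solve_speciation(manual_state(eps, theta))
    K <- st$K
    res <- function(f) f * (1 + as.numeric(K %*% f)) - theta
    oracle <- pracma::fsolve(res, x0 = theta / 2, tol = 1e-13)$x
    expect_equal(st$f, as.numeric(oracle), tolerance = 1e-8)
  }
})

test_that("contact populations conserve every species", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(2:6, 1)
    eps <- stats::runif(n, -6, 6)
    theta <- stats::runif(n)
    theta <- 0.8 * theta / sum(theta)
    st <- solve_speciation(manual_state(eps, theta))
    cm <- contact_matrix(st)
    expect_equal(cm, t(cm))
    recovered <- st$f + rowSums(cm) + diag(cm) # diagonal counted twice
    expect_equal(recovered, st$theta, tolerance = 1e-9)
  }
  # single species: f + 2 theta_11 = theta
  st <- solve_speciation(single_species_state(0, 0.5))
  cm <- contact_matrix(st)
  expect_equal(st$f + 2 * cm[1, 1], 0.5, tolerance = 1e-9)
  expect_error(contact_matrix(single_species_state(0, 0.5)), "not solved")
})

test_that("the solved point does not depend on the damping factor", {
  st <- manual_state(c(2.8, 2.8, -4.5, -4.5), rep(0.1845, 4))
  f1 <- solve_speciation(st, damping = 0.2)$f
  f2 <- solve_speciation(st, damping = 0.8)$f
  expect_equal(f1, f2, tolerance = 1e-8)
})

test_that("solvation energy is zero in vacuum and vanishes in the gas limit", {
  gas <- gas_phase(298)
  probes <- seq(-8, 8, by = 0.5)
  expect_equal(solvation_energy(probes, gas), rep(0, length(probes)))

  # theta -> 0: dG_solv -> 0 for any probe, even the strongest complement
  worst <- vapply(c(1e-5, 1e-7, 1e-9), function(theta) {
    st <- solve_speciation(single_species_state(-3, theta))
    max(abs(solvation_energy(probes, st)))
  }, numeric(1))
  expect_true(all(diff(worst) < 0))
  expect_lt(worst[3], 1e-3)
})

test_that("a dense nonpolar phase solvates a nonpolar probe favorably", {
  # all contacts at K = exp(-E_vdW/RT) ~ 9.58: the log argument exceeds 1
  st <- solve_speciation(single_species_state(0, 0.738))
  expect_lt(solvation_energy(0, st), 0)
})

test_that("a nonpolar probe pays a desolvation penalty in associated water", {
  # strong water-water hydrogen bonding depletes free sites, so a probe that
  # cannot hydrogen-bond is better off in the void: the hydrophobic effect
  st <- solved_water_phase()
  expect_gt(solvation_energy(0, st), 0)
  # while a strong donor is well solvated by the free acceptor sites
  expect_lt(solvation_energy(5, st), 0)
})

test_that("solvation of a donor probe strengthens monotonically in acceptor solvent", {
  st <- solve_speciation(single_species_state(-4, 0.4))
  dg <- solvation_energy(seq(0, 5, by = 0.25), st)
  expect_true(all(diff(dg) <= 0))
})

test_that("transfer energies are antisymmetric and anchored to the gas phase", {
  water <- solved_water_phase()
  gas <- gas_phase(298)
  eps <- seq(-5, 5, by = 1)
  expect_equal(transfer_energy(eps, water, water), rep(0, length(eps)))
  expect_equal(transfer_energy(eps, gas, water),
               -transfer_energy(eps, water, gas))
  expect_equal(transfer_energy(eps, gas, water),
               solvation_energy(eps, water))
  expect_error(transfer_energy(0, gas_phase(310), water),
               "different temperatures")
})
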