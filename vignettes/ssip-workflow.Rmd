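---
title: "From electrostatic potential surfaces to liquid-phase equilibria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From electrostatic potential surfaces to liquid-phase equilibria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssipr)
```

## The model

ssipr implements the surface site interaction point (SSIP) description of
noncovalent chemistry and the pairwise equilibrium model built on it
(SSIMPLE — the surface site interaction model for the properties of liquids
at equilibrium). A neutral organic molecule is replaced by a set of discrete
sites, each covering an equal-area footprint of its van der Waals surface
(the 0.002 e bohr⁻³ electron-density isosurface) and each carrying a signed
interaction parameter $\epsilon$. Positive $\epsilon$ behaves like the
experimental hydrogen-bond donor parameter $\alpha$, negative $\epsilon$
like the acceptor parameter $-\beta$; $\epsilon^2$ is a molar energy, so
$\epsilon$ has units $(\mathrm{kJ\,mol^{-1}})^{1/2}$.

Any two sites $i$ and $j$ can form a 1:1 contact with

$$K_{ij} = \exp\!\left(-\frac{E_{\mathrm{vdW}} +
  \min(\epsilon_i\epsilon_j,\,0)}{RT}\right),$$

where $E_{\mathrm{vdW}} = -5.6\ \mathrm{kJ\,mol^{-1}}$ is the constant van
der Waals contact energy between two equal-area sites (van der Waals
energies are approximately linear in surface area, which is why equal-area
footprints admit a single constant). For a same-sign (repulsive) pair the
sites are assumed to misalign so that only the nondirectional van der Waals
contact is made: the polar term is set to zero. $K_{ij}$ is made
dimensionless by normalizing all concentrations by the maximum theoretical
site density $c_{\max} = 300\ \mathrm{M}$, which follows from the
5 Å³ reference volume per site (the van der Waals volume of water divided
by its four sites).

A liquid phase is a vector of site occupancies
$\theta_i = c_i / c_{\max}$; whatever is not occupied is the void fraction
$\theta_E = 1 - \sum_i \theta_i$. At equilibrium the free fractions $f_i$
satisfy the mass balance

$$\theta_i = f_i\Big(1 + \sum_j K_{ij} f_j\Big),$$

where the $j = i$ term correctly counts an $i$–$i$ contact as consuming two
copies of $i$ (the contact population itself is
$\theta_{ii} = K_{ii} f_i^2 / 2$). From the solved speciation the package
derives solvation free energies of ideal probe sites, phase-transfer
energies, functional group interaction profiles (FGIPs) and solvent
similarity indices (SSIs).

## The footprinting pipeline

`read_cube()` ingests a matched pair of Gaussian cube grids — electron
density and electrostatic potential — in their native bohr geometry.
`build_surface_sample()` then

1. triangulates the 0.002 e bohr⁻³ density level set by marching
   tetrahedra with linear edge interpolation (each voxel is split into six
   tetrahedra around its main diagonal; shared edges are merged so the mesh
   is watertight and connected),
2. assigns each vertex one third of every incident triangle's area, which
   conserves the total mesh area exactly, and
3. interpolates the potential trilinearly at each vertex, converting
   hartree to kJ mol⁻¹ (× 2625.4996).

All downstream geometry is in angstrom; the bohr→angstrom conversion
(× 0.529177210903) happens once, at this boundary. Marching tetrahedra was
chosen over classic marching cubes because it has no ambiguous sign
configurations, so the mesh is deterministic and free of topological holes
that would corrupt the area bookkeeping; on the analytic spherical fixture
the mesh area at 64³ resolution is within 1.4 % of $4\pi r^2$.

`footprint()` coarse-grains the sampled surface into
$n = \max(1, \mathrm{round}(A_{\mathrm{total}} / A_{\mathrm{SSIP}}))$
sites. The site budget is first split between the positive- and
negative-potential regions in proportion to their areas
(largest-remainder rounding), so a strongly polar minority patch is never
swallowed by the majority sign. Patches are then grown greedily: the seed
is the unclaimed point with the largest |MEPS| among the sign classes that
still have quota (ties broken lexicographically by coordinates for
determinism), and the patch claims the nearest unclaimed points until its
area reaches the per-site footprint, never consuming points a later seed of
the other class will need. Leftover points attach to the nearest seed, so
patch areas always sum exactly to the sampled area. The site sits at the
patch's extremal point — the extremum *is* the interaction site — rather
than at the patch centroid, which would smear a directional hydrogen-bond
site toward the nonpolar background.

### Tunable parameters

* `ssip_area` (default **9.35 Ų**): the equal-area footprint. The value is
  fixed by the canonical four-site description of water: a water-sized van
  der Waals surface of ≈ 37.4 Ų divided by four sites. It is configurable
  because coarser or finer descriptions are legitimate model choices.
* `iso_level` (default **0.002 e bohr⁻³**): the density defining the
  surface.
* `calibration`: the MEPS → $\epsilon$ map, a pair of odd-extended
  polynomial branches through the origin (`calibration_curve()`). The
  default is linear with coefficient 0.01 $(\mathrm{kJ\,mol^{-1}})^{1/2}$
  per kJ mol⁻¹ on both branches, chosen once so that realistic extrema of
  a small polar molecule's surface potential (≈ +280 / −230 kJ mol⁻¹ for
  water's donors and lone pairs) map onto $\epsilon$ values of the
  magnitude of water's experimental hydrogen-bond parameters. Published
  quadratic calibration fits can be supplied as longer coefficient
  vectors; the curve is a pluggable policy, not a claim about the original
  calibration's coefficients, which this package does not reproduce.

## Phase assembly and the void

`read_phase_tsv()` parses the phase dialect — one phase per line,
temperature first, then (component, mole fraction) pairs — and
`build_phase_state()` resolves the components in a solvent library (SSIP
XML files plus molar volumes, which the tsv format does not carry). Mixture
molarity assumes ideal mixing, $c_{\mathrm{mix}} = 1/\sum_k \chi_k V_{m,k}$.
Mole fractions must sum to 1 within 10⁻⁶; violations are hard errors rather
than silent renormalizations, because they almost always indicate a typo in
the input file.

The void is treated as an inert reference: it is excluded from the
speciation solver (unoccupied volume binds nothing) and pairs with probe
sites at $K = 1$, i.e. zero free energy and no van der Waals term. Two
consequences anchor the energy scale: a probe in vacuum has exactly zero
solvation energy, and
$\Delta G_{\mathrm{solv}}(\epsilon) =
 -RT\ln(\theta_E + \sum_j K(\epsilon,\epsilon_j) f_j)$
can be *positive* in a strongly self-associated solvent — a nonpolar probe
in water pays ≈ +1.5 kJ mol⁻¹ with the bundled synthetic water, the
familiar hydrophobic desolvation cost — while any dense weakly polar phase
solvates it favorably. The void treatment is isolated in
`solvation_energy()` so an alternative convention can be substituted in one
place.

## Numerical choices

* **Speciation solver**: damped fixed-point iteration
  $f \leftarrow (1-d)f + d\,\theta/(1 + Kf)$ with $d = 0.5$, residual
  tolerance 10⁻¹², cap 10⁴ iterations. The iteration is a contraction for
  the occupancies ($\theta \le 1$) and association strengths (up to
  $K \sim 10^4$) of molecular liquids, and the fixed point is independent
  of $d$ (verified to 10⁻⁸ at $d = 0.2$ vs $0.8$); Newton steps would add
  complexity without buying robustness here. Non-convergence raises an
  error carrying the residual history.
* **Homodimer convention**: the mass balance uses
  $f_i(1 + \sum_j K_{ij}f_j)$ with $\theta_{ii} = K_{ii}f_i^2/2$, so
  $f_i + \sum_{j\ne i}\theta_{ij} + 2\theta_{ii} = \theta_i$ holds to
  10⁻⁹. Double-counting of self-contacts is the classic defect in this
  family of models; the conservation identity is asserted in the tests for
  every solved phase.
* **Degenerate inputs**: zero-area triangles contribute nothing to vertex
  areas (counted, not fatal); an empty phase solves trivially with
  $\theta_E = 1$; probes never perturb the solvent speciation
  (infinite-dilution contract); compositions whose sites would exceed
  $c_{\max}$ raise an over-packing error naming the composition.
* **Tie-breaking**: patch seeds with equal |MEPS| are ordered by
  $(-|\mathrm{MEPS}|, x, y, z)$; identical inputs always produce identical
  SSIP sets.

## The applications

The FGIP tabulates, over a grid of donor probes $+\alpha$ (default 0–5,
step 0.1) and acceptor probes $-\beta$ (default 0–10, step 0.2), the
exchange free energy of bringing two dissolved probes into contact:

$$\Delta\Delta G_{\mathrm{FGI}}(a,b) = \Delta G_{\mathrm{int}}(a,b)
  + \Delta G_{ss} - \Delta G_{\mathrm{solv}}(a) -
  \Delta G_{\mathrm{solv}}(b),$$

with $\Delta G_{\mathrm{int}} = E_{\mathrm{vdW}} + \min(\epsilon_a
\epsilon_b, 0)$ the direct contact term and $\Delta G_{ss}$ the
population-weighted mean solvation energy of the phase's own sites (the
solvent–solvent contact regained when two solutes pair). This is the
minimal bookkeeping with the correct limits — in the gas phase the profile
reduces to $\Delta G_{\mathrm{int}}$ exactly, and it is symmetric in the
two probes to machine precision — and it lives in one internal function so
a different exchange convention can be swapped in. With the bundled
synthetic water at 298 K the complementary strong-site corner (large
$\alpha$, large $\beta$) is strongly favorable while the mismatched edge
(large $\alpha$, $\beta = 0$) is not, the qualitative signature expected of
water.

The SSI compares two phases through their solvation profiles
$D_P(\epsilon) = \Delta G_{\mathrm{solv}}(\epsilon\,|\,P)$ over idealized
probes ($\epsilon$ from −10 to +5, step 0.1, spanning strong acceptors to
strong donors). The default metric is the uncentered cosine of the two
profiles — reflexively 1, symmetric, and decaying as one phase's sites move
away from the other's; the metric is pluggable pending any alternative
definition.

## What the synthetic fixtures emulate — and what they do not

Quantum-chemical surface generation is deliberately out of scope: the
package consumes cube files from any electronic-structure code. The
synthetic module provides analytic stand-ins so that every stage is
testable without one:

* `make_gaussian_cubes()` — Gaussian densities and softened point-charge
  potentials (softening radius 0.1 bohr, excluding only nodes essentially
  on top of a charge). Every sampled value has a closed form; the
  0.002-level set of a unit Gaussian is a sphere of radius
  $\sqrt{\ln 500} \approx 2.4929$ bohr.
* `make_water_like_sample()` — a 37.4 Ų spherical cloud with two +280 and
  two −230 kJ mol⁻¹ tetrahedral lobes, emulating water's two donors and
  two lone pairs; it footprints to exactly four sites, two of each sign.
* The bundled solvent descriptors (`inst/extdata`) are *synthetic*
  four-site water and seven-site ethanol sets with literature-magnitude
  hydrogen-bond parameters; they are not the published per-solvent SSIP
  library, which is external supplementary material.

Passing tests therefore demonstrate the correctness of the machinery —
geometry, coarse-graining, equilibria, bookkeeping — on fields whose ground
truth is analytic. They do not validate DFT-quality surface potentials,
conformational averaging, or the published calibration coefficients, and
per-molecule $\epsilon$ values will not match published solvent libraries
until such a calibration is supplied.

Problem sizes used throughout the documentation and tests — 64³ grids for
surface fixtures, ~10³-point surface clouds, 4–11-species phases — are the
package's chosen demonstration scale; the algorithms are resolution- and
size-agnostic.

## Known limitations

* $E_{\mathrm{vdW}}$ is temperature-independent and mixing is ideal;
  non-ideal excess volumes and activity coefficients are out of scope.
* The SSIP XML dialect is a documented functional schema, not
  byte-compatible with any external tool's schema.
* Symmetry detection (merging equivalent sites) is not performed.
* Charged species are outside the model's domain (the calibration and
  $E_{\mathrm{vdW}}$ constant are premised on neutral organic surfaces).

## A worked example

```{r example, eval = FALSE}
lib <- read_ssip_library(system.file("extdata", package = "ssipr"))
tsv <- tempfile(); write_example_phase_tsv(tsv)
states <- lapply(read_phase_tsv(tsv),
                 function(s) solve_speciation(build_phase_state(s, lib)))
states[[1]]                      # pure water: void fraction 0.262
solvation_energy(c(0, 5), states[[1]])
fgip(states[[1]])                # 51 x 51 water FGIP
ssi(states[[1]], states[[2]])    # water vs water/ethanol: 0.9975
```
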