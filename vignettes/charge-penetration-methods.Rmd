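---
title: "Basin-resolved electrostatics and charge penetration: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Basin-resolved electrostatics and charge penetration: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iqfpen)
```

## The model

`iqfpen` analyses the electrostatic interaction of a two-fragment
noncovalent complex from continuous charge densities, in the real-space
framework of the quantum theory of atoms in molecules (QTAIM) and its
fragment-level grouping, interacting quantum fragments (IQF). The total
charge density is the electron density plus point nuclei; space is
partitioned into attraction basins $\Omega_I$ of the electron-density
gradient field, one per nucleus, and electrostatic energies are decomposed
into intra-basin self terms and basin-pair interaction terms.

Two densities of the complex are distinguished:

* the **zeroth-order density** $\rho^0 = \rho_A^0 + \rho_B^0$, the sum of
  the unrelaxed fragment densities placed at the complex geometry. Its
  fragment-fragment Coulomb interaction $E^0_{ele}$ is the classical
  (SAPT-like first-order) electrostatic reference;
* a **relaxed density** of the complex, whose intra/interfragment split
  gives the electrostatic contribution to the formation energy,
  $\Delta E_{ele} = \Delta E^A_{ele} + \Delta E^B_{ele} + E^{AB,ele}_{inter}$.

Combining the basin partition of $\rho^0$ with the fragment split of the
density itself double-decomposes $E^0_{ele}$ into exactly four surviving
terms,

$$E^0_{ele} \;=\; E^{AB}_{inter} \;+\; E^{A}_{intra} \;+\; E^{B}_{intra}
\;+\; E^{BA}_{tail\text{-}tail},$$

where $E^{AB}_{inter}$ is each fragment density (with its nuclei) inside
its own basins — the ordinary interfragment term that survives at long
range — while the other three measure density interpenetration:
$E^{A}_{intra}$ is the penetrating tail of $B$ interacting with the host
density and nuclei of $A$ inside $\Omega_A$ (and conversely for
$E^{B}_{intra}$), and the tail–tail term is the pure electron–electron
repulsion of the two penetrating tails, hence non-negative. Their sum is
the basin-resolved charge-penetration energy

$$E^{IQF}_{pen} = E^{A}_{intra} + E^{B}_{intra} + E^{BA}_{tail\text{-}tail},$$

an alternative to the classical multipole-reference definition
$E_{pen} = E^0_{ele} - E_{mtp}(\ell_{max})$, in which truncation and
penetration effects mix (the package reports both, with the truncation
order recorded). The mutual charge-penetration electron counts — electrons
of one fragment found inside the partner's basins — accompany every
decomposition.

## Density models

The engine is density-agnostic behind a small interface (`density_eval`,
`density_grad`, `nuclei_of`, `electron_count`):

* **Promolecular Gaussian densities** (`build_promolecule`,
  `gaussian_density`): one or more spherical Gaussian primitives per atom,
  population `q` integrating exactly, neutral by default. A "polarized"
  mode (`polarize_density`) displaces part of an atom's population to
  emulate relaxed densities, so intrafragment relaxation terms can be
  nonzero without any quantum-chemistry input. Every whole-fragment
  Coulomb quantity is closed-form for this model (erf integrals), which
  the numerics exploit heavily (below).
* **Wavefunction densities** (`read_wfx`, `read_molden`): Cartesian
  primitives with per-MO coefficients (s, p, d for wfx; s, p contracted
  shells for molden), evaluable for density and gradient on arbitrary
  points. These drive the identical grid/basin/expansion machinery; no
  analytic shortcuts are assumed for them.

The promolecular stand-in is qualitatively, not quantitatively, realistic:
real monomer densities (e.g. Hartree–Fock) have exponential tails and
shell structure, so absolute penetration energies of real complexes are
not reproduced. What the synthetic model does reproduce — and what the
tests probe — is the *structure* of the theory: closure of the four-term
identity, the distance decay of every penetration descriptor, sign
structure, multipole-truncation behaviour, and conservation through the
partition.

## Synthetic fixtures

`make_toy_dimer()` provides five neutral presets mirroring the interaction
classes of noncovalent benchmark sets: `hb` (head-to-tail polar OH-like
diatomics, equilibrium centroid separation 4.9 bohr), `polar2` (a more
polar variant, 4.8 bohr), `mixed` (polar diatomic against a closed-shell
atom, 5.4 bohr), `disp` (two diffuse closed-shell atoms, 5.0 bohr) and
`homo` (an apolar homodimer, 4.2 bohr). Exponents and populations were
chosen once so that equilibrium mutual charge-penetration counts fall in
the few-hundredths-of-an-electron range typical of real dimers, the polar
presets bind by several kcal/mol electrostatically, and the apolar presets
have sub-kcal/mol electrostatics dominated by the penetration terms. The
default scan factors are the common eight-point convention of
scaled-separation benchmark sets (0.90–2.00).

## Numerical scheme

**Grids.** Each atom carries a two-zone product grid: a beta-sphere
interior (radius 0.60 times the distance from the nucleus to its nearest
internuclear density saddle, found by a bracketed 1-D line search) and an
outer region to `r_max` = 15 bohr. Radial nodes are Gauss–Legendre in the
mapped coordinate $r = r_0\,q^2/(1-q)^2$; angular rules are
Gauss–Legendre × trapezoid product rules whose polynomial exactness
matches the requested Lebedev order (974/382 inner and 5810/512 outer
points in the production profile; the reduced test profile uses 110/60 and
266/90). All points carry smooth Becke fuzzy-cell weights so overlapping
shells integrate space exactly once; the beta-spheres' role is
topological — their interiors are assigned to their basin without gradient
ascent. A hard quadrature cut at the beta-sphere surface was deliberately
avoided: it makes integrands discontinuous on neighbouring atoms' shells
and costs three orders of magnitude in grid convergence, while the smooth
weights keep the beta-sphere volume integral within 0.2%.

**Basins.** Grid points are assigned by fixed-step gradient ascent
(initial step 0.1 bohr, halved whenever the density would decrease,
capture radius 0.3 bohr, at most 500 steps). Points where
$\rho^0 < 10^{-10}$ e/bohr³ go to the nearest attractor directly — at
those densities the gradient field is numerical round-off and the weighted
contribution is below every stated tolerance. Trajectories that stall on a
ridge fall back to the nearest attractor with a warning count;
convergence to a genuine maximum away from every nucleus (a non-nuclear
attractor) raises an error rather than silently merging basins.

**Restricted Coulomb energies.** Basin-restricted densities are projected
onto real spherical harmonics on the radial shells of the basin's own atom
(a one-centre Laplace expansion, default $\ell_{max} = 10$; the
bipolar-inside/Laplace-outside split used by some QTAIM integration codes
is collapsed into this single configurable order).
The restricted potential follows from the two cumulative radial integrals,
computed with natural-cubic-spline quadrature on the shared mesh — a
trapezoid rule on the reduced mesh leaves ~10⁻⁴ relative error, which
would dominate the 10⁻⁶-hartree oracle tolerances. Two conditioning
safeguards matter at high $\ell$: profiles for $\ell \ge 1$ are zeroed
below r = 0.05 bohr (their true magnitude there, $\propto r^\ell$, is far
below projection round-off, while the $s^{1-\ell}$ weight would amplify
that round-off catastrophically), and the $r^{-(\ell+1)}$ branch of the
potential is suppressed in the same region.

**Accuracy strategy.** The large electron–nuclear cancellations in basin
energies are never formed from truncated expansions alone. Wherever the
density is a Gaussian fragment model, host pieces are rewritten as *full
fragment minus penetrating tail*: full-fragment potentials and
fragment–fragment interactions are closed-form, masked grid sums use the
exact pointwise integrand, and only the small tail pieces go through the
Laplace expansions, so every term's absolute error scales with the (small)
overlap. Consequently the four-term identity closes to machine precision
by construction, the independent accuracy checks are the erf closed form
(10⁻⁶ hartree on whole-space pieces) and a brute-force double-grid sum
(10⁻³ hartree on basin pairs), and the relaxed zeroth-order bookkeeping is
exact. For wavefunction densities the generic expansion route is used
throughout; its basin-pair accuracy at the reduced profile is of order
10⁻³ hartree, improving with the angular orders.

**Known numerical limitations.** Basin ownership is resolved pointwise, so
quantities concentrated at a dividing surface through high-density regions
(e.g. the intra-fragment O–H surface of a polar diatomic) carry a
few-times-10⁻³-electron mask noise at the reduced profile; this redistributes
energy between atom pairs of the *same* fragment but cancels in fragment
totals. Per-pair comparisons against point-multipole models are therefore
made on fixtures whose dividing surfaces pass through near-vacuum.

## Multipolar comparators

Point-charge and distributed-multipole electrostatics use spherical-tensor
site moments (Racah-normalised real solid harmonics, traceless Buckingham
quadrupoles) and Cartesian interaction tensors through rank 4, keeping all
terms with $\ell_1, \ell_2 \le \ell_{max} \in \{0, 1, 2\}$ — the common
multipolar force-field convention. Three moment sources are provided:
QTAIM basin multipoles integrated on the grid (`basin_multipoles`), exact
analytic distributed multipoles of promolecular fragments
(`promol_multipoles`; traceless moments of a displaced spherical Gaussian
equal the solid harmonic at its centre), and ESP-fitted point charges
(`fit_charges`, a plain equality-constrained least-squares fit on
golden-spiral vdW shells at 1.4–2.0 × Bondi radii — no hyperbolic
restraint is applied, a documented difference from RESP protocols). The
scan driver's $E_{mtp}$ columns use the analytic promolecular moments so
that truncation behaviour (monotone improvement with $\ell_{max}$, decay
of $E^0_{ele} - E_{mtp}$ at least as $R^{-4}$ for neutral dipolar dimers)
is observed free of grid noise.

## Problem sizes and design choices

The test suite and the acceptance script run everything at the reduced
profile (110/60 inner, 266/90 outer, $\ell_{max} = 10$), the package's
stated test configuration: a four-atom dimer then carries ~180k grid
points and a full five-preset × eight-factor sweep completes in a few
minutes on one core. The production profile matches the integration
settings typical of published QTAIM basin analyses and is available
through `grid_profile("production")`.

Open choices resolved here, as package policy: the radial map
$r_0 q^2/(1-q)^2$ (any smooth map reproducing the conservation invariants
is acceptable; this one concentrates nodes near the nucleus and reaches
`r_max` smoothly); basins of the zeroth-order analysis are always those of
$\rho^0$, never of a relaxed density; nuclei belong to their own basin and
are never split; fragment relabelling A↔B must leave the penetration
energy invariant and swap the intra terms, which the symmetrised
electron–electron sums guarantee identically; and scan geometries are
generated by rigid translation of fragment B along the fragment-centroid
axis.
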