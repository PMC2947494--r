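---
title: "Implicit-membrane continuum electrostatics with memslab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Implicit-membrane continuum electrostatics with memslab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memslab)
```

## The model

`memslab` solves the linearized Poisson–Boltzmann equation (LPBE) for
proteins at or in a lipid bilayer, with the bilayer represented implicitly as
a low-dielectric slab.  In reduced units, with
$\bar\phi = e\psi/k_BT$ the dimensionless potential, the equation is

$$-\nabla\cdot\big(\epsilon(\mathbf r)\,\nabla\bar\phi\big)
  + \bar\kappa^2(\mathbf r)\,\bar\phi
  = \frac{e^2}{\epsilon_0 k_BT}\,\rho(\mathbf r),$$

where $\epsilon$ is the position-dependent relative permittivity,
$\bar\kappa^2 = e^2\sum_i n_i z_i^2/(\epsilon_0 k_BT)$ is the
Debye–Hückel screening coefficient (zero wherever mobile ions are excluded;
$\bar\kappa^{-1}\sqrt{\epsilon_s}$ is the Debye length), and $\rho$ is the
fixed charge density in e/Å³.  All three coefficient fields live on regular
node-centered grids (`scalar_grid`), read and written as OpenDX files, and
are built from PQR structures (coordinates + per-atom charge and radius):

* **Dielectric map** — nodes inside the molecular region get
  $\epsilon_p$, all others $\epsilon_s$.  The molecular region is the
  probe-carved ("molecular") surface: nodes within $r_i + r_{probe}$ of an
  atom are candidates, and candidates covered by a solvent-accessible probe
  sphere are returned to solvent.  Accessible probe centers are sampled on
  each atom's accessible sphere on a deterministic Fibonacci lattice with
  `surface_sphere_density` points/Å² (default 10); the probe radius defaults
  to 1.4 Å (water).  A faster single-pass inflated-van-der-Waals surface is
  available via `surface_spec(method = "vdw_inflated")`.  No dielectric
  smoothing is applied: smoothing would shift the energies of every
  workflow, and the abrupt two-phase map is what the harmonic-mean stencil
  below expects.
* **Kappa map** — the dimensionless ion accessibility in {0, 1}: zero
  within `atom radius + ion radius` (default 2 Å) of any atom.  The bulk
  coefficient $\bar\kappa^2$ is applied at solve time from the ion species
  and temperature, which keeps the map itself concentration-independent and
  lets the same map serve runs at different ionic strengths.
* **Charge map** — atomic point charges spread with a cubic B-spline kernel
  (two-node half-support per axis).  The kernel is a partition of unity, so
  total charge is conserved exactly, and it reproduces linear functions, so
  the charge centroid is preserved.  Atom-site potentials are interpolated
  with the *same* kernel, which makes the grid self-energy of a charge
  identical across solves on congruent grids and lets it cancel exactly in
  energy differences.

## The membrane

`add_membrane()` rewrites the solution-phase maps node by node, in a fixed
order: (1) protein nodes are never modified; (2) non-protein nodes inside
the slab's z-extent and outside the pore-exclusion region get the membrane
dielectric (or the head-group dielectric within `headgroup_thickness` of
either face) and zero ion accessibility; (3) everything else is untouched.
Design choices that were genuinely open:

* Protein-node detection compares the dielectric value with
  $\epsilon_p$; because $\epsilon_p$ may legitimately equal the membrane
  dielectric (both 2 in typical channel setups), the builder retains an
  explicit protein mask from map construction and uses it whenever present.
  Equality testing alone would mistake previously written membrane for
  protein on a second pass.
* The exclusion region is a frustum: the radius interpolates linearly in z
  between the lower and upper exclusion radii.  Two stacked cylinders split
  at mid-slab would be the only obvious alternative; the linear ramp avoids
  the discontinuity.
* Head-group layers occupy the outermost `headgroup_thickness` of the slab
  symmetrically on both faces, and ions are excluded from head groups as
  well as from the core, consistent with the assumption (used by the
  analytic boundary profile below) that ions cannot enter any part of the
  slab.
* The inner solution space is defined only by `z < z_bottom` plus ion
  accessibility; water in a channel lumen inside the slab belongs to the
  outer space, whatever the exclusion geometry did.

## Transmembrane potential

With the inner bath held at $V$ and the outer bath at 0, the LPBE no longer
decays to zero below the membrane.  The fix is an effective uniform source
over the inner space: every inner-space node adds
$2\,c\,N_A\,\bar\phi_{in}/10^{27}$ e/Å³ to the charge map, where $c$ is the
molar concentration of one species of the (symmetric, monovalent)
electrolyte and $\bar\phi_{in} = eV/k_BT$.  Far below the membrane the
screening term then balances the source at $\bar\phi = \bar\phi_{in}$, as it
must.  Because the equation is linear, the total field separates into the
protein's own field and the membrane-potential field $\bar\phi_{mp}$; the
latter is solved with all protein charges zeroed but the protein cavity and
membrane still in the dielectric/kappa maps.

Dirichlet boundary values for these runs come from the analytic profile of a
bare slab: exponential Debye decay to 0 above, a linear drop across the
slab (where $\bar\kappa = 0$), and exponential approach to $\bar\phi_{in}$
below, joined continuously with the dielectric-weighted flux condition
$\epsilon_w \phi'_w = \epsilon_m \phi'_m$ at both faces.  The profile uses
the membrane-core dielectric for the whole slab and ignores head groups.
`slab_profile()` is verified in the test suite against an independent 1-D
two-point boundary-value solve to better than 0.1%.

## Solver and focusing

The operator is the standard flux-conservative 7-point stencil with
harmonic-mean face permittivities; it is symmetric positive definite and is
solved with Jacobi-preconditioned conjugate gradients (compiled kernel),
relative residual $10^{-6}$ by default.  Far-field boundary options are
zero, single Debye–Hückel (whole structure as one screened sphere),
multiple Debye–Hückel (per-atom screened-Coulomb superposition), the
analytic slab profile, and focusing.  A focusing ladder solves coarse to
fine, each finer grid taking boundary values from trilinear interpolation
of its parent; charge spreading refuses atoms within the kernel support of
a grid edge, so a ladder that focuses too tightly fails loudly rather than
silently truncating charge.

Numerical notes:

* Binary (node-wise) ion accessibility is used in the screening term; no
  spline smoothing of $\bar\kappa^2$.
* Dielectric interfaces are sharpest when they fall *between* node planes:
  the harmonic-mean stencil then places the jump exactly at the mid-face.
  The membrane-potential verification grids are therefore chosen with the
  slab faces mid-cell (e.g. a 128 Å box, 65 nodes, centered at z = 1 for a
  slab at ±14 Å); with faces on node planes the effective slab is half a
  cell too thick on either side, a pure discretization artifact.
* Degenerate inputs fail early with informative errors: empty structures,
  non-congruent maps, focusing children outside parents, nonzero membrane
  potential without electrolyte, non-convergence within `maxit`.

## Workflows

* `protein_solvation()` — $\Delta G = G(\text{membrane}) - G(\text{bulk
  water})$, both states on the identical ladder (self-energies cancel).
* `ion_solvation()` — $\Delta G = G(\text{protein+ion, membrane}) -
  G(\text{protein, membrane}) - G(\text{ion, water})$; three systems per
  level.  `protein_charges_off` zeroes protein charges while keeping the
  cavity, and `protein_keep_residues` retains a residue range (e.g. pore
  helices) — both needed for the classic channel decompositions.
* `gating_charge()` — for each voltage in a symmetric sweep (5 points from
  $-V_{max}$ to $+V_{max}$ including 0; 5 is the smallest odd count that
  still exposes a nonlinearity if one were present), solves
  $\bar\phi_{mp}$ per state and takes the interaction energy
  $\sum_i q_i \bar\phi_{mp}(r_i)\,k_BT$ — the pure cross term, which is the
  separable part under the linear equation.  The valence is the
  least-squares slope of $\Delta G(V)$ against $-eV$.  Sign convention:
  moving positive charge from the inner bath (held at $V$) to the outer
  bath (0) between state 1 and state 2 gives positive valence; a +1 e test
  charge crossing the whole slab yields valence $\approx$ +1.

## Fixtures: what they emulate and what they do not

The package is fully testable without external structure files.
`build_helix()` constructs a coarse-grained ideal $\alpha$-helix — 27
residues, 1.5 Å rise, 3.6 residues/turn, z-aligned and centered — of
neutral hydrophobic residues (leucine by default, chosen as the typical
transmembrane hydrophobic; the identity only sets bead radii) with a single
central arginine carrying +1 e, i.e. the canonical charged-helix membrane
insertion problem.  Each residue contributes a neutral backbone bead, a
z-aligned ±0.35 e charge pair emulating the aligned peptide dipoles of a
helix backbone (so the uncharged variant still pays a small, realistic
insertion cost), and a side-chain bead with the residue's formal net
charge.  It is not an all-atom PARSE/CHARMM structure:
it exercises the full pipeline (surface, membrane, ladder, energies) and
reproduces the qualitative physics (large positive insertion penalty,
sharply reduced for the uncharged variant), but its absolute energies are
not comparable to all-atom results, which depend strongly on the charge
and radius set.  `build_test_charge_system()` provides the analytic
gating-valence fixture.  The packaged case configuration files mirror the
three standard workflow parameterizations and expect externally prepared
PQR files for real proteins.

Problem sizes in the tests and the acceptance script are chosen to keep a
full run at a few minutes on one core: oracle comparisons run at 65³–129³
(0.3–2.5 Å spacing), workflow smoke tests at 33³.  The helix solvation in
the acceptance script runs the full 200 → 100 → 50 Å ladder at 65³.

## Known limitations

Only the linearized PB equation is available with membrane-potential
boundaries (the field decomposition requires linearity), and the nonlinear
equation is not implemented at all.  The membrane is flat and rigid — no
bending, no non-polar/lipid-packing terms.  Water-filled cavities must be
protected manually with the exclusion radii; there is no automatic cavity
detection.  The analytic boundary profile ignores the head-group
dielectric.  Structures are used in the orientation given: align and
center them before building maps.
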