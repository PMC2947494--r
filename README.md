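# memslab

Continuum electrostatics for membrane proteins: `memslab` builds
dielectric, ion-accessibility and charge maps from PQR structures, embeds
an implicit membrane slab (head-group layers, pore-exclusion cylinders,
transmembrane potential) in those maps, and solves the linearized
Poisson–Boltzmann equation (LPBE) on regular grids with electrostatic
focusing.  It is aimed at structural biologists and biophysicists who want
the three standard membrane-protein energy calculations without driving a
PB solver by hand:

* **Protein solvation** — the electrostatic cost of moving a protein (for
  example a charged transmembrane helix) from bulk water into the bilayer.
* **Ion solvation** — the transfer free energy of an ion from bulk water
  into a membrane-embedded channel, with optional charges-off and
  residue-subset decompositions.
* **Gating charge** — the voltage-sensor valence of a conformational
  change: the slope of the state energy difference against the applied
  membrane potential, in elementary charges.

## The model in brief

In reduced units ($\bar\phi = e\psi/k_BT$) the LPBE is

$$-\nabla\cdot(\epsilon\nabla\bar\phi) + \bar\kappa^2\bar\phi
  = \frac{e^2}{\epsilon_0 k_BT}\rho,$$

discretized with the flux-conservative 7-point stencil (harmonic-mean face
permittivities) and solved by preconditioned conjugate gradients in
compiled code.  The membrane is a dielectric slab normal to z with optional
high-dielectric head-group skins; a transmembrane potential $V$ enters
through (i) an analytic slab-profile Dirichlet boundary and (ii) a uniform
effective source density $2\,c\,N_A\,\bar\phi_{in}/10^{27}$ e/Å³ over the
inner bath.  Grids are OpenDX files; structures are whitespace-delimited
PQR.  See the vignette `vignettes/membrane-electrostatics.Rmd` for the full
account.

## Worked example

A coarse-grained 27-residue hydrophobic helix carrying a single central
arginine, inserted into a 42 Å membrane with 8 Å head-group layers:

```r
library(memslab)

helix <- build_helix()            # 27 residues, Arg14, net charge +1 e
mem   <- membrane_geometry(z_bottom = -21, thickness = 42,
                           headgroup_thickness = 8,
                           eps_membrane = 2, eps_headgroup = 80)
res <- protein_solvation(helix, mem, lengths = list(200, 100, 50),
                         counts = 65, eps_protein = 5)
res
#> Solvation energy (membrane - water): 105.07 kJ/mol  (25.1123 kcal/mol, 42.3848 kT)
```

The positive sign is the membrane insertion penalty of the charged helix;
replacing the arginine with alanine
(`build_helix(charged_residue = "ALA")`) drops it to 1.2 kcal/mol with
the same settings, showing that the penalty is dominated by the buried
charge.  A unit test charge carried across the
whole membrane gives the expected unit valence:

```r
tc  <- build_test_charge_system(-24, 24, q = 1)
gc  <- gating_charge(tc$state1, tc$state2,
                     membrane_geometry(-14, 28),
                     lengths = list(c(120, 120, 128)), counts = 65,
                     eps_protein = 2, center = c(0, 0, 1))
gc$valence_e
#> [1] 0.9934774
```

Complete runs can also be driven from configuration files
(`inst/extdata/case*.cfg`, mirroring the three standard workflow
parameter tables) through `run_workflow()` or the `exec/memslab`
command-line script (`run`, `preview`, `converge`, `fixture`
subcommands).

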