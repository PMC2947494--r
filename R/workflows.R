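#' Concatenate two structures
#'
#' Atoms of `b` are appended after those of `a` (list position remains atom
#' identity).
#' @param a,b [pqr_structure()] objects.
#' @param label label of the combined structure.
#' @return a [pqr_structure()].
#' @export
combine_structures <- function(a, b, label = "combined") {
  pqr_structure(rbind(as.data.frame(a), as.data.frame(b)), label = label)
}

#' Zero a structure's charges, optionally keeping a residue range
#'
#' Retains all atoms (the dielectric cavity is unchanged) and zeroes partial
#' charges, except those of residues in `keep_residues` which are preserved.
#'
#' @param s a [pqr_structure()].
#' @param keep_residues optional integer vector of residue numbers whose
#'   charges are kept (e.g. pore helices).
#' @return a [pqr_structure()] with modified charges.
#' @export
zero_charges <- function(s, keep_residues = NULL) {
  keep <- if (is.null(keep_residues)) rep(FALSE, nrow(s)) else
    s$residue_number %in% keep_residues
  s$charge[!keep] <- 0
  s
}

# Build the full map set of one system on one grid level.
build_level_maps <- function(structure, gs, eps_protein, eps_solvent, surf,
                             ions, consts, membrane = NULL,
                             source_structure = structure) {
  diel <- build_dielectric_map(structure, gs, eps_protein, eps_solvent, surf)
  kappa <- build_kappa_map(structure, gs, ions, consts)
  inner <- NULL
  if (!is.null(membrane)) {
    mod <- add_membrane(diel, kappa, membrane, eps_protein)
    diel <- mod$diel; kappa <- mod$kappa
    inner <- build_inner_space_mask(kappa, membrane)
  }
  charge <- spread_charges(source_structure, gs)
  list(gs = gs, diel = diel, kappa = kappa, charge = charge, inner = inner)
}

ladder_grid_specs <- function(lengths, counts, center = c(0, 0, 0)) {
  lapply(lengths, function(L) grid_spec(center, L, counts))
}

# Solve one system over a focusing ladder and return its total energy.
solve_system_energy <- function(structure, membrane, lengths, counts,
                                eps_protein, eps_solvent, ions, surf, consts,
                                bc0, tol, source_structure = structure,
                                energy_structure = source_structure,
                                center = c(0, 0, 0)) {
  specs <- ladder_grid_specs(lengths, counts, center)
  levels <- lapply(specs, function(gs)
    build_level_maps(structure, gs, eps_protein, eps_solvent, surf, ions,
                     consts, membrane, source_structure))
  sol <- solve_focus_ladder(levels, bc0 = bc0, structure = source_structure,
                            ions = ions, eps_solvent = eps_solvent,
                            consts = consts, tol = tol)
  list(energy = grid_energy(sol$field, energy_structure, consts, "total"),
       field = sol$field, log = sol$log)
}

#' Protein (helix) solvation energy in the membrane
#'
#' Transfer energy of a structure from bulk water into the membrane:
#' \eqn{\Delta G = G_{membrane} - G_{water}}, both total electrostatic
#' energies computed on the identical focusing ladder so that grid
#' self-energies cancel.
#'
#' @param structure a [pqr_structure()], z-aligned and centered externally.
#' @param membrane a [membrane_geometry()].
#' @param lengths vector of cube side lengths, coarse to fine (Angstrom).
#' @param counts nodes per axis (same at every level).
#' @param eps_protein,eps_solvent dielectric constants.
#' @param ions list of [ion_species()].
#' @param surf a [surface_spec()].
#' @param consts [physical_constants()].
#' @param bc0 far-field boundary model of the coarsest level.
#' @param tol solver tolerance.
#' @param center grid center of every ladder level (Angstrom).
#' @return an object of class `solvation_result`: `delta`
#'   ([energy_report()]), per-state energies, and solver logs.
#' @export
protein_solvation <- function(structure, membrane, lengths, counts,
                              eps_protein = 5, eps_solvent = 80,
                              ions = monovalent_salt(0.1),
                              surf = surface_spec(),
                              consts = physical_constants(), bc0 = "mdh",
                              tol = 1e-6, center = c(0, 0, 0)) {
  stopifnot(inherits(membrane, "membrane_geometry"))
  mem <- solve_system_energy(structure, membrane, lengths, counts,
                             eps_protein, eps_solvent, ions, surf, consts,
                             bc0, tol, center = center)
  wat <- solve_system_energy(structure, NULL, lengths, counts, eps_protein,
                             eps_solvent, ions, surf, consts, bc0, tol,
                             center = center)
  structure(list(
    delta = energy_report(mem$energy$kT - wat$energy$kT, consts),
    membrane_state = mem$energy, water_state = wat$energy,
    log = rbind(cbind(state = "membrane", mem$log),
                cbind(state = "water", wat$log))),
    class = "solvation_result")
}

#' @export
print.solvation_result <- function(x, ...) {
  cat("Solvation energy (membrane - water): ")
  print(x$delta)
  invisible(x)
}

#' Ion transfer free energy into a membrane-embedded protein
#'
#' \eqn{\Delta G = G(\mathrm{protein+ion, membrane}) -
#' G(\mathrm{protein, membrane}) - G(\mathrm{ion, bulk\ water})}, all three
#' systems on the identical focusing ladder (three solves per level).
#'
#' @param protein a [pqr_structure()] of the channel/protein only.
#' @param ion a [pqr_structure()] of the transferred ion (plus any fixed
#'   companion ions, e.g. selectivity-filter ions).
#' @param protein_charges_off zero the protein partial charges while keeping
#'   its dielectric cavity.
#' @param protein_keep_residues residue numbers whose charges stay on when
#'   `protein_charges_off` (e.g. pore helices 62:74).
#' @inheritParams protein_solvation
#' @return a `solvation_result` with the three state energies.
#' @export
ion_solvation <- function(protein, ion, membrane, lengths, counts,
                          eps_protein = 2, eps_solvent = 80,
                          ions = monovalent_salt(0.1),
                          surf = surface_spec(),
                          consts = physical_constants(), bc0 = "mdh",
                          tol = 1e-6, protein_charges_off = FALSE,
                          protein_keep_residues = NULL, center = c(0, 0, 0)) {
  stopifnot(inherits(membrane, "membrane_geometry"))
  prot <- if (protein_charges_off)
    zero_charges(protein, protein_keep_residues) else protein
  both <- combine_structures(prot, ion, "protein+ion")
  a <- solve_system_energy(both, membrane, lengths, counts, eps_protein,
                           eps_solvent, ions, surf, consts, bc0, tol,
                           center = center)
  b <- solve_system_energy(prot, membrane, lengths, counts, eps_protein,
                           eps_solvent, ions, surf, consts, bc0, tol,
                           center = center)
  cc <- solve_system_energy(ion, NULL, lengths, counts, eps_protein,
                            eps_solvent, ions, surf, consts, bc0, tol,
                            center = center)
  structure(list(
    delta = energy_report(a$energy$kT - b$energy$kT - cc$energy$kT, consts),
    protein_ion_state = a$energy, protein_state = b$energy,
    ion_water_state = cc$energy,
    log = rbind(cbind(state = "protein+ion", a$log),
                cbind(state = "protein", b$log),
                cbind(state = "ion/water", cc$log))),
    class = "solvation_result")
}

#' Gating charge (voltage-sensor valence) of a conformational change
#'
#' For each membrane potential `V` in a symmetric sweep, solves the
#' transmembrane-potential field \eqn{\phi_{mp}} of each state (protein
#' charges zeroed, state-specific dielectric cavity plus membrane, analytic
#' slab boundary values, inner-bath effective source) and computes the
#' interaction energy \eqn{\sum_i q_i \phi_{mp}(r_i)\,kT} of the state's
#' charges with that field.  The valence is the least-squares slope of
#' \eqn{\Delta G(V) = G_2(V) - G_1(V)} against \eqn{-eV}, in elementary
#' charges: positive valence means the 1-to-2 transition moves positive
#' charge from the inner bath (held at `V`) toward the outer bath (0 mV).
#'
#' @param state1,state2 [pqr_structure()] objects (e.g. open and closed
#'   states), aligned and centered externally.
#' @param V_max sweep endpoint in mV; the sweep has `n_sweep` equally spaced
#'   voltages from `-V_max` to `+V_max` (including 0).
#' @param n_sweep number of sweep points (odd, >= 3).
#' @inheritParams protein_solvation
#' @return an object of class `gating_result`: `valence_e`, per-voltage
#'   table `sweep` (energies in kT and kcal/mol), and the maximum
#'   linear-fit residual.
#' @export
gating_charge <- function(state1, state2, membrane, lengths, counts,
                          eps_protein = 5, eps_solvent = 80,
                          ions = monovalent_salt(0.1),
                          surf = surface_spec(),
                          consts = physical_constants(), V_max = 50,
                          n_sweep = 5, tol = 1e-6, center = c(0, 0, 0)) {
  stopifnot(inherits(membrane, "membrane_geometry"), V_max > 0,
            n_sweep >= 3, n_sweep %% 2 == 1)
  kap <- kappa_bulk(ions, eps_solvent, consts)
  if (kap <= 0)
    stop("gating-charge calculations require nonzero ionic strength")
  volts <- seq(-V_max, V_max, length.out = n_sweep)
  specs <- ladder_grid_specs(lengths, counts, center)

  state_energy <- function(s, V) {
    if (V == 0) return(list(kT = 0, log = NULL))
    slab <- slab_profile_params(V, membrane$z_bottom, membrane$z_top,
                                membrane$eps_membrane, eps_solvent, kap,
                                consts)
    uncharged <- zero_charges(s)
    levels <- lapply(specs, function(gs) {
      lm <- build_level_maps(s, gs, eps_protein, eps_solvent, surf, ions,
                             consts, membrane, source_structure = uncharged)
      lm$charge <- apply_membrane_source(lm$charge, lm$inner, V, ions, consts)
      lm
    })
    sol <- solve_focus_ladder(levels, bc0 = "membrane_potential",
                              ions = ions, eps_solvent = eps_solvent,
                              slab = slab, consts = consts, tol = tol)
    list(kT = grid_energy(sol$field, s, consts, "interaction")$kT,
         log = sol$log)
  }

  g1 <- vapply(volts, function(V) state_energy(state1, V)$kT, 0)
  g2 <- vapply(volts, function(V) state_energy(state2, V)$kT, 0)
  dg <- g2 - g1
  # dG = -Q * e*V: regress dG (kT) on the reduced potential phi_in = eV/kT
  phi_in <- volts / consts$kT_mV
  fit <- stats::lm.fit(cbind(1, phi_in), dg)
  valence <- -unname(fit$coefficients[2])
  structure(list(
    valence_e = valence,
    sweep = data.frame(V_mV = volts, G1_kT = g1, G2_kT = g2, dG_kT = dg,
                       dG_kcal_mol = dg * consts$kT_kcal_mol),
    fit_residual_kT = max(abs(fit$residuals))),
    class = "gating_result")
}

#' @export
print.gating_result <- function(x, ...) {
  cat(sprintf("Voltage-sensor valence: %+.4f e (max fit residual %.2e kT)\n",
              x$valence_e, x$fit_residual_kT))
  print(x$sweep, row.names = FALSE)
  invisible(x)
}

#' Grid-refinement convergence scan of a workflow
#'
#' Reruns a workflow configuration at a series of grid node counts, holding
#' every other parameter fixed, and reports the percent error of each energy
#' relative to the finest level.
#'
#' @param cfg a [run_config()].
#' @param node_counts integer vector of per-axis node counts (e.g.
#'   `c(33, 65, 129)`).
#' @return data frame with `nodes`, `spacing` (finest grid, Angstrom),
#'   `value` (kcal/mol for energies, e for valences) and `pct_error` versus
#'   the largest node count.
#' @export
convergence_scan <- function(cfg, node_counts) {
  stopifnot(inherits(cfg, "run_config"), length(node_counts) >= 1)
  node_counts <- sort(as.integer(node_counts))
  vals <- vapply(node_counts, function(n) {
    cfg$grid_dimensions <- rep(n, 3)
    workflow_value(run_workflow(cfg))
  }, 0)
  fine_len <- cfg$fine_grid_lengths[1]
  ref <- vals[length(vals)]
  data.frame(nodes = node_counts,
             spacing = fine_len / (node_counts - 1),
             value = vals,
             pct_error = abs(vals - ref) / abs(ref) * 100)
}

# Scalar headline value of a workflow result.
workflow_value <- function(res) {
  if (inherits(res, "gating_result")) res$valence_e else res$delta$kcal_mol
}
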