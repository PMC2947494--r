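#' Coarse-grained residue parameters for fixture helices
#'
#' Per-residue pseudo-atom table used by [build_helix()]: one neutral
#' backbone bead per residue plus (except glycine) one side-chain bead
#' carrying the residue's net formal charge, with PARSE-like radii.
#'
#' @return data frame with `residue`, `sc_charge`, `sc_radius`,
#'   `sc_offset` (radial offset of the side-chain bead from the backbone,
#'   Angstrom).
#' @export
helix_residue_table <- function() {
  data.frame(
    residue = c("LEU", "ALA", "GLY", "ARG", "LYS", "ASP", "GLU"),
    sc_charge = c(0, 0, NA, +1, +1, -1, -1),
    sc_radius = c(2.6, 2.2, NA, 2.5, 2.4, 2.4, 2.5),
    sc_offset = c(2.0, 1.5, NA, 4.0, 3.5, 2.5, 3.0))
}

#' Build an ideal transmembrane helix fixture
#'
#' Constructs a coarse-grained ideal alpha-helix aligned on z and centered at
#' the origin: per residue, one neutral backbone bead on a helix of the given
#' radius, rise and periodicity, a z-aligned pair of partial charges
#' (+/-0.35 e, 2 Angstrom apart) emulating the peptide-bond dipole of the
#' helix backbone, and a side-chain bead displaced radially outward.  All
#' residues are a neutral hydrophobic default except a single charged
#' residue, emulating a hydrophobic membrane-spanning segment carrying one
#' charge at its center.
#'
#' @param n_residues number of residues (default 27).
#' @param charged_residue residue name of the charged position (from
#'   [helix_residue_table()]); `"ALA"` or `"LEU"` give an uncharged variant.
#' @param charged_position 1-based residue index of the charged residue
#'   (default 14, the center of 27).
#' @param default_residue neutral residue used everywhere else.
#' @param rise rise per residue (Angstrom, canonical 1.5).
#' @param residues_per_turn helical periodicity (canonical 3.6).
#' @param helix_radius backbone helix radius (Angstrom).
#' @return a [pqr_structure()].
#' @export
build_helix <- function(n_residues = 27, charged_residue = "ARG",
                        charged_position = 14, default_residue = "LEU",
                        rise = 1.5, residues_per_turn = 3.6,
                        helix_radius = 2.3) {
  tab <- helix_residue_table()
  if (!charged_residue %in% tab$residue)
    stop("unknown residue: ", charged_residue)
  if (!default_residue %in% tab$residue)
    stop("unknown residue: ", default_residue)
  stopifnot(n_residues >= 1, charged_position >= 1,
            charged_position <= n_residues)
  rows <- list()
  serial <- 0L
  for (i in seq_len(n_residues)) {
    res <- if (i == charged_position) charged_residue else default_residue
    p <- tab[tab$residue == res, ]
    ang <- 2 * pi * (i - 1) / residues_per_turn
    z <- (i - (n_residues + 1) / 2) * rise
    bb <- c(helix_radius * cos(ang), helix_radius * sin(ang), z)
    serial <- serial + 1L
    rows[[length(rows) + 1]] <- data.frame(
      serial = serial, name = "BB", residue_name = res, residue_number = i,
      x = bb[1], y = bb[2], z = bb[3], charge = 0, radius = 2.3)
    # peptide-dipole pair: aligned with the axis like helix backbone C=O/N-H
    for (dp in list(c(+1, 0.35), c(-1, -0.35))) {
      serial <- serial + 1L
      rows[[length(rows) + 1]] <- data.frame(
        serial = serial, name = if (dp[2] > 0) "DP" else "DM",
        residue_name = res, residue_number = i,
        x = bb[1], y = bb[2], z = bb[3] + dp[1], charge = dp[2],
        radius = 1.5)
    }
    if (!is.na(p$sc_radius)) {
      sc_r <- helix_radius + p$sc_offset
      serial <- serial + 1L
      rows[[length(rows) + 1]] <- data.frame(
        serial = serial, name = "SC", residue_name = res, residue_number = i,
        x = sc_r * cos(ang), y = sc_r * sin(ang), z = z,
        charge = p$sc_charge, radius = p$sc_radius)
    }
  }
  pqr_structure(do.call(rbind, rows),
                label = sprintf("helix-%d-%s%d", n_residues, charged_residue,
                                charged_position))
}

#' Pair of single-charge structures for gating-valence checks
#'
#' Two one-atom structures that differ only in z: a probe charge placed
#' below and above (or part-way across) the membrane.  Used as the
#' open/closed input pair of [gating_charge()] to verify that a full
#' traversal of the transmembrane field yields unit valence.
#'
#' @param z1,z2 z positions of the charge in states 1 and 2 (Angstrom).
#' @param q charge in elementary charges.
#' @param radius atom radius (Angstrom).
#' @return list with `state1` and `state2` ([pqr_structure()]).
#' @export
build_test_charge_system <- function(z1, z2, q = 1, radius = 2) {
  mk <- function(z, lab) pqr_structure(data.frame(
    serial = 1L, name = "Q", residue_name = "ION", residue_number = 1L,
    x = 0, y = 0, z = z, charge = q, radius = radius), label = lab)
  list(state1 = mk(z1, sprintf("test-charge z=%g", z1)),
       state2 = mk(z2, sprintf("test-charge z=%g", z2)))
}

#' Single-ion structure
#'
#' @param q charge (e), `radius` in Angstrom, `pos` numeric(3) position.
#' @param name atom name.
#' @return a [pqr_structure()].
#' @export
build_ion <- function(q = 1, radius = 2, pos = c(0, 0, 0), name = "ION") {
  pqr_structure(data.frame(
    serial = 1L, name = name, residue_name = "ION", residue_number = 1L,
    x = pos[1], y = pos[2], z = pos[3], charge = q, radius = radius),
    label = name)
}
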