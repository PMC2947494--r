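# Shared fixtures and small independent oracles used across test files.

# Random structure with atoms kept inside a box of half-width `half`.
random_structure <- function(n, half = 10, max_charge = 1) {
  pqr_structure(data.frame(
    serial = seq_len(n), name = "X", residue_name = "RES",
    residue_number = seq_len(n),
    x = round(stats::runif(n, -half, half), 4),
    y = round(stats::runif(n, -half, half), 4),
    z = round(stats::runif(n, -half, half), 4),
    charge = round(stats::runif(n, -max_charge, max_charge), 4),
    radius = round(stats::runif(n, 0.5, 3), 4)), label = "random")
}

random_grid <- function(n = 5) {
  scalar_grid(array(stats::rnorm(n^3), dim = c(n, n, n)),
              origin = stats::runif(3, -5, 5),
              spacing = stats::runif(3, 0.3, 1.5))
}

# Born transfer closed form, kcal/mol: (q^2 / 2a) (1/e2 - 1/e1) * ke,
# ke = e^2/(4 pi eps0) per Angstrom in kcal/mol.
born_closed_form <- function(q = 1, a = 2, eps_from = 80, eps_to = 2) {
  pc <- physical_constants()
  ke <- pc$coupling_A * pc$kT_kcal_mol / (4 * pi)
  q^2 / (2 * a) * (1 / eps_to - 1 / eps_from) * ke
}

# Independent 1-D two-point boundary-value solve of the slab equations:
# -d/dz(eps phi') + kbar2*acc*phi = kbar2*[z < z_bot]*phi_in on [-zmax, zmax],
# phi(-zmax) = phi_in, phi(zmax) = 0.  Dense banded finite differences.
slab_bvp_oracle <- function(V, z_bot, z_top, eps_m, eps_w, conc,
                            zmax = 150, n = 4001) {
  pc <- physical_constants()
  zg <- seq(-zmax, zmax, length.out = n)
  h <- zg[2] - zg[1]
  zf <- (zg[-1] + zg[-n]) / 2
  ef <- ifelse(zf >= z_bot & zf <= z_top, eps_m, eps_w)
  acc <- ifelse(zg >= z_bot & zg <= z_top, 0, 1)
  kbar2 <- pc$coupling_A * (2 * conc * pc$avogadro / 1e27)
  phi_in <- V / pc$kT_mV
  main <- c(1, (ef[-(n - 1)] + ef[-1]) / h^2 + kbar2 * acc[2:(n - 1)], 1)
  lower <- c(-ef[-(n - 1)] / h^2, 0)
  upper <- c(0, -ef[-1] / h^2)
  A <- Matrix::bandSparse(n, n, k = -1:1,
                          diagonals = list(lower, main, upper))
  rhs <- ifelse(zg < z_bot, kbar2 * phi_in, 0)
  rhs[1] <- phi_in; rhs[n] <- 0
  sol <- as.numeric(Matrix::solve(A, rhs))
  stats::approxfun(zg, sol)
}

# Solve the Born ion (interior eps 2) in a uniform solvent on a two-level
# focusing ladder and return the total grid energy in kcal/mol.
born_grid_energy <- function(eps_solvent, counts, lengths = list(120, 40)) {
  pc <- physical_constants()
  ion <- build_ion(q = 1, radius = 2)
  levels <- lapply(lengths, function(L) {
    gs <- grid_spec(c(0, 0, 0), L, counts)
    list(gs = gs,
         diel = build_dielectric_map(ion, gs, 2, eps_solvent),
         kappa = build_kappa_map(ion, gs, list(), pc),
         charge = spread_charges(ion, gs))
  })
  sol <- solve_focus_ladder(levels, "mdh", ion, list(), eps_solvent,
                            consts = pc)
  grid_energy(sol$field, ion, pc, "total")$kcal_mol
}
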