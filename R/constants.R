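#' Physical constants for electrostatic calculations
#'
#' Bundles the CODATA constants used throughout the package together with the
#' temperature, and precomputes the derived conversion factors: the thermal
#' voltage kT/e (mV), kT in kcal/mol and kJ/mol, and the electrostatic
#' coupling constant \eqn{e^2/(\epsilon_0 k T)} expressed in Angstroms, which
#' is the factor multiplying a number density (e/A^3) on the right-hand side
#' of the reduced-potential Poisson-Boltzmann equation.
#'
#' @param temperature temperature in Kelvin (default 298.15).
#' @return an object of class `physical_constants`: a list with fields
#'   `temperature`, `k_boltzmann` (J/K), `elementary_charge` (C),
#'   `avogadro` (1/mol), `eps0` (F/m), `kT` (J), `kT_mV` (thermal voltage in
#'   mV), `kT_kcal_mol`, `kT_kJ_mol`, and `coupling_A`
#'   (\eqn{e^2/(\epsilon_0 k T)} in Angstroms).
#' @export
#' @examples
#' pc <- physical_constants()
#' pc$kT_mV     # ~25.7 mV at 298.15 K
physical_constants <- function(temperature = 298.15) {
  stopifnot(is.numeric(temperature), length(temperature) == 1, temperature > 0)
  e <- 1.602176634e-19
  kB <- 1.380649e-23
  NA_ <- 6.02214076e23
  eps0 <- 8.8541878128e-12
  kT <- kB * temperature
  structure(list(
    temperature = temperature,
    k_boltzmann = kB,
    elementary_charge = e,
    avogadro = NA_,
    eps0 = eps0,
    kT = kT,
    kT_mV = 1000 * kT / e,
    kT_kcal_mol = kT * NA_ / 4184,
    kT_kJ_mol = kT * NA_ / 1000,
    # e^2/(eps0 kT) in Angstrom: couples charge number density (e/A^3) to the
    # reduced potential.  Equals 4*pi times the vacuum Bjerrum length.
    coupling_A = e^2 / (eps0 * kT) * 1e10
  ), class = "physical_constants")
}

#' @export
print.physical_constants <- function(x, ...) {
  cat(sprintf("Physical constants at T = %.2f K\n", x$temperature))
  cat(sprintf("  kT/e = %.4f mV;  kT = %.5f kcal/mol = %.5f kJ/mol\n",
              x$kT_mV, x$kT_kcal_mol, x$kT_kJ_mol))
  cat(sprintf("  e^2/(eps0 kT) = %.2f A\n", x$coupling_A))
  invisible(x)
}

#' An ion species in the bathing electrolyte
#'
#' @param valence signed valence in elementary charges.
#' @param concentration bulk molar concentration (mol/L).
#' @param radius ionic radius in Angstroms, used to inflate atoms when
#'   carving the ion-exclusion (Stern) layer in the kappa map.
#' @return an object of class `ion_species`.
#' @export
ion_species <- function(valence, concentration, radius = 2.0) {
  stopifnot(is.finite(valence), is.finite(concentration), concentration >= 0,
            is.finite(radius), radius >= 0)
  structure(list(valence = valence, concentration = concentration,
                 radius = radius), class = "ion_species")
}

#' Standard symmetric 1:1 electrolyte
#'
#' @param concentration molar concentration of each species (mol/L).
#' @param radius ionic radius in Angstroms.
#' @return a list of two `ion_species` with valences +1 and -1.
#' @export
monovalent_salt <- function(concentration = 0.1, radius = 2.0) {
  list(ion_species(+1, concentration, radius),
       ion_species(-1, concentration, radius))
}

ionic_strength <- function(ions) {
  if (length(ions) == 0) return(0)
  sum(vapply(ions, function(i) i$concentration * i$valence^2, 0)) / 2
}

check_ions <- function(ions) {
  for (i in ions) {
    stopifnot(inherits(i, "ion_species"))
    if (i$concentration < 0) stop("ion concentration must be non-negative")
  }
  invisible(ions)
}

#' Bulk Debye screening parameter
#'
#' Computes the Debye-Hueckel screening constant
#' \eqn{\kappa^2 = e^2 \sum_i n_i z_i^2 / (\epsilon_0 \epsilon_s k T)}
#' (both mobile species counted, so \eqn{\kappa^{-1}} is the usual Debye
#' length) with number densities in ions per cubic Angstrom.
#'
#' @param ions list of [ion_species()].
#' @param eps_solvent solvent relative permittivity.
#' @param consts [physical_constants()].
#' @return `kappa` in 1/Angstrom (`1/kappa` is the Debye length).
#' @export
#' @examples
#' kappa_bulk(monovalent_salt(0.1), 80, physical_constants())  # ~0.103 1/A
kappa_bulk <- function(ions, eps_solvent, consts = physical_constants()) {
  check_ions(ions)
  if (length(ions) == 0) return(0)
  # sum n_i z_i^2 in A^-3: molar conc -> ions/A^3 via N_A / 1e27
  nz2 <- sum(vapply(ions, function(i) i$concentration * i$valence^2, 0)) *
    consts$avogadro / 1e27
  sqrt(consts$coupling_A * nz2 / eps_solvent)
}
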