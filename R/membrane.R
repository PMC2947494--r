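#' Implicit-membrane slab geometry
#'
#' The membrane is a dielectric slab normal to z, spanning
#' `[z_bottom, z_bottom + thickness]`, with optional high-dielectric
#' head-group layers of thickness `headgroup_thickness` at each face and a
#' water-filled exclusion frustum around the z-axis through (0, 0) whose
#' radius interpolates linearly from `lower_exclusion_radius` at the bottom
#' face to `upper_exclusion_radius` at the top face.
#'
#' @param z_bottom z of the membrane bottom face (Angstrom).
#' @param thickness total slab thickness including head groups (> 0).
#' @param headgroup_thickness per-leaflet head-group thickness
#'   (`2 * headgroup_thickness < thickness`).
#' @param eps_membrane core relative permittivity.
#' @param eps_headgroup head-group relative permittivity.
#' @param upper_exclusion_radius,lower_exclusion_radius exclusion-cylinder
#'   radii at the top and bottom faces (Angstrom, >= 0).
#' @return an object of class `membrane_geometry`.
#' @export
membrane_geometry <- function(z_bottom, thickness,
                              headgroup_thickness = 0,
                              eps_membrane = 2,
                              eps_headgroup = 80,
                              upper_exclusion_radius = 0,
                              lower_exclusion_radius = 0) {
  stopifnot(thickness > 0, headgroup_thickness >= 0,
            2 * headgroup_thickness < thickness,
            eps_membrane >= 1, eps_headgroup >= 1,
            upper_exclusion_radius >= 0, lower_exclusion_radius >= 0)
  structure(list(z_bottom = z_bottom, thickness = thickness,
                 headgroup_thickness = headgroup_thickness,
                 eps_membrane = eps_membrane,
                 eps_headgroup = eps_headgroup,
                 upper_exclusion_radius = upper_exclusion_radius,
                 lower_exclusion_radius = lower_exclusion_radius,
                 z_top = z_bottom + thickness),
            class = "membrane_geometry")
}

#' Exclusion-cylinder radius at a height inside the slab
#'
#' Linear interpolation between the lower radius at the bottom face and the
#' upper radius at the top face.
#'
#' @param z height (Angstrom); must lie within the slab.
#' @param geom a [membrane_geometry()].
#' @return radius in Angstroms.
#' @export
interpolate_exclusion_radius <- function(z, geom) {
  if (any(z < geom$z_bottom - 1e-9) || any(z > geom$z_top + 1e-9))
    stop("z outside the membrane slab")
  f <- (z - geom$z_bottom) / geom$thickness
  geom$lower_exclusion_radius +
    f * (geom$upper_exclusion_radius - geom$lower_exclusion_radius)
}

#' Insert the membrane slab into dielectric and kappa maps
#'
#' Iterates over grid nodes in the order: (1) protein nodes are never
#' modified; (2) non-protein nodes inside the slab's z-extent and outside the
#' exclusion frustum get the membrane (or head-group) dielectric and zero ion
#' accessibility; (3) all other nodes are untouched.  Protein nodes are
#' identified from the `protein_mask` attribute of `diel` when present
#' (required when `eps_protein` equals the membrane or head-group
#' dielectric), otherwise by exact equality with `eps_protein`.
#'
#' @param diel dielectric [scalar_grid()] from [build_dielectric_map()].
#' @param kappa accessibility [scalar_grid()] from [build_kappa_map()].
#' @param geom a [membrane_geometry()].
#' @param eps_protein the protein dielectric used to build `diel`.
#' @return list with modified grids `diel` and `kappa` (the `protein_mask`
#'   attribute is carried through).
#' @export
add_membrane <- function(diel, kappa, geom, eps_protein) {
  stopifnot(inherits(diel, "scalar_grid"), inherits(kappa, "scalar_grid"),
            inherits(geom, "membrane_geometry"))
  stop_if_not_congruent(diel, kappa)
  d <- dim(diel$values)
  zc <- axis_coords(diel, 3)
  if (geom$z_bottom > max(zc) || geom$z_top < min(zc))
    warning("membrane slab lies outside the grid z-range")
  half_w <- min((max(axis_coords(diel, 1)) - min(axis_coords(diel, 1))) / 2,
                (max(axis_coords(diel, 2)) - min(axis_coords(diel, 2))) / 2)
  if (max(geom$upper_exclusion_radius, geom$lower_exclusion_radius) > half_w)
    warning("exclusion radius exceeds the grid half-width; membrane ring may vanish")

  protein <- attr(diel, "protein_mask")
  if (is.null(protein)) protein <- diel$values == eps_protein

  in_slab_z <- zc >= geom$z_bottom - 1e-9 & zc <= geom$z_top + 1e-9
  xs <- axis_coords(diel, 1); ys <- axis_coords(diel, 2)
  r2 <- outer(xs^2, ys^2, "+")  # radial distance^2 from the z-axis

  dv <- diel$values; kv <- kappa$values
  hg <- geom$headgroup_thickness
  for (k in which(in_slab_z)) {
    z <- zc[k]
    rex <- interpolate_exclusion_radius(min(max(z, geom$z_bottom), geom$z_top),
                                        geom)
    mem_here <- !protein[, , k] & (r2 >= rex^2)
    if (!any(mem_here)) next
    in_head <- hg > 0 &&
      (z <= geom$z_bottom + hg + 1e-9 || z >= geom$z_top - hg - 1e-9)
    eps_here <- if (in_head) geom$eps_headgroup else geom$eps_membrane
    slab_d <- dv[, , k]; slab_k <- kv[, , k]
    slab_d[mem_here] <- eps_here
    slab_k[mem_here] <- 0
    dv[, , k] <- slab_d; kv[, , k] <- slab_k
  }
  diel$values <- dv
  kappa$values <- kv
  attr(diel, "protein_mask") <- protein
  list(diel = diel, kappa = kappa)
}

#' Inner-solution-space indicator mask
#'
#' Marks nodes of the inner bath: below the membrane bottom and
#' ion-accessible in the membrane-modified kappa map.  Channel-lumen water
#' inside the slab belongs to the outer space and is never marked.
#'
#' @param kappa_mem membrane-modified accessibility map from [add_membrane()].
#' @param geom a [membrane_geometry()].
#' @return a [scalar_grid()] of 0/1 indicators.
#' @export
build_inner_space_mask <- function(kappa_mem, geom) {
  stopifnot(inherits(kappa_mem, "scalar_grid"),
            inherits(geom, "membrane_geometry"))
  zc <- axis_coords(kappa_mem, 3)
  below <- zc < geom$z_bottom - 1e-9
  vals <- array(0, dim = dim(kappa_mem$values))
  vals[, , below] <- as.numeric(kappa_mem$values[, , below] != 0)
  scalar_grid(vals, kappa_mem$origin, kappa_mem$spacing)
}

#' Install the inner-bath effective source charge
#'
#' For transmembrane-potential calculations the inner bath held at potential
#' `V` acts as a uniform effective source: every inner-space node receives an
#' added number density \eqn{2 c N_A \bar\phi_{in} / 10^{27}} per cubic
#' Angstrom, where `c` is the molar concentration of one species of the
#' (assumed balanced, symmetric) electrolyte and
#' \eqn{\bar\phi_{in} = eV/kT} is the reduced inner potential.
#'
#' @param charge charge-density [scalar_grid()] (e/Angstrom^3).
#' @param mask inner-space mask from [build_inner_space_mask()].
#' @param V inner-bath potential in mV (outer bath at 0).
#' @param ions list of [ion_species()]; must have nonzero ionic strength when
#'   `V != 0`.
#' @param consts [physical_constants()].
#' @return the modified charge map.
#' @export
apply_membrane_source <- function(charge, mask, V, ions,
                                  consts = physical_constants()) {
  stopifnot(inherits(charge, "scalar_grid"), inherits(mask, "scalar_grid"))
  stop_if_not_congruent(charge, mask)
  if (V == 0) return(charge)
  check_ions(ions)
  conc <- membrane_salt_concentration(ions)
  if (conc <= 0)
    stop("membrane potential requires a nonzero electrolyte concentration")
  phi_in <- V / consts$kT_mV
  density <- 2 * conc * consts$avogadro * phi_in / 1e27  # e per A^3
  charge$values <- charge$values + density * mask$values
  charge
}

# Concentration of one species of a balanced symmetric monovalent
# electrolyte; validates the assumption.
membrane_salt_concentration <- function(ions) {
  if (length(ions) == 0) return(0)
  vs <- vapply(ions, function(i) i$valence, 0)
  cs <- vapply(ions, function(i) i$concentration, 0)
  if (sum(vs * cs) != 0)
    stop("electrolyte must be net-neutral for membrane-potential runs")
  if (any(abs(vs) != 1))
    stop("membrane-potential source assumes a symmetric monovalent electrolyte")
  mean(cs)
}
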