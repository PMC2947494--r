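#' Molecular-surface parameters
#'
#' @param solvent_probe_radius solvent probe radius in Angstroms (1.4 for
#'   water).
#' @param surface_sphere_density angular sampling density of candidate probe
#'   centers on atom spheres, points per square Angstrom.
#' @param method `"molecular"` for the two-pass probe-carved molecular
#'   surface, `"vdw_inflated"` for the faster single-pass surface in which
#'   every node within `radius + probe` of an atom is protein.
#' @return an object of class `surface_spec`.
#' @export
surface_spec <- function(solvent_probe_radius = 1.4,
                         surface_sphere_density = 10,
                         method = c("molecular", "vdw_inflated")) {
  method <- match.arg(method)
  stopifnot(solvent_probe_radius >= 0, surface_sphere_density > 0)
  structure(list(solvent_probe_radius = solvent_probe_radius,
                 surface_sphere_density = surface_sphere_density,
                 method = method), class = "surface_spec")
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  n <- max(as.integer(n), 1L)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Candidate probe centers: points on each atom's solvent-accessible sphere
# (radius r_i + probe) kept only if not buried inside any other atom's
# accessible sphere.
accessible_probe_centers <- function(s, surf) {
  probe <- surf$solvent_probe_radius
  xyz <- atom_coords(s)
  rs <- s$radius + probe
  pts_list <- lapply(seq_len(nrow(s)), function(i) {
    npts <- max(12L, ceiling(surf$surface_sphere_density * 4 * pi * rs[i]^2))
    sweep(fibonacci_sphere(npts) * rs[i], 2, xyz[i, ], "+")
  })
  pts <- do.call(rbind, pts_list)
  buried <- points_buried_cpp(pts, xyz, rs, 1e-6)
  pts[!buried, , drop = FALSE]
}

# Logical node mask of the probe-carved molecular region on grid spec `gs`.
molecular_region_mask <- function(s, gs, surf) {
  probe <- surf$solvent_probe_radius
  xyz <- atom_coords(s)
  dims <- gs$counts
  # pass 1: nodes within (r_i + probe) of any atom
  cand <- nodes_in_spheres_cpp(dims, gs$origin, gs$spacing, xyz,
                               s$radius + probe)
  if (surf$method == "vdw_inflated" || probe == 0)
    return(array(cand, dim = dims))
  # pass 2: carve back to solvent every candidate node covered by an
  # accessible probe sphere; nodes inside the bare vdW spheres stay protein.
  centers <- accessible_probe_centers(s, surf)
  carved <- nodes_in_spheres_cpp(dims, gs$origin, gs$spacing, centers,
                                 rep(probe, nrow(centers)))
  vdw <- nodes_in_spheres_cpp(dims, gs$origin, gs$spacing, xyz, s$radius)
  array(vdw | (cand & !carved), dim = dims)
}

#' Build the dielectric map of a solvated structure
#'
#' Nodes inside the probe-defined molecular region get `eps_protein`, all
#' other nodes `eps_solvent`.  The molecular region is built in two passes:
#' nodes within `radius + probe` of any atom are candidates, then candidates
#' covered by a solvent-accessible probe sphere are returned to solvent.
#' The protein-region mask is retained in the `"protein_mask"` attribute so
#' membrane insertion can identify protein nodes even when `eps_protein`
#' coincides with the membrane dielectric.
#'
#' @param s a [pqr_structure()].
#' @param gs a [grid_spec()].
#' @param eps_protein,eps_solvent relative permittivities (>= 1).
#' @param surf a [surface_spec()].
#' @return a [scalar_grid()] of permittivities with attribute
#'   `protein_mask` (logical array).
#' @export
build_dielectric_map <- function(s, gs, eps_protein, eps_solvent,
                                 surf = surface_spec()) {
  stopifnot(inherits(s, "pqr_structure"), inherits(gs, "grid_spec"),
            eps_protein >= 1, eps_solvent >= 1)
  mask <- molecular_region_mask(s, gs, surf)
  if (!any(mask))
    warning("grid does not contain any protein-region node")
  vals <- array(eps_solvent, dim = gs$counts)
  vals[mask] <- eps_protein
  g <- scalar_grid(vals, gs$origin, gs$spacing)
  attr(g, "protein_mask") <- mask
  g
}

#' Build the ion-accessibility (kappa) map
#'
#' Stores the dimensionless accessibility in `{0, 1}`: 0 at nodes within
#' `atom radius + ion radius` of any atom (the Stern exclusion layer), 1 in
#' bulk electrolyte.  The bulk screening coefficient
#' \eqn{\bar\kappa^2 = \epsilon_s \kappa^2} is applied at solve time from the
#' ionic strength and temperature, so the map itself is
#' concentration-independent.  With no ions the map is identically 0.
#'
#' @param s a [pqr_structure()].
#' @param gs a [grid_spec()].
#' @param ions list of [ion_species()]; may be empty (pure Poisson).
#' @param consts [physical_constants()].
#' @return a [scalar_grid()] of 0/1 accessibilities.
#' @export
build_kappa_map <- function(s, gs, ions, consts = physical_constants()) {
  stopifnot(inherits(s, "pqr_structure"), inherits(gs, "grid_spec"))
  check_ions(ions)
  if (length(ions) == 0 || all(vapply(ions, function(i) i$concentration, 0) == 0))
    return(scalar_grid(array(0, dim = gs$counts), gs$origin, gs$spacing))
  rion <- max(vapply(ions, function(i) i$radius, 0))
  excl <- nodes_in_spheres_cpp(gs$counts, gs$origin, gs$spacing,
                               atom_coords(s), s$radius + rion)
  vals <- array(1, dim = gs$counts)
  vals[array(excl, dim = gs$counts)] <- 0
  scalar_grid(vals, gs$origin, gs$spacing)
}

# Cubic B-spline kernel, support |t| < 2 (in node units).
bspline3 <- function(t) {
  a <- abs(t)
  ifelse(a < 1, (4 - 6 * a^2 + 3 * a^3) / 6,
         ifelse(a < 2, (2 - a)^3 / 6, 0))
}

# Per-axis node indices (1-based) and weights of the cubic B-spline stencil
# for fractional 0-based coordinate u on an axis with n nodes.
bspline_axis <- function(u, n) {
  i0 <- floor(u)
  idx <- i0 + (-1:2)
  if (idx[1] < 0 || idx[4] > n - 1) return(NULL)
  list(idx = idx + 1L, w = bspline3(u - idx))
}

#' Spread atomic charges onto a grid as a density map
#'
#' Maps each atomic point charge onto the grid with a cubic B-spline
#' kernel, which has a two-node half-support per axis, exactly
#' conserves total charge, and preserves the charge centroid.  Node values
#' are charge densities in e/Angstrom^3, so `sum(values) * prod(spacing)`
#' equals the structure's net charge.
#'
#' @param s a [pqr_structure()].
#' @param gs a [grid_spec()].
#' @return a [scalar_grid()] charge-density map.
#' @export
spread_charges <- function(s, gs) {
  stopifnot(inherits(s, "pqr_structure"), inherits(gs, "grid_spec"))
  vals <- array(0, dim = gs$counts)
  vox <- prod(gs$spacing)
  u <- grid_coords(empty_grid(gs), atom_coords(s))
  for (a in seq_len(nrow(s))) {
    if (s$charge[a] == 0) next
    wx <- bspline_axis(u[a, 1], gs$counts[1])
    wy <- bspline_axis(u[a, 2], gs$counts[2])
    wz <- bspline_axis(u[a, 3], gs$counts[3])
    if (is.null(wx) || is.null(wy) || is.null(wz))
      stop(sprintf(
        "atom %d ('%s' %s%d) is within the charge-spreading kernel support of the grid boundary",
        a, s$name[a], s$residue_name[a], s$residue_number[a]))
    w3 <- outer(outer(wx$w, wy$w), wz$w) * (s$charge[a] / vox)
    vals[wx$idx, wy$idx, wz$idx] <- vals[wx$idx, wy$idx, wz$idx] + w3
  }
  scalar_grid(vals, gs$origin, gs$spacing)
}

#' Evaluate a grid field at atom positions with the B-spline kernel
#'
#' Uses the same cubic B-spline used by [spread_charges()], so that the grid
#' self-energy of a charge cancels exactly in differences of energies
#' computed on identical grids.
#'
#' @param g a [scalar_grid()] (e.g. a reduced-potential field).
#' @param pts n x 3 matrix of positions.
#' @return numeric(n) field values.
#' @export
bspline_interp <- function(g, pts) {
  pts <- rbind(pts)
  d <- dim(g$values)
  u <- grid_coords(g, pts)
  out <- numeric(nrow(pts))
  for (a in seq_len(nrow(pts))) {
    wx <- bspline_axis(u[a, 1], d[1])
    wy <- bspline_axis(u[a, 2], d[2])
    wz <- bspline_axis(u[a, 3], d[3])
    if (is.null(wx) || is.null(wy) || is.null(wz))
      stop("evaluation point within kernel support of the grid boundary")
    out[a] <- sum(g$values[wx$idx, wy$idx, wz$idx] *
                    outer(outer(wx$w, wy$w), wz$w))
  }
  out
}
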