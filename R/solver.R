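#' Assemble the linearized Poisson-Boltzmann operator
#'
#' Builds the symmetric 7-point finite-difference operator
#' \deqn{A\phi = -\nabla\cdot(\epsilon\nabla\phi) + \bar\kappa^2 a \phi}
#' on a regular grid, with face permittivities taken as the harmonic mean of
#' the two adjacent node values and the screening term
#' \eqn{\bar\kappa^2 = e^2 \sum_i n_i z_i^2 / (\epsilon_0 k T)} (units 1/A^2)
#' applied at ion-accessible nodes (`a` is the 0/1 kappa map).  The
#' right-hand side pairing is \eqn{A\phi = (e^2/\epsilon_0 kT)\,\rho} with
#' \eqn{\rho} in e/A^3 and \eqn{\phi} the reduced potential.
#'
#' @param diel dielectric [scalar_grid()].
#' @param kappa 0/1 accessibility [scalar_grid()].
#' @param ions list of [ion_species()] (may be empty).
#' @param consts [physical_constants()].
#' @return an object of class `lpbe_operator`.
#' @export
assemble_lpbe_operator <- function(diel, kappa, ions = list(),
                                   consts = physical_constants()) {
  stopifnot(inherits(diel, "scalar_grid"), inherits(kappa, "scalar_grid"))
  stop_if_not_congruent(diel, kappa)
  check_ions(ions)
  nz2 <- if (length(ions) == 0) 0 else
    sum(vapply(ions, function(i) i$concentration * i$valence^2, 0)) *
      consts$avogadro / 1e27
  kbar2 <- consts$coupling_A * nz2  # = eps_s * kappa^2, in 1/A^2
  structure(list(
    eps = as.numeric(diel$values),
    diag = kbar2 * as.numeric(kappa$values),
    dims = dim(diel$values),
    spacing = diel$spacing,
    origin = diel$origin,
    kbar2 = kbar2), class = "lpbe_operator")
}

#' Apply the assembled operator to a grid function
#'
#' Boundary entries of `x` participate as Dirichlet couplings; the result is
#' zero on the boundary.
#'
#' @param op an [assemble_lpbe_operator()] result.
#' @param x numeric array or vector on the same grid.
#' @return numeric array `A x` (zero on the six faces).
#' @export
apply_lpbe_operator <- function(op, x) {
  stopifnot(inherits(op, "lpbe_operator"), length(x) == prod(op$dims))
  y <- lpbe_apply_cpp(op$eps, op$diag, as.numeric(x), op$dims, op$spacing)
  array(y, dim = op$dims)
}

#' Interior operator as a sparse matrix
#'
#' Materializes the operator restricted to interior nodes, mostly useful for
#' small-grid inspection and verification.
#'
#' @param op an [assemble_lpbe_operator()] result.
#' @return a symmetric `Matrix::dgCMatrix` over interior nodes, ordered
#'   x-fastest.
#' @export
lpbe_operator_matrix <- function(op) {
  d <- op$dims
  inner <- lapply(1:3, function(a) 2:(d[a] - 1))
  ni <- vapply(inner, length, 0L)
  idx3 <- as.matrix(expand.grid(ix = inner[[1]], iy = inner[[2]],
                                iz = inner[[3]]))
  full_index <- function(m) (m[, 1] - 1) + d[1] * (m[, 2] - 1) +
    d[1] * d[2] * (m[, 3] - 1) + 1
  row_of <- function(m) (m[, 1] - 2) + ni[1] * (m[, 2] - 2) +
    ni[1] * ni[2] * (m[, 3] - 2) + 1
  eps <- op$eps
  p <- full_index(idx3)
  rows <- row_of(idx3)
  i <- integer(0); j <- integer(0); v <- numeric(0)
  diag_acc <- op$diag[p]
  offs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  for (o in offs) {
    ax <- which(o != 0)
    nb3 <- sweep(idx3, 2, o, "+")
    q <- full_index(nb3)
    cf <- 2 * eps[p] * eps[q] / (eps[p] + eps[q]) / op$spacing[ax]^2
    diag_acc <- diag_acc + cf
    inb <- nb3[, 1] >= 2 & nb3[, 1] <= d[1] - 1 &
           nb3[, 2] >= 2 & nb3[, 2] <= d[2] - 1 &
           nb3[, 3] >= 2 & nb3[, 3] <= d[3] - 1
    i <- c(i, rows[inb]); j <- c(j, row_of(nb3[inb, , drop = FALSE]))
    v <- c(v, -cf[inb])
  }
  i <- c(i, rows); j <- c(j, rows); v <- c(v, diag_acc)
  Matrix::sparseMatrix(i = i, j = j, x = v, dims = rep(prod(ni), 2))
}

#' Parameters of the analytic transmembrane slab potential
#'
#' @param V inner-bath potential in mV (outer bath at 0).
#' @param z_bottom,z_top z-extent of the slab (Angstrom).
#' @param eps_membrane slab relative permittivity (head groups ignored).
#' @param eps_water solvent relative permittivity.
#' @param kappa bulk Debye screening constant (1/Angstrom, > 0 for nonzero
#'   `V`), e.g. from [kappa_bulk()].
#' @param consts [physical_constants()].
#' @return an object of class `slab_profile_params`.
#' @export
slab_profile_params <- function(V, z_bottom, z_top, eps_membrane = 2,
                                eps_water = 80, kappa,
                                consts = physical_constants()) {
  stopifnot(z_top > z_bottom, eps_membrane >= 1, eps_water >= 1, kappa >= 0)
  if (V != 0 && kappa <= 0)
    stop("membrane-potential boundary profile requires nonzero ionic strength")
  structure(list(V = V, z_bottom = z_bottom, z_top = z_top,
                 eps_membrane = eps_membrane, eps_water = eps_water,
                 kappa = kappa, phi_in = V / consts$kT_mV),
            class = "slab_profile_params")
}

#' Analytic transmembrane potential profile of a bare dielectric slab
#'
#' The reduced potential of a planar low-dielectric slab between two baths of
#' symmetric electrolyte, with the inner bath (below the slab) held at
#' reduced potential \eqn{\bar\phi_{in}} and the outer bath at 0: exponential
#' Debye decay above the slab, linear drop across it, exponential approach to
#' \eqn{\bar\phi_{in}} below, continuous at the faces with the
#' dielectric-weighted flux jump \eqn{\epsilon_w \phi'_w = \epsilon_m \phi'_m}.
#' Used as the Dirichlet boundary condition of membrane-potential solves.
#'
#' @param z heights in Angstroms (vectorized).
#' @param p a [slab_profile_params()].
#' @return reduced potential at each `z`.
#' @export
slab_profile <- function(z, p) {
  stopifnot(inherits(p, "slab_profile_params"))
  if (p$V == 0) return(rep(0, length(z)))
  L <- p$z_top - p$z_bottom
  beta <- p$eps_membrane / (p$eps_water * p$kappa)
  s <- -p$phi_in / (L + 2 * beta)   # linear slope inside the slab
  phi_top <- -s * beta
  out <- numeric(length(z))
  hi <- z > p$z_top
  lo <- z < p$z_bottom
  mid <- !hi & !lo
  out[hi] <- phi_top * exp(-p$kappa * (z[hi] - p$z_top))
  out[mid] <- phi_top + s * (z[mid] - p$z_top)
  out[lo] <- p$phi_in + s * beta * exp(p$kappa * (z[lo] - p$z_bottom))
  out
}

# Screened-Coulomb (Debye-Hueckel) reduced potential of a charged sphere.
dh_potential <- function(r, q, a, eps_solvent, kappa, consts) {
  consts$coupling_A * q * exp(-kappa * pmax(r - a, 0)) /
    (4 * pi * eps_solvent * (1 + kappa * a) * pmax(r, 1e-6))
}

#' Dirichlet boundary values for a solve
#'
#' Computes the reduced potential on the six faces of a grid for the chosen
#' boundary model: `"zero"`; `"sdh"` (single Debye-Hueckel: the whole
#' structure as one effective charged sphere); `"mdh"` (multiple
#' Debye-Hueckel: per-atom screened-Coulomb superposition); `"focus"`
#' (trilinear interpolation of a parent solution, which must strictly contain
#' this grid); `"membrane_potential"` ([slab_profile()] evaluated at each
#' boundary node's z).
#'
#' @param gs a [grid_spec()] for the grid being solved.
#' @param type boundary model (see above).
#' @param structure a [pqr_structure()], required for `"sdh"`/`"mdh"`.
#' @param ions list of [ion_species()] (screening of `"sdh"`/`"mdh"`).
#' @param eps_solvent solvent permittivity for `"sdh"`/`"mdh"`.
#' @param parent parent `potential field` ([scalar_grid()]) for `"focus"`.
#' @param slab a [slab_profile_params()] for `"membrane_potential"`.
#' @param consts [physical_constants()].
#' @return full-grid numeric array whose boundary entries hold the Dirichlet
#'   values (interior entries are 0).
#' @export
boundary_values <- function(gs, type = c("zero", "sdh", "mdh", "focus",
                                         "membrane_potential"),
                            structure = NULL, ions = list(),
                            eps_solvent = 80, parent = NULL, slab = NULL,
                            consts = physical_constants()) {
  type <- match.arg(type)
  g <- empty_grid(gs)
  bmask <- boundary_mask(gs$counts)
  vals <- array(0, dim = gs$counts)
  if (type == "zero") return(vals)
  pts <- all_node_coords(g)[as.vector(bmask), , drop = FALSE]
  if (type %in% c("sdh", "mdh")) {
    stopifnot(inherits(structure, "pqr_structure"))
    kap <- kappa_bulk(ions, eps_solvent, consts)
    if (type == "sdh") {
      ctr <- colMeans(atom_coords(structure))
      a <- max(structure$radius)
      r <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
      vals[bmask] <- dh_potential(r, net_charge(structure), a, eps_solvent,
                                  kap, consts)
    } else {
      acc <- numeric(nrow(pts))
      xyz <- atom_coords(structure)
      for (a in seq_len(nrow(structure))) {
        if (structure$charge[a] == 0) next
        r <- sqrt(rowSums(sweep(pts, 2, xyz[a, ])^2))
        acc <- acc + dh_potential(r, structure$charge[a],
                                  structure$radius[a], eps_solvent, kap,
                                  consts)
      }
      vals[bmask] <- acc
    }
  } else if (type == "focus") {
    stopifnot(inherits(parent, "scalar_grid"))
    plo <- parent$origin
    phi_ <- parent$origin + (dim(parent$values) - 1) * parent$spacing
    glo <- gs$origin
    ghi <- gs$origin + (gs$counts - 1) * gs$spacing
    if (any(glo < plo - 1e-9) || any(ghi > phi_ + 1e-9))
      stop("focus child grid is not contained in the parent grid")
    vals[bmask] <- trilinear_interp(parent, pts)
  } else {  # membrane_potential
    stopifnot(inherits(slab, "slab_profile_params"))
    vals[bmask] <- slab_profile(pts[, 3], slab)
  }
  vals
}

#' Solve the linearized Poisson-Boltzmann system
#'
#' Solves \eqn{A\phi = (e^2/\epsilon_0 kT)\rho} with Dirichlet boundary
#' values, using Jacobi-preconditioned conjugate gradients on the symmetric
#' 7-point operator.
#'
#' @param op an [assemble_lpbe_operator()] result.
#' @param charge charge-density [scalar_grid()] (e/A^3) congruent with the
#'   operator grid.
#' @param boundary full-grid array of Dirichlet values (see
#'   [boundary_values()]); only the face entries are used.
#' @param consts [physical_constants()].
#' @param tol relative-residual convergence tolerance.
#' @param maxit maximum CG iterations.
#' @return a `potential_field`: a [scalar_grid()] of reduced potential
#'   \eqn{\phi = e\psi/kT} with attributes `iterations` and `relres`.
#' @export
solve_lpbe <- function(op, charge, boundary = NULL,
                       consts = physical_constants(), tol = 1e-6,
                       maxit = 20000L) {
  stopifnot(inherits(op, "lpbe_operator"), inherits(charge, "scalar_grid"))
  if (!identical(dim(charge$values), op$dims))
    stop("charge map is not congruent with the operator grid")
  stopifnot(tol > 0, tol < 1)
  if (is.null(boundary)) boundary <- array(0, dim = op$dims)
  rhs <- consts$coupling_A * as.numeric(charge$values)
  res <- lpbe_cg_cpp(op$eps, op$diag, rhs, as.numeric(boundary), op$dims,
                     op$spacing, tol, as.integer(maxit))
  if (!res$converged)
    stop(sprintf("PB solve did not converge in %d iterations (relres %.3e)",
                 res$iterations, res$relres))
  field <- scalar_grid(array(res$phi, dim = op$dims), op$origin, op$spacing)
  attr(field, "iterations") <- res$iterations
  attr(field, "relres") <- res$relres
  class(field) <- c("potential_field", class(field))
  field
}

#' Convert a reduced-potential field to millivolts
#' @param field a `potential_field` (reduced units).
#' @param consts [physical_constants()].
#' @return a [scalar_grid()] in mV.
#' @export
potential_mV <- function(field, consts = physical_constants()) {
  scalar_grid(field$values * consts$kT_mV, field$origin, field$spacing)
}

#' Electrostatic energy of charges in a potential field
#'
#' Total (self) energy \eqn{\tfrac12\sum_i q_i\phi(r_i)\,kT} when the charges
#' sourced the field, or interaction energy \eqn{\sum_i q_i\phi(r_i)\,kT}
#' when the field is foreign to the charges (the gating-charge workflow).
#' Atom-site potentials are evaluated with the same cubic B-spline kernel
#' used for charge spreading, so grid self-energies cancel exactly in
#' differences taken on identical grids.
#'
#' @param field a `potential_field` (reduced potential).
#' @param charges a [pqr_structure()], or a charge-density [scalar_grid()]
#'   congruent with the field.
#' @param consts [physical_constants()].
#' @param mode `"total"` (factor 1/2) or `"interaction"` (factor 1).
#' @return an `energy_report`: list with `kT`, `kcal_mol`, `kJ_mol`.
#' @export
grid_energy <- function(field, charges, consts = physical_constants(),
                        mode = c("total", "interaction")) {
  mode <- match.arg(mode)
  half <- if (mode == "total") 0.5 else 1
  if (inherits(charges, "pqr_structure")) {
    qs <- charges$charge
    keep <- qs != 0
    e_kT <- if (!any(keep)) 0 else
      half * sum(qs[keep] *
                 bspline_interp(field, atom_coords(charges)[keep, , drop = FALSE]))
  } else if (inherits(charges, "scalar_grid")) {
    stop_if_not_congruent(field, charges)
    e_kT <- half * sum(charges$values * field$values) * prod(field$spacing)
  } else stop("charges must be a pqr_structure or a scalar_grid")
  energy_report(e_kT, consts)
}

#' Build an energy report in kT, kcal/mol and kJ/mol
#' @param e_kT energy in units of kT.
#' @param consts [physical_constants()].
#' @return an object of class `energy_report`.
#' @export
energy_report <- function(e_kT, consts = physical_constants()) {
  structure(list(kT = e_kT,
                 kcal_mol = e_kT * consts$kT_kcal_mol,
                 kJ_mol = e_kT * consts$kT_kJ_mol),
            class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf("%.6g kJ/mol  (%.6g kcal/mol, %.6g kT)\n",
              x$kJ_mol, x$kcal_mol, x$kT))
  invisible(x)
}

#' Solve a focusing ladder
#'
#' Solves a sequence of grids from coarsest to finest; the first level uses
#' the requested far-field boundary model and each subsequent level takes its
#' Dirichlet values from the previous solution by trilinear interpolation.
#' Each level carries its own maps (dielectric, kappa, charge) built on that
#' level's grid.
#'
#' @param levels list (coarse to fine) of lists with elements `gs`
#'   ([grid_spec()]), `diel`, `kappa`, `charge` (scalar grids on `gs`).
#' @param bc0 boundary model of the coarsest level: `"zero"`, `"sdh"`,
#'   `"mdh"` or `"membrane_potential"`.
#' @param structure structure for `"sdh"`/`"mdh"` boundaries.
#' @param ions list of [ion_species()].
#' @param eps_solvent solvent permittivity (boundary models).
#' @param slab [slab_profile_params()] for `"membrane_potential"`.
#' @param consts [physical_constants()].
#' @param tol,maxit passed to [solve_lpbe()].
#' @return list with `field` (finest-level `potential_field`) and `log`
#'   (data frame of per-level grid size, spacing, iterations, residual).
#' @export
solve_focus_ladder <- function(levels, bc0 = "mdh", structure = NULL,
                               ions = list(), eps_solvent = 80, slab = NULL,
                               consts = physical_constants(), tol = 1e-6,
                               maxit = 20000L) {
  stopifnot(length(levels) >= 1)
  field <- NULL
  log <- list()
  for (k in seq_along(levels)) {
    lv <- levels[[k]]
    bc <- if (k == 1)
      boundary_values(lv$gs, bc0, structure = structure, ions = ions,
                      eps_solvent = eps_solvent, slab = slab,
                      consts = consts)
    else
      boundary_values(lv$gs, "focus", parent = field, consts = consts)
    op <- assemble_lpbe_operator(lv$diel, lv$kappa, ions, consts)
    field <- solve_lpbe(op, lv$charge, bc, consts, tol, maxit)
    log[[k]] <- data.frame(level = k, nodes = lv$gs$counts[1],
                           spacing = lv$gs$spacing[1],
                           iterations = attr(field, "iterations"),
                           relres = attr(field, "relres"))
  }
  list(field = field, log = do.call(rbind, log))
}
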