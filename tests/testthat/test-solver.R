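test_that("discrete Laplacian annihilates linear fields in a uniform medium", {
  gs <- grid_spec(c(0, 0, 0), 10, 9)
  diel <- empty_grid(gs, 80)
  kap <- empty_grid(gs, 0)
  op <- assemble_lpbe_operator(diel, kap, list())
  g <- empty_grid(gs)
  zc <- axis_coords(g, 3)
  for (k in seq_along(zc)) g$values[, , k] <- 3 * zc[k] + 1
  y <- apply_lpbe_operator(op, g$values)
  expect_equal(max(abs(y[2:8, 2:8, 2:8])), 0, tolerance = 1e-10)
})

test_that("the operator is symmetric for heterogeneous dielectrics", {
  set.seed(3)
  gs <- grid_spec(c(0, 0, 0), 6, 7)
  diel <- empty_grid(gs)
  diel$values[] <- runif(length(diel$values), 2, 80)
  kap <- empty_grid(gs)
  kap$values[] <- rbinom(length(kap$values), 1, 0.5)
  op <- assemble_lpbe_operator(diel, kap, monovalent_salt(0.1))
  inner <- !boundary_mask(gs$counts)
  for (i in 1:5) {
    u <- array(0, gs$counts); v <- array(0, gs$counts)
    u[inner] <- rnorm(sum(inner)); v[inner] <- rnorm(sum(inner))
    Au <- apply_lpbe_operator(op, u)
    Av <- apply_lpbe_operator(op, v)
    expect_equal(sum(Au * v), sum(u * Av), tolerance = 1e-10)
  }
})

test_that("stencil assembly agrees with brute-force flux-balance assembly", {
  set.seed(5)
  gs <- grid_spec(c(1, -2, 0.5), c(4, 5, 6), 5)
  diel <- empty_grid(gs)
  diel$values[] <- runif(length(diel$values), 1, 100)
  kap <- empty_grid(gs)
  kap$values[] <- rbinom(length(kap$values), 1, 0.5)
  ions <- monovalent_salt(0.2)
  op <- assemble_lpbe_operator(diel, kap, ions)
  A <- as.matrix(lpbe_operator_matrix(op))
  # oracle: dense assembly from the flux-balance formula, one row per
  # interior node, harmonic-mean face permittivities
  pc <- physical_constants()
  kbar2 <- pc$coupling_A * 2 * 0.2 * pc$avogadro / 1e27
  d <- gs$counts; h <- gs$spacing
  inner <- as.matrix(expand.grid(i = 2:(d[1] - 1), j = 2:(d[2] - 1),
                                 k = 2:(d[3] - 1)))
  nI <- nrow(inner)
  row_id <- function(i, j, k) (i - 2) + (d[1] - 2) * (j - 2) +
    (d[1] - 2) * (d[2] - 2) * (k - 2) + 1
  B <- matrix(0, nI, nI)
  for (r in seq_len(nI)) {
    i <- inner[r, 1]; j <- inner[r, 2]; k <- inner[r, 3]
    e0 <- diel$values[i, j, k]
    diag_acc <- kbar2 * kap$values[i, j, k]
    for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      ax <- which(o != 0)
      nb <- c(i, j, k) + o
      en <- diel$values[nb[1], nb[2], nb[3]]
      cf <- 2 * e0 * en / (e0 + en) / h[ax]^2
      diag_acc <- diag_acc + cf
      if (all(nb >= 2 & nb <= d - 1))
        B[r, row_id(nb[1], nb[2], nb[3])] <- -cf
    }
    B[r, r] <- diag_acc
  }
  expect_equal(A, B, tolerance = 1e-12)
  expect_equal(A, t(A), tolerance = 1e-12)
})

test_that("slab profile has the stated asymptotics and midpoint", {
  pc <- physical_constants()
  kap <- kappa_bulk(monovalent_salt(0.1), 80, pc)
  p <- slab_profile_params(-50, -14, 14, 2, 80, kap, pc)
  expect_equal(slab_profile(500, p), 0, tolerance = 1e-12)
  expect_equal(slab_profile(-500, p), p$phi_in, tolerance = 1e-9)
  expect_equal(slab_profile(0, p), p$phi_in / 2)  # symmetric slab: V/2
  # continuity at both faces
  eps <- 1e-9
  expect_equal(slab_profile(14 - eps, p), slab_profile(14 + eps, p),
               tolerance = 1e-6)
  expect_equal(slab_profile(-14 - eps, p), slab_profile(-14 + eps, p),
               tolerance = 1e-6)
  # dielectric-weighted flux jump at the top face
  d <- 1e-5
  grad_w <- (slab_profile(14 + 2 * d, p) - slab_profile(14 + d, p)) / d
  grad_m <- (slab_profile(14 - d, p) - slab_profile(14 - 2 * d, p)) / d
  expect_equal(80 * grad_w, 2 * grad_m, tolerance = 1e-3)
  expect_error(slab_profile_params(-50, -14, 14, 2, 80, 0),
               "ionic strength")
})

test_that("slab profile matches an independent 1-D boundary-value solve", {
  pc <- physical_constants()
  kap <- kappa_bulk(monovalent_salt(0.1), 80, pc)
  p <- slab_profile_params(-50, -14, 14, 2, 80, kap, pc)
  oracle <- slab_bvp_oracle(-50, -14, 14, 2, 80, 0.1)
  zs <- seq(-38, 38, length.out = 20)
  expect_equal(slab_profile(zs, p), oracle(zs),
               tolerance = 1e-3)  # < 0.1% of the profile scale
})

test_that("boundary models behave at their degenerate points", {
  gs <- grid_spec(c(0, 0, 0), 40, 17)
  ion <- build_ion(q = 1, radius = 2)
  ions <- monovalent_salt(0.1)
  # multiple-DH for one atom equals single-DH
  expect_equal(boundary_values(gs, "mdh", structure = ion, ions = ions),
               boundary_values(gs, "sdh", structure = ion, ions = ions))
  # membrane-potential faces approach the two bath values
  pc <- physical_constants()
  p <- slab_profile_params(-50, -5, 5, 2, 80,
                           kappa_bulk(ions, 80, pc), pc)
  bv <- boundary_values(gs, "membrane_potential", slab = p)
  expect_equal(bv[9, 9, 17], 0, tolerance = abs(p$phi_in) * 0.25)
  expect_equal(bv[9, 9, 1], p$phi_in, tolerance = abs(p$phi_in) * 0.25)
  expect_true(abs(bv[9, 9, 1] - p$phi_in) < abs(bv[9, 9, 17]))
})

test_that("focus boundaries reproduce parent values at coincident nodes", {
  set.seed(9)
  parent <- scalar_grid(array(rnorm(17^3), dim = c(17, 17, 17)),
                        origin = c(-8, -8, -8), spacing = c(1, 1, 1))
  gs <- grid_spec(c(0, 0, 0), 8, 9)  # child nodes coincide with parent nodes
  bv <- boundary_values(gs, "focus", parent = parent)
  expect_equal(bv[1, 5, 5], parent$values[5, 9, 9], tolerance = 1e-12)
  expect_equal(bv[9, 9, 9], parent$values[13, 13, 13], tolerance = 1e-12)
  # a child that pokes outside the parent is refused
  gs_big <- grid_spec(c(0, 0, 0), 40, 9)
  expect_error(boundary_values(gs_big, "focus", parent = parent),
               "not contained")
})

test_that("zero source with zero boundaries yields the zero field", {
  gs <- grid_spec(c(0, 0, 0), 10, 9)
  op <- assemble_lpbe_operator(empty_grid(gs, 80), empty_grid(gs, 0), list())
  f <- solve_lpbe(op, empty_grid(gs, 0))
  expect_true(all(f$values == 0))
})

test_that("solutions obey the discrete maximum principle", {
  set.seed(13)
  gs <- grid_spec(c(0, 0, 0), 10, 11)
  diel <- empty_grid(gs)
  diel$values[] <- runif(length(diel$values), 2, 80)
  op <- assemble_lpbe_operator(diel, empty_grid(gs, 0), list())
  bv <- array(0, gs$counts)
  bm <- boundary_mask(gs$counts)
  bv[bm] <- runif(sum(bm), -1, 2)
  f <- solve_lpbe(op, empty_grid(gs, 0), bv, tol = 1e-8)
  expect_gte(min(f$values), min(bv[bm]) - 1e-6)
  expect_lte(max(f$values), max(bv[bm]) + 1e-6)
})

test_that("the linear solver is linear: superposition and charge scaling", {
  pc <- physical_constants()
  ions <- monovalent_salt(0.1)
  gs <- grid_spec(c(0, 0, 0), 40, 33)
  a1 <- build_ion(q = 1, pos = c(-5, 0, 0))
  a2 <- build_ion(q = -0.5, pos = c(6, 2, 0))
  both <- combine_structures(a1, a2)
  solve_one <- function(s) {
    diel <- empty_grid(gs, 80)
    kap <- build_kappa_map(s, gs, ions, pc)
    op <- assemble_lpbe_operator(diel, kap, ions, pc)
    bc <- boundary_values(gs, "mdh", structure = s, ions = ions, consts = pc)
    solve_lpbe(op, spread_charges(s, gs), bc, pc, tol = 1e-8)
  }
  # superposition on a shared kappa geometry: use the combined exclusion map
  kap_both <- build_kappa_map(both, gs, ions, pc)
  op <- assemble_lpbe_operator(empty_grid(gs, 80), kap_both, ions, pc)
  f1 <- solve_lpbe(op, spread_charges(a1, gs),
                   boundary_values(gs, "mdh", structure = a1, ions = ions),
                   pc, tol = 1e-8)
  f2 <- solve_lpbe(op, spread_charges(a2, gs),
                   boundary_values(gs, "mdh", structure = a2, ions = ions),
                   pc, tol = 1e-8)
  f12 <- solve_lpbe(op, spread_charges(both, gs),
                    boundary_values(gs, "mdh", structure = both, ions = ions),
                    pc, tol = 1e-8)
  expect_equal(f12$values, f1$values + f2$values,
               tolerance = 1e-5)
  # total self-energy scales as alpha^2
  e1 <- grid_energy(solve_one(a1), a1, pc, "total")$kT
  a1x2 <- a1; a1x2$charge <- 2 * a1$charge
  e2 <- grid_energy(solve_one(a1x2), a1x2, pc, "total")$kT
  expect_equal(e2 / e1, 4, tolerance = 1e-4)
})

test_that("energy reports keep the unit triple consistent", {
  pc <- physical_constants()
  r <- energy_report(1 / pc$kT_kcal_mol, pc)  # exactly 1 kcal/mol
  expect_equal(r$kcal_mol, 1)
  expect_equal(r$kJ_mol, 4.184)
  r0 <- energy_report(0, pc)
  expect_identical(c(r0$kT, r0$kcal_mol, r0$kJ_mol), c(0, 0, 0))
})

test_that("a one-level ladder is a direct solve and focusing is consistent", {
  pc <- physical_constants()
  ion <- build_ion(q = 1, radius = 2)
  mk_level <- function(L, n) {
    gs <- grid_spec(c(0, 0, 0), L, n)
    list(gs = gs, diel = empty_grid(gs, 80),
         kappa = build_kappa_map(ion, gs, list(), pc),
         charge = spread_charges(ion, gs))
  }
  one <- solve_focus_ladder(list(mk_level(40, 33)), "mdh", ion, list(), 80,
                            consts = pc)
  gs <- grid_spec(c(0, 0, 0), 40, 33)
  op <- assemble_lpbe_operator(empty_grid(gs, 80),
                               build_kappa_map(ion, gs, list(), pc),
                               list(), pc)
  direct <- solve_lpbe(op, spread_charges(ion, gs),
                       boundary_values(gs, "mdh", structure = ion,
                                       ions = list(), consts = pc), pc)
  expect_equal(one$field$values, direct$values, tolerance = 1e-12)
  # 2-level focused energy within 1% of the single fine-grid solve
  two <- solve_focus_ladder(list(mk_level(120, 33), mk_level(40, 33)),
                            "mdh", ion, list(), 80, consts = pc)
  e_focus <- grid_energy(two$field, ion, pc)$kcal_mol
  e_direct <- grid_energy(direct, ion, pc)$kcal_mol
  expect_equal(e_focus, e_direct, tolerance = 0.01)
})

test_that("non-congruent maps and bad charges are refused", {
  gs <- grid_spec(c(0, 0, 0), 10, 9)
  gs2 <- grid_spec(c(0, 0, 0), 10, 11)
  expect_error(assemble_lpbe_operator(empty_grid(gs, 80),
                                      empty_grid(gs2, 0), list()),
               "congruent")
  op <- assemble_lpbe_operator(empty_grid(gs, 80), empty_grid(gs, 0), list())
  expect_error(solve_lpbe(op, empty_grid(gs2, 0)), "congruent")
  f <- solve_lpbe(op, empty_grid(gs, 0))
  far <- build_ion(q = 1, pos = c(50, 0, 0))
  expect_error(grid_energy(f, far), "boundary")
})
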