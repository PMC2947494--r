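helix_maps <- function(counts = 33, len = 60, eps_p = 5,
                       ions = monovalent_salt(0.1)) {
  s <- build_helix()
  gs <- grid_spec(c(0, 0, 0), len, counts)
  list(s = s, gs = gs,
       diel = build_dielectric_map(s, gs, eps_p, 80),
       kappa = build_kappa_map(s, gs, ions))
}

test_that("membrane rewrite follows the protein/slab/exclusion order", {
  m <- helix_maps()
  geom <- membrane_geometry(z_bottom = -21, thickness = 42,
                            headgroup_thickness = 8, eps_membrane = 2,
                            eps_headgroup = 80)
  mod <- add_membrane(m$diel, m$kappa, geom, 5)
  idx <- function(p) {
    u <- round((p - m$gs$origin) / m$gs$spacing) + 1
    cbind(u[1], u[2], u[3])
  }
  # far from the axis at slab mid-plane: membrane core
  p <- c(-26.25, 0, 0)
  expect_equal(mod$diel$values[idx(p)], 2)
  expect_equal(mod$kappa$values[idx(p)], 0)
  # inside the protein at the slab mid-plane: untouched
  expect_equal(mod$diel$values[idx(c(0, 0, 0))], 5)
  # 4 A below the top slab face, outside protein: head group, ions excluded
  p <- c(-26.25, 0, 16.875)
  expect_equal(mod$diel$values[idx(p)], 80)
  expect_equal(mod$kappa$values[idx(p)], 0)
  # above the slab: still bulk water
  p <- c(-26.25, 0, 24.375)
  expect_equal(mod$diel$values[idx(p)], 80)
  expect_equal(mod$kappa$values[idx(p)], 1)
})

test_that("the exclusion cylinder keeps the pore clear of membrane", {
  ion <- build_ion(q = 0, radius = 2, pos = c(25, 25, 0))  # protein off-axis
  gs <- grid_spec(c(0, 0, 0), 120, 33)
  diel <- build_dielectric_map(ion, gs, 2, 80)
  kappa <- build_kappa_map(ion, gs, monovalent_salt(0.1))
  geom <- membrane_geometry(-12, 24, eps_membrane = 2,
                            upper_exclusion_radius = 24,
                            lower_exclusion_radius = 24)
  mod <- add_membrane(diel, kappa, geom, 2)
  # on the cylinder axis inside the slab: remains water
  expect_equal(mod$diel$values[17, 17, 17], 80)
  expect_equal(mod$kappa$values[17, 17, 17], 1)
  # outside the exclusion radius inside the slab: membrane
  expect_equal(mod$diel$values[29, 17, 17], 2)  # x = 45 A
})

test_that("exclusion radius interpolates linearly across the slab", {
  geom <- membrane_geometry(-12, 24, upper_exclusion_radius = 24,
                            lower_exclusion_radius = 16)
  expect_equal(interpolate_exclusion_radius(-12, geom), 16)
  expect_equal(interpolate_exclusion_radius(12, geom), 24)
  expect_equal(interpolate_exclusion_radius(0, geom), 20)
  expect_error(interpolate_exclusion_radius(13, geom), "outside")
})

test_that("membrane insertion is idempotent and preserves the protein", {
  m <- helix_maps()
  geom <- membrane_geometry(-21, 42, headgroup_thickness = 8)
  once <- add_membrane(m$diel, m$kappa, geom, 5)
  twice <- add_membrane(once$diel, once$kappa, geom, 5)
  expect_equal(twice$diel$values, once$diel$values)
  expect_equal(twice$kappa$values, once$kappa$values)
  expect_identical(which(once$diel$values == 5), which(m$diel$values == 5))
})

test_that("protein detection survives eps_protein equal to eps_membrane", {
  m <- helix_maps(eps_p = 2)
  geom <- membrane_geometry(-12, 24, eps_membrane = 2)
  mod <- add_membrane(m$diel, m$kappa, geom, 2)
  protein_before <- attr(m$diel, "protein_mask")
  # repeated insertion with the retained mask leaves protein nodes intact
  again <- add_membrane(mod$diel, mod$kappa, geom, 2)
  expect_equal(again$diel$values, mod$diel$values)
  expect_true(all(mod$diel$values[protein_before] == 2))
  # and solvent nodes inside the slab became membrane (kappa = 0)
  zc <- axis_coords(mod$kappa, 3)
  slab <- zc > -12 & zc < 12
  expect_true(all(mod$kappa$values[, , slab][!protein_before[, , slab]] %in% 0))
})

test_that("inner space is the ion-accessible bath below the membrane", {
  m <- helix_maps()
  geom <- membrane_geometry(-21, 42, headgroup_thickness = 8)
  mod <- add_membrane(m$diel, m$kappa, geom, 5)
  mask <- build_inner_space_mask(mod$kappa, geom)
  idx <- function(p) {
    u <- round((p - m$gs$origin) / m$gs$spacing) + 1
    cbind(u[1], u[2], u[3])
  }
  expect_equal(mask$values[idx(c(-20, 10, -26.25))], 1)  # bulk below slab
  expect_equal(mask$values[idx(c(-26.25, 0, 0))], 0)     # inside the slab
  expect_equal(mask$values[idx(c(20, -10, 26.25))], 0)   # above the slab
  # theta = 1 implies kappa != 0 and z below the membrane bottom
  on <- which(mask$values == 1, arr.ind = TRUE)
  expect_true(all(mod$kappa$values[on] != 0))
  expect_true(all(axis_coords(mask, 3)[on[, 3]] < geom$z_bottom))
})

test_that("lumen water inside the slab belongs to the outer space", {
  ion <- build_ion(q = 0, radius = 2, pos = c(25, 25, 0))
  gs <- grid_spec(c(0, 0, 0), 120, 33)
  geom <- membrane_geometry(-12, 24, upper_exclusion_radius = 24,
                            lower_exclusion_radius = 24)
  mod <- add_membrane(build_dielectric_map(ion, gs, 2, 80),
                      build_kappa_map(ion, gs, monovalent_salt(0.1)),
                      geom, 2)
  mask <- build_inner_space_mask(mod$kappa, geom)
  expect_equal(mask$values[17, 17, 17], 0)  # lumen water at slab mid-height
})

test_that("membrane source density matches the closed form and is odd in V", {
  gs <- grid_spec(c(0, 0, 0), 40, 17)
  mask <- empty_grid(gs, 0)
  mask$values[, , axis_coords(mask, 3) < -10] <- 1
  chg0 <- empty_grid(gs, 0)
  ions <- monovalent_salt(0.1)
  pc <- physical_constants()
  # V = 0: identity
  expect_identical(apply_membrane_source(chg0, mask, 0, ions)$values,
                   chg0$values)
  cm <- apply_membrane_source(chg0, mask, -50, ions, pc)
  # closed form: 2 c N_A phi_in / 1e27 per A^3 at inner nodes
  phi_in <- -50 * 1.602176634e-19 / (1.380649e-23 * 298.15) / 1000
  expected <- 2 * 0.1 * 6.02214076e23 * phi_in / 1e27
  inner <- mask$values == 1
  expect_equal(unique(cm$values[inner]), expected, tolerance = 1e-12)
  expect_true(all(cm$values[!inner] == 0))
  # flipping V flips every added density
  cp <- apply_membrane_source(chg0, mask, +50, ions, pc)
  expect_equal(cp$values, -cm$values)
  # V != 0 without electrolyte is refused
  expect_error(apply_membrane_source(chg0, mask, -50, list()), "electrolyte")
})

test_that("membrane insertion never touches the charge bookkeeping", {
  m <- helix_maps()
  chg <- spread_charges(m$s, m$gs)
  geom <- membrane_geometry(-21, 42)
  add_membrane(m$diel, m$kappa, geom, 5)  # charge map not an argument
  expect_equal(sum(chg$values) * prod(m$gs$spacing), net_charge(m$s),
               tolerance = 1e-10)
})

test_that("geometry warnings fire for out-of-grid slabs and oversized radii", {
  m <- helix_maps(counts = 17, len = 30)
  expect_warning(add_membrane(m$diel, m$kappa,
                              membrane_geometry(100, 20), 5), "z-range")
  expect_warning(add_membrane(m$diel, m$kappa,
                              membrane_geometry(-10, 20,
                                                upper_exclusion_radius = 28,
                                                lower_exclusion_radius = 28),
                              5), "half-width")
})
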