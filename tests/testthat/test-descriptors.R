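test_that("radius of gyration matches closed forms", {
  m1 <- molecule("C", no_bonds)
  expect_equal(radius_of_gyration(conformer(matrix(c(1, 2, 3), 1)), m1), 0)

  # two equal masses 2 A apart, unit weighting: 1.0
  m2 <- molecule(c("C", "C"), data.frame(i = 1, j = 2, order = 1L))
  c2 <- conformer(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(radius_of_gyration(c2, m2, "unit"), 1.0)

  # square of 4 equal masses, side 2: sqrt(2)
  m4 <- molecule(rep("C", 4),
                 data.frame(i = c(1, 2, 3, 4), j = c(2, 3, 4, 1), order = 1L))
  c4 <- conformer(rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0)))
  expect_equal(radius_of_gyration(c4, m4, "unit"), sqrt(2))

  # C-H pair: two-body closed form L * sqrt(m1 m2) / (m1 + m2)
  mch <- molecule(c("C", "H"), data.frame(i = 1, j = 2, order = 1L))
  cch <- conformer(rbind(c(0, 0, 0), c(1.09, 0, 0)))
  expected <- 1.09 * sqrt(12.011 * 1.008) / (12.011 + 1.008)
  expect_equal(radius_of_gyration(cch, mch, "mass"), expected,
               tolerance = 1e-12)
})

test_that("rgyr is rigid-motion invariant and scales linearly", {
  w <- mk_methanol()
  r0 <- radius_of_gyration(w$conf, w$mol)
  R <- rotation_matrix(c(1, 2, 3), 0.9)
  moved <- conformer(w$conf$coords %*% t(R) +
                       matrix(c(5, -2, 1), nrow(w$conf$coords), 3,
                              byrow = TRUE))
  expect_equal(radius_of_gyration(moved, w$mol), r0, tolerance = 1e-12)
  scaled <- conformer(w$conf$coords * 2.5)
  expect_equal(radius_of_gyration(scaled, w$mol), 2.5 * r0,
               tolerance = 1e-12)
})

test_that("psa_3d: isolated sphere, empty set, and analytic two-sphere cap", {
  mO <- molecule("O", no_bonds)
  cO <- conformer(matrix(0, 1, 3))
  expect_equal(psa_3d(cO, 1L, mO), 4 * pi * 1.52^2, tolerance = 1e-6)

  meth <- mk_methane()
  expect_identical(psa_3d(meth$conf, assign_psa_atoms(meth$mol), meth$mol), 0)

  # N sphere (1.55) cut by a C sphere (1.70) at 1.4 A: spherical-cap oracle
  mNC <- molecule(c("N", "C", "H"),
                  data.frame(i = c(1, 1), j = c(2, 3), order = 1L))
  d <- 1.4; Rn <- 1.55; Rc <- 1.70
  cNC <- conformer(rbind(c(0, 0, 0), c(d, 0, 0), c(-1.01, 0, 0)))
  cosa <- (d^2 + Rn^2 - Rc^2) / (2 * d * Rn)
  oracle_n <- 2 * pi * Rn^2 * (1 + cosa)
  # H inside both spheres adds its exposed cap too; restrict to atom 1
  got <- psa_3d(cNC, 1L, mNC, points_per_atom = 4096L)
  # the H sphere hides a little of N as well: use a H-free variant
  mNC2 <- molecule(c("N", "C"), data.frame(i = 1, j = 2, order = 1L),
                   check_connected = FALSE)
  got2 <- psa_3d(conformer(rbind(c(0, 0, 0), c(d, 0, 0))), 1L, mNC2,
                 points_per_atom = 4096L)
  expect_lt(abs(got2 - oracle_n) / oracle_n, 0.01)
  expect_lte(got, got2)
})

test_that("psa_3d is rotation invariant and bounded by the bare-sphere sum", {
  met <- mk_methanol()
  pa <- assign_psa_atoms(met$mol)
  p0 <- psa_3d(met$conf, pa, met$mol)
  R <- rotation_matrix(c(1, 0, 2), 1.3)
  p1 <- psa_3d(conformer(met$conf$coords %*% t(R) + 3), pa, met$mol)
  expect_lt(abs(p1 - p0) / p0, 0.01)   # sampling tolerance only
  bound <- sum(4 * pi * (c(1.52, 1.20))^2)  # O + H bare spheres
  expect_lt(p0, bound)
})

test_that("psa_3d decreases monotonically as a nonpolar neighbour closes in", {
  mNC <- molecule(c("N", "C"), data.frame(i = 1, j = 2, order = 1L),
                  check_connected = FALSE)
  vals <- vapply(seq(3.5, 1.0, by = -0.5), function(d)
    psa_3d(conformer(rbind(c(0, 0, 0), c(d, 0, 0))), 1L, mNC), numeric(1))
  expect_true(all(diff(vals) <= 1e-9))
})

test_that("psa_3d converges: doubling the lattice changes fixtures < 1%", {
  for (fx in list(mk_methanol(), mk_water())) {
    pa <- assign_psa_atoms(fx$mol)
    a <- psa_3d(fx$conf, pa, fx$mol, points_per_atom = 1024L)
    b <- psa_3d(fx$conf, pa, fx$mol, points_per_atom = 2048L)
    expect_lt(abs(a - b) / b, 0.01)
  }
})

test_that("tpsa reproduces fragment sums and cross-check reference values", {
  expect_equal(tpsa(mk_benzene()$mol), 0)
  expect_equal(tpsa(mk_methanol()$mol), 20.23)   # single hydroxyl fragment
  # reference values computed with an independent implementation (RDKit)
  expect_equal(tpsa(example_molecule("pomalidomide")), 109.57, tolerance = 1e-6)
  expect_equal(tpsa(example_molecule("saquinavir")), 166.75, tolerance = 1e-6)
  expect_equal(tpsa(example_molecule("cmp98_synthetic")), 250.95,
               tolerance = 1e-6)
  # NOSP mode adds the two aromatic thiazole sulfurs (28.24 each)
  expect_equal(tpsa(example_molecule("cmp98_synthetic"), "NOSP"),
               250.95 + 2 * 28.24, tolerance = 1e-6)
})

test_that("tpsa warns and falls back on unparameterized environments", {
  # divalent neutral N with no hydrogens has no tabulated environment
  weird <- molecule(c("N", "C", "C", "H", "H", "H", "H", "H", "H"),
                    data.frame(i = c(1, 1, 2, 2, 2, 3, 3, 3),
                               j = c(2, 3, 4, 5, 6, 7, 8, 9),
                               order = 1L))
  expect_warning(v <- tpsa(weird), "unparameterized")
  expect_gt(v, 0)
})

test_that("vdw_volume: single sphere, additivity, and lens-overlap oracle", {
  mC <- molecule("C", no_bonds)
  v1 <- vdw_volume(conformer(matrix(0, 1, 3)), mC, grid_step = 0.15)
  expect_lt(abs(v1 - 4 / 3 * pi * 1.70^3) / (4 / 3 * pi * 1.70^3), 0.02)

  m2 <- molecule(c("C", "C"), data.frame(i = 1, j = 2, order = 1L),
                 check_connected = FALSE)
  far <- vdw_volume(conformer(rbind(c(0, 0, 0), c(8, 0, 0))), m2,
                    grid_step = 0.15)
  expect_lt(abs(far - 2 * 4 / 3 * pi * 1.70^3) / far, 0.02)

  d <- 1.5; R <- 1.70
  lens <- pi * (2 * R - d)^2 * (d^2 + 4 * d * R) / (12 * d)
  expected <- 2 * 4 / 3 * pi * R^3 - lens
  near <- vdw_volume(conformer(rbind(c(0, 0, 0), c(d, 0, 0))), m2,
                     grid_step = 0.15)
  expect_lt(abs(near - expected) / expected, 0.02)
})

test_that("superposition RMSD: identity, rigid invariance, Horn oracle", {
  met <- mk_methanol()
  expect_equal(superpose_rmsd(met$conf, met$conf), 0, tolerance = 1e-8)

  R <- rotation_matrix(c(0.3, -1, 0.5), 2.2)
  moved <- conformer(met$conf$coords %*% t(R) +
                       matrix(c(-4, 2, 7), nrow(met$conf$coords), 3,
                              byrow = TRUE))
  expect_lt(superpose_rmsd(met$conf, moved), 1e-6)

  set.seed(31)
  for (rep in 1:5) {
    A <- matrix(rnorm(24), ncol = 3)
    B <- A %*% t(rotation_matrix(rnorm(3), runif(1, 0, pi))) +
      matrix(rnorm(24, sd = 0.3), ncol = 3)
    got <- superpose_rmsd(conformer(A), conformer(B))
    expect_equal(got, horn_rmsd(A, B), tolerance = 1e-3)
  }
})

test_that("superpose_rmsd enforces matching topology and nonempty subsets", {
  a <- conformer(matrix(rnorm(9), 3))
  b <- conformer(matrix(rnorm(12), 4))
  expect_error(superpose_rmsd(a, b), "topology mismatch")
  expect_error(superpose_rmsd(a, conformer(matrix(rnorm(9), 3)),
                              subset = integer()), "nonempty")
})
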