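test_that("flat periodic sheet has the stated area and zero bending energy", {
  m <- build_flat_mesh(700, 20)
  expect_equal(m$area_nm2, 490000, tolerance = 1e-3)
  expect_equal(bending_energy(m), 0, tolerance = 1e-8)
  # refinement quadruples vertices (roughly) and preserves the area
  m2 <- build_flat_mesh(700, 10)
  expect_gt(nrow(m2$vertices) / nrow(m$vertices), 3.4)
  expect_equal(m2$area_nm2, 490000, tolerance = 1e-6)
})

test_that("discrete Helfrich sphere converges to 8 pi kappa", {
  e3 <- bending_energy(build_sphere_mesh(40, 3), bending_params(20))
  e4 <- bending_energy(build_sphere_mesh(40, 4), bending_params(20))
  ref <- 8 * pi * 20
  expect_lt(abs(e3 / ref - 1), 0.02)
  expect_lt(abs(e4 / ref - 1), abs(e3 / ref - 1))  # monotone improvement
  # kappa linearity and radius independence
  e3b <- bending_energy(build_sphere_mesh(80, 3), bending_params(40))
  expect_equal(e3b, 2 * e3, tolerance = 1e-6)
})

test_that("small-slope bump matches the analytic plate-limit energy", {
  # Gaussian bump h0 exp(-r^2 / 2 s^2): E -> pi kappa h0^2 / s^2
  m <- build_flat_mesh(700, 10)
  h0 <- 8; s <- 60
  r2 <- (m$vertices[, 1] - 350)^2 + (m$vertices[, 2] - 350)^2
  m$vertices[, 3] <- h0 * exp(-r2 / (2 * s^2))
  expect_equal(bending_energy(m, bending_params(20)), pi * 20 * h0^2 / s^2,
               tolerance = 0.01)
})

test_that("bending energy is invariant under rigid motions", {
  m <- build_sphere_mesh(40, 2)
  e0 <- bending_energy(m)
  q <- clathrid:::quat_from_axis_angle(c(1, -1, 2), 1.1)
  m$vertices <- t(clathrid:::quat_rotate(q, t(m$vertices))) +
    matrix(c(13, -7, 22), nrow(m$vertices), 3, byrow = TRUE)
  expect_equal(bending_energy(m), e0, tolerance = 1e-9)
  expect_gt(e0, 0)
})

test_that("cage construction follows the chord geometry of the pucker", {
  c96 <- generate_cage(12, 96)
  c98 <- generate_cage(12, 98)
  expect_equal(c96$R_nm, 17 / (2 * sin(6 * pi / 180)))
  expect_gt(c96$R_nm, c98$R_nm)       # softer curvature -> larger sphere
  # virtual sites sit 9 nm from each trimer COM
  d <- sqrt(rowSums((c96$com - c96$vsite)^2))
  expect_equal(d, rep(9, 12), tolerance = 1e-9)
  # flat limit: infinite radius, sites 9 nm below the COM plane
  cf <- generate_cage(7, 90)
  expect_equal(cf$R_nm, Inf)
  expect_equal(unique(cf$com[, 3] - cf$vsite[, 3]), 9)
  expect_error(generate_cage(2, 98), "at least 3")
})

test_that("zero-stiffness schedule leaves the sheet flat", {
  mesh <- build_flat_mesh(350, 20)
  cage <- generate_cage(8, 98, center_xy = c(175, 175))
  cage$k_start_kcal <- 1e-12
  cage$k_stop_kcal <- 1e-11
  fit <- minimize_coupled(mesh, cage, optimize_pose = FALSE)
  expect_lt(fit$energy_kBT, 1e-4)
  expect_lt(max(abs(fit$mesh$vertices[, 3])), 0.1)
})

test_that("minimized bending energy scales with the bending modulus", {
  # shallow cage in the mesh-converged regime: at the final spring stiffness
  # the geometry is constraint-dominated, so energy is proportional to kappa
  cage <- generate_cage(8, 96, center_xy = c(175, 175))
  f1 <- minimize_coupled(build_flat_mesh(350, 14), cage, bending_params(20))
  f2 <- minimize_coupled(build_flat_mesh(350, 14), cage, bending_params(40))
  expect_true(f1$converged && f2$converged)
  expect_equal(f2$energy_kBT / f1$energy_kBT, 2, tolerance = 0.05)
})
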