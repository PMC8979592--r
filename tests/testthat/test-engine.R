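test_that("3D binding probability behaves like the radiation-boundary pair", {
  expect_equal(p_bind_3d(10, ka = 0, D = 26, sigma_nm = 5, dt_us = 3), 0)
  # out of diffusional reach
  expect_lt(p_bind_3d(200, ka = 10, D = 26, sigma_nm = 5, dt_us = 3), 1e-12)
  # monotone decreasing in separation
  p <- p_bind_3d(c(5, 6, 8, 12, 20), 1, 26, 5, 3)
  expect_true(all(diff(p) < 0))
  # uniform-partner integral reproduces the macroscopic rate: the
  # independent oracle is deterministic quadrature, not the propagator
  f <- function(r) p_bind_3d(r, 1, 26, 5, 3) * 4 * pi * r^2
  k_int <- stats::integrate(f, 5, 150)$value / 3 / (1e3 / 602.214076)
  expect_equal(k_int, kon_macroscopic(1, 5, 26), tolerance = 0.01)
})

test_that("2D scheme integrates to the 2D rate and respects the annulus", {
  expect_equal(p_bind_2d(5.5, ka_2D = 0, sigma_nm = 5, dt_us = 3), 0)
  expect_equal(p_bind_2d(7, 0.003, 5, 3), 0)        # outside the annulus
  p <- p_bind_2d(5.5, 0.003, 5, 3, delta_nm = 1)
  a_ann <- pi * (6^2 - 5^2)
  expect_equal(p, 1 - exp(-0.003 * 3 / a_ann))
  # rate density integrates back to ka_2D over the annulus
  expect_equal(-log(1 - p) / 3 * a_ann, 0.003, tolerance = 1e-12)
})

test_that("ring closure is gated by the contact cutoff and strain", {
  p <- model_params()
  r0 <- ring_closure_probability(p, 5.6)
  expect_false(r0$eligible)             # beyond the 5.5 nm cutoff
  r1 <- ring_closure_probability(p, 5.2)
  expect_true(r1$eligible)
  # closure probability carries exp(-dG_strain): strain 6.9 weakens closed
  # polygons ~1e3-fold relative to an ideal bond
  p0 <- model_params(dG_strain = 0)
  r_ideal <- ring_closure_probability(p0, 5.2)
  expect_equal(r_ideal$probability / r1$probability, exp(6.9),
               tolerance = 1e-9)
  expect_equal(round(exp(6.9) / 1e3, 1), 1)
  # realized rebind/unbind ratios
  kb_us <- 0.083 * 120 * 1e-6
  expect_equal(r_ideal$probability / (kb_us * 3), 1e6 / 120,
               tolerance = 1e-9)
  # cooperativity: use a smaller step so the probability is not clamped at 1
  p0f <- model_params(dG_strain = 0, dt = 1)
  r_coop <- ring_closure_probability(p0f, 5.2, adaptor_bound = TRUE)
  expect_equal(r_coop$probability / (kb_us * 1), (1e6 / 120) * exp(2.4),
               tolerance = 1e-9)
})

test_that("trajectories are reproducible for a fixed seed", {
  sc <- make_bimolecular_scenario("3D", ka = 5, KD = 50, A_copies = 40,
                                  B_copies = 40, box_um = rep(0.15, 3),
                                  sigma_nm = 2, D_A = 20, D_B = 20)
  t1 <- run_simulation(sc, 0.01, seed = 99, output_every_s = 1e-3)
  t2 <- run_simulation(sc, 0.01, seed = 99, output_every_s = 1e-3)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$final$pos, t2$final$pos)
  t3 <- run_simulation(sc, 0.01, seed = 100, output_every_s = 1e-3)
  expect_false(identical(t1$frames$n_bonds, t3$frames$n_bonds))
})

test_that("closed systems conserve copies; empty systems only advance time", {
  sc <- make_bimolecular_scenario("3D", ka = 5, KD = 50, A_copies = 30,
                                  B_copies = 25, box_um = rep(0.15, 3),
                                  sigma_nm = 2, D_A = 20, D_B = 20)
  tr <- run_simulation(sc, 0.03, seed = 4, output_every_s = 1e-3)
  totA <- tr$frames$sol_clathrin + tr$frames$mem_clathrin  # species A (type 0)
  totB <- tr$frames$sol_adaptor + tr$frames$mem_adaptor    # species B (type 1)
  expect_true(all(totA == 30))
  expect_true(all(totB == 25))
  # empty scenario: nothing but the clock moves
  sc0 <- make_bimolecular_scenario("3D", A_copies = 0, B_copies = 0,
                                   box_um = rep(0.15, 3))
  tr0 <- run_simulation(sc0, 0.001, seed = 1, output_every_s = 1e-4)
  expect_true(all(tr0$frames$sol_clathrin == 0))
  expect_gt(max(tr0$frames$time_s), 0.00095)  # clock advanced to the end
})

test_that("excluded volume holds over a full assembly trajectory", {
  sc <- make_physiologic_scenario(ap_conc = 3, area_um2 = 0.04,
                                  height_um = 0.25, CLA_conc = 3)
  tr <- run_simulation(sc, 0.2, seed = 8, output_every_s = 0.01)
  pos <- tr$final$pos
  ty <- tr$final$type
  cmp <- tr$final$comp
  cla <- which(ty == 0)
  L <- sqrt(0.04) * 1e3
  viol <- 0
  for (i in seq_along(cla)) {
    for (j in seq_along(cla)) {
      if (j <= i) next
      a <- cla[i]; b <- cla[j]
      d <- pos[, a] - pos[, b]
      d[1:2] <- d[1:2] - L * round(d[1:2] / L)
      # directly bonded partners sit at 17 nm; any pair closer than 10 nm
      # violates the trimer COM exclusion
      if (sqrt(sum(d^2)) < 10 - 1e-6) viol <- viol + 1
    }
  }
  expect_equal(viol, 0)
  # copies conserved in the closed physiologic system
  tot <- tr$frames$sol_clathrin + tr$frames$mem_clathrin
  expect_true(all(tot == tot[1]))
})

test_that("reservoir maintains the target solution copy number", {
  sc <- make_invitro_scenario(rho_AP = 0, area_um2 = 0.09, height_um = 0.5,
                              CLA_bulk = 0.4) |> suppressWarnings()
  # kdestroy sets the relaxation time; use a fast reservoir so the window
  # after 0.4 s is stationary
  tr <- run_simulation(sc, 1.2, seed = 12, output_every_s = 0.005,
                       kdestroy_s = 10)
  target <- sc$reservoir_target
  x <- tr$frames$sol_clathrin[tr$frames$time_s > 0.4]
  expect_lt(abs(mean(x) - target) / target, 0.15)
  expect_gt(stats::sd(x), 0.3 * sqrt(target))  # Poisson-like fluctuations
  # target 0: no creation ever
  sc0 <- suppressWarnings(make_invitro_scenario(rho_AP = 0,
                                                area_um2 = 0.09,
                                                height_um = 0.5,
                                                CLA_bulk = 0))
  tr0 <- run_simulation(sc0, 0.02, seed = 12, output_every_s = 0.01)
  expect_true(all(tr0$frames$sol_clathrin == 0))
})

test_that("trajectory CSV round-trips and records provenance", {
  sc <- make_bimolecular_scenario("3D", A_copies = 10, B_copies = 10,
                                  box_um = rep(0.15, 3))
  tr <- run_simulation(sc, 0.003, seed = 2, output_every_s = 1e-3)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, tf)
  back <- read_trajectory_csv(tf)
  expect_equal(back$frames$n_bonds, tr$frames$n_bonds)
  expect_true(any(grepl("seed: 2", back$meta)))
  expect_true(any(grepl("dG_strain=6.9", back$meta)))
})
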