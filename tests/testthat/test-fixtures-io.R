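test_that("fixture equilibria come from the closed quadratic solution", {
  # 48 + 48 copies at K_D = 120 uM in 1 um^3
  sc <- make_bimolecular_scenario("3D", ka = 0.083, KD = 120, A_copies = 48,
                                  B_copies = 48, box_um = c(1, 1, 1))
  eq <- fixture_equilibrium(sc)
  Kc <- 120 * 602.214076
  s <- 96 + Kc
  expect_equal(eq$bound_copies, (s - sqrt(s^2 - 4 * 48 * 48)) / 2)
  expect_lt(eq$bound_fraction_A, 0.01)   # weak binding at 80 nM
  # 2D: area constant K_D * h
  sc2 <- make_bimolecular_scenario("2D", ka = 0.083, KD = 120, h_nm = 30,
                                   A_copies = 100, B_copies = 100,
                                   box_um = c(1, 1, 0.1))
  eq2 <- fixture_equilibrium(sc2)
  expect_equal(eq2$KD_copies, 120 * 602.214076 * 0.03)  # ~2.2e3 per um^2
  # dimensional reduction: at matched copies and rates the 2D system is
  # more bound whenever DF = V/(A h) > 1
  sc3 <- make_bimolecular_scenario("3D", ka = 0.083, KD = 120,
                                   A_copies = 100, B_copies = 100,
                                   box_um = c(1, 1, 1))
  expect_gt(fixture_equilibrium(sc2)$bound_fraction_A,
            fixture_equilibrium(sc3)$bound_fraction_A)
  # langmuir monotonicity: doubling sites increases binding
  l1 <- fixture_equilibrium(make_bimolecular_scenario("langmuir", KD = 2,
                                                      A_copies = 100,
                                                      n_sites = 200))
  l2 <- fixture_equilibrium(make_bimolecular_scenario("langmuir", KD = 2,
                                                      A_copies = 100,
                                                      n_sites = 400))
  expect_gt(l2$bound_fraction_A, l1$bound_fraction_A)
})

test_that("generate_fixture bundles inputs with their references", {
  g <- generate_fixture("growth_curve", b = 10, tau = 13, k = 1 / 121,
                        E = 5000)
  expect_equal(unname(g$reference["tau"]), 13)
  f <- glance(fit_lag_exponential(g$input))
  expect_equal(f$tau, 13, tolerance = 1e-5)
  l <- generate_fixture("landscape_curve", seed = 5)
  expect_equal(l$reference$n1, 25)
  b <- generate_fixture("bimolecular_3d", KD = 120, A_copies = 48,
                        B_copies = 48, box_um = c(1, 1, 1))
  expect_true(is.numeric(b$reference$bound_copies))
  expect_error(generate_fixture("nope"), "arg")
})

test_that("geometry exports produce well-formed XYZ, PDB and OFF files", {
  tpl <- build_clathrin_template(90)
  cx <- snap_on_binding(new_complex(tpl), 1, 1,
                        new_complex(tpl, c(40, 0, 0)), 1, 1, sigma = 5)
  xf <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(cx, xf)
  lines <- readLines(xf)
  expect_equal(as.integer(lines[1]), 12 + 2)      # 12 sites + 2 COMs
  expect_equal(length(lines), 12 + 2 + 2)
  pf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(cx, pf)
  pl <- readLines(pf)
  expect_true(all(grepl("^ATOM|^END", pl)))
  mf <- withr::local_tempfile(fileext = ".off")
  write_mesh_off(build_flat_mesh(300, 30), mf)
  ml <- readLines(mf)
  expect_equal(ml[1], "OFF")
})

test_that("the command-line interface evaluates the closed-form model", {
  tf <- withr::local_tempfile(fileext = ".json")
  status <- run_cli(c("theory", "--preset", "invitro", "--out", tf))
  expect_equal(status, 0L)
  out <- jsonlite::fromJSON(tf)
  expect_equal(out$tau, 12.5, tolerance = 0.01)
  expect_equal(run_cli(c("frobnicate")), 2L)
  expect_equal(run_cli(character()), 1L)
})

test_that("cli simulate writes a reproducible trajectory", {
  tf1 <- withr::local_tempfile(fileext = ".csv")
  tf2 <- withr::local_tempfile(fileext = ".csv")
  suppressMessages({
    run_cli(c("simulate", "--preset", "physiologic", "--ap-conc", "0.2",
              "--seed", "7", "--t-end", "0.002", "--out", tf1))
    run_cli(c("simulate", "--preset", "physiologic", "--ap-conc", "0.2",
              "--seed", "7", "--t-end", "0.002", "--out", tf2))
  })
  expect_identical(readLines(tf1), readLines(tf2))
})
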