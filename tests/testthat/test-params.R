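test_that("derived energies and cooperativity factor match the fixed K_Ds", {
  p <- model_params()
  expect_equal(p$dG_CC_free, -log(1e6 / 120))          # ~ -9.03 k_B T
  expect_equal(p$dG_CC_coop, p$dG_CC_free - 2.4)
  expect_equal(p$f_coop, exp(2.4))
})

test_that("reaction table keeps off-rates fixed and accelerates on-rates", {
  rx <- derive_rates(model_params())
  cc <- rx[rx$reaction == "CC", ]
  ccx <- rx[rx$reaction == "CC_coop", ]
  expect_equal(ccx$ka_3D, exp(2.4) * 0.083, tolerance = 1e-12)
  expect_equal(ccx$kb, cc$kb)                    # off-rate unchanged
  # k_b / k_a equals the configured K_D to machine precision
  expect_equal(cc$kb / cc$ka_3D, 120, tolerance = 1e-12)
  ac <- rx[rx$reaction == "AC", ]
  expect_equal(ac$kb / ac$ka_3D, 25, tolerance = 1e-12)
  # 2D rates: ka_2D = ka_3D / h for every clathrin channel, kb unchanged,
  # hence K_D,2D = K_D,3D * h
  expect_equal(cc$ka_2D, cc$ka_3D / 30)
  expect_equal(cc$kb / cc$ka_2D, 120 * 30)
  # zero cooperativity collapses the variants
  rx0 <- derive_rates(model_params(dG_coop = 0))
  expect_equal(rx0$ka_3D[rx0$reaction == "CC"],
               rx0$ka_3D[rx0$reaction == "CC_coop"])
})

test_that("macroscopic rate combines reaction and diffusion resistances", {
  # diffusion limit
  expect_equal(kon_macroscopic(1e12, 5, 26),
               4 * pi * 5 * 26 / (1e3 / 602.214076), tolerance = 1e-3)
  # clathrin-clathrin is strongly reaction-limited: k_on ~ k_a within 0.01%
  expect_equal(kon_macroscopic(0.083, 5, 26), 0.083, tolerance = 1e-4)
  # equal resistances halve the rate
  kD_uM <- 4 * pi * 5 * 26 / (1e3 / 602.214076)
  expect_equal(kon_macroscopic(kD_uM, 5, 26), kD_uM / 2, tolerance = 1e-12)
})

test_that("in vitro scenario encodes density, reservoir and geometry", {
  sc <- make_invitro_scenario(0.009)
  expect_equal(sc$n_implicit_sites, 9000)        # 0.009 nm^-2 over 1 um^2
  expect_equal(sc$reservoir_target, 0.08 * 602.214076)  # ~48 copies at 80 nM
  expect_equal(sc$V_um3, 1)
  expect_warning(make_invitro_scenario(0.0005), "bounds")
  sc0 <- suppressWarnings(make_invitro_scenario(0))
  expect_equal(sc0$n_implicit_sites, 0)          # control: no recruitment
})

test_that("physiologic scenario fixes copies from concentrations", {
  sc <- make_physiologic_scenario(0.6)
  expect_equal(sc$CLA_copies, round(0.65 * 0.49 * 602.214076))  # ~192
  expect_false(sc$reservoir)
  expect_false(sc$solution_AC_binding)
  expect_equal(sc$lipid_sites_per_um2, 2e4)
  # maximal surface density if all adaptors localize
  expect_equal(concentration_geometry("max_surface_density", conc_uM = 0.6,
                                      height_um = 1), 361, tolerance = 0.01)
  # copies -> concentration -> copies round-trips
  conc <- sc$CLA_copies / (sc$V_um3 * 602.214076)
  expect_equal(round(conc * sc$V_um3 * 602.214076), sc$CLA_copies)
})

test_that("solution scenario removes the membrane and can stabilize cages", {
  sc <- make_solution_scenario(0.2, alpha = 98, dG_bonus = 2,
                               strain_reduction = 2.3)
  expect_equal(sc$n_implicit_sites, 0)
  expect_true(sc$solution_AC_binding)
  expect_equal(sc$params$dG_strain, 6.9 - 2.3)
  expect_equal(sc$dG_bonus, 2)
  expect_warning(make_solution_scenario(0.2, alpha = 92), "96 or 98")
})

test_that("scenario and template JSON round-trips preserve the model", {
  tf <- withr::local_tempfile(fileext = ".json")
  tpl <- build_clathrin_template(98)
  write_template_json(tpl, tf)
  tpl2 <- read_template_json(tf)
  expect_equal(tpl2$interfaces$x, tpl$interfaces$x)
  expect_equal(tpl2$D_trans, tpl$D_trans)
  sf <- withr::local_tempfile(fileext = ".json")
  sc <- make_invitro_scenario(0.009)
  write_scenario_json(sc, sf)
  sc2 <- read_scenario_json(sf)
  expect_equal(sc2$n_implicit_sites, sc$n_implicit_sites)
  expect_equal(sc2$params$dG_strain, sc$params$dG_strain)
})
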