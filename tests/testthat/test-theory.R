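test_that("dimensionality factor covers the in vitro / physiologic regimes", {
  expect_equal(dimensionality_factor(30e-3, 1, 30), 1)   # V = A h
  expect_equal(dimensionality_factor(991, 1, 30), 991 / 0.03)  # ~3.3e4
  expect_equal(dimensionality_factor(1, 1, 30), 1 / 0.03, tolerance = 1e-12)
  expect_error(dimensionality_factor(-1, 1, 30), "positive")
})

test_that("lag time reproduces the term-by-term arithmetic at the optimum", {
  tau <- lag_time(theory_inputs(), theory_coefficients())
  expect_equal(tau$t_localization, 3.2 / (9000 * 0.0012 * 0.08),
               tolerance = 1e-12)                        # ~3.70 s
  nuc <- 1 / (exp(2.4) * 0.083 * 0.08 * (991 / 0.03)^(1 / 8.2) *
              exp(-6.9 / 8.3))
  expect_equal(tau$t_nucleation, nuc, tolerance = 1e-12) # ~8.8 s
  expect_equal(tau$tau, 3.70 + 8.82, tolerance = 0.01)   # ~12.5 s total
  # limits: infinite adaptor density removes the localization term
  tau_inf <- lag_time(theory_inputs(rho_AP = 1e9))
  expect_lt(tau_inf$t_localization, 1e-6)
  tau0 <- lag_time(theory_inputs(rho_AP = 0))
  expect_true(tau0$infinite_lag)
})

test_that("steepness is adaptor-dominated at the in vitro optimum", {
  ke <- growth_steepness(theory_inputs(), theory_coefficients())
  expect_equal(ke$kE_adaptor,
               0.0012 * 9000 * 0.08 * (991 / 0.03)^(1 / 3.2),
               tolerance = 1e-12)                        # ~22 copies/um^2/s
  expect_gt(ke$kE_adaptor, 20)
  expect_lt(ke$kE_clathrin, 1e-5)                        # ~4e-6 (fit units)
  expect_equal(growth_steepness(theory_inputs(CLA_bulk = 0))$kE, 0)
})

test_that("lag and steepness respond with the documented signs", {
  base <- theory_inputs()
  up <- function(...) theory_inputs(...)
  expect_lt(lag_time(up(rho_AP = 0.012))$tau, lag_time(base)$tau)
  expect_lt(lag_time(up(k_AP_CLA = 0.002))$tau, lag_time(base)$tau)
  expect_lt(lag_time(up(CLA_bulk = 0.2))$tau, lag_time(base)$tau)
  expect_lt(lag_time(up(dG_coop = -3))$tau, lag_time(base)$tau)
  # strain slows nucleation but accelerates growth (opposite signs)
  expect_gt(lag_time(up(dG_strain = 9))$tau, lag_time(base)$tau)
  expect_gt(growth_steepness(up(dG_strain = 9))$kE_clathrin,
            growth_steepness(base)$kE_clathrin)
  expect_gt(growth_steepness(up(rho_AP = 0.012))$kE,
            growth_steepness(base)$kE)
})

test_that("rebinding ratios match the strained-loop energetics", {
  expect_equal(rebinding_ratio(120), 1e6 / 120, tolerance = 1e-12)   # 8.3e3
  expect_equal(rebinding_ratio(120, adaptor_bound = TRUE),
               (1e6 / 120) * exp(2.4), tolerance = 1e-12)            # 9.2e4
  expect_equal(signif(rebinding_ratio(120), 2), 8.3e3)
  expect_equal(signif(rebinding_ratio(120, TRUE), 2), 9.2e4)
  # strain exactly canceling the bond free energy gives ratio 1
  expect_equal(rebinding_ratio(120, dG_strain = log(1e6 / 120)), 1,
               tolerance = 1e-12)
  # ratio * exp(dG_strain) is strain-independent
  r1 <- rebinding_ratio(120, dG_strain = 2) * exp(2)
  r2 <- rebinding_ratio(120, dG_strain = 5) * exp(5)
  expect_equal(r1, r2)
})

test_that("effective bond count reflects the strain penalty", {
  expect_equal(effective_bond_count(-11.4, 6.9), (6 * 11.4 - 6.9) / 11.4)
  expect_equal(round(effective_bond_count(-11.4, 6.9), 1), 5.4)
  expect_equal(effective_bond_count(-11.4, 0), 6)
  expect_equal(effective_bond_count(-9.03, 6.9), (6 * 9.03 - 6.9) / 9.03,
               tolerance = 1e-12)                                    # ~5.24
  expect_error(effective_bond_count(3, 6.9), "negative")
})

test_that("concentration/geometry conversions match the worked numbers", {
  expect_equal(concentration_geometry("copies_in_volume", conc_uM = 0.08,
                                      volume_um3 = 1), 48.18, tolerance = 1e-3)
  expect_equal(concentration_geometry("va_ratio", volume_uL = 200,
                                      area_um2 = 2.017e8), 991.6,
               tolerance = 1e-3)
  expect_equal(concentration_geometry("langmuir_surface_density",
                                      sites_per_nm2 = 0.0746, conc_uM = 0.2,
                                      KD_uM = 1), 0.0746 * 0.2 / 1.2, tolerance = 1e-9)
  expect_error(concentration_geometry("va_ratio", volume_uL = -1,
                                      area_um2 = 1), "non-negative")
})

test_that("coefficient fitting is an exact fixed point on clean data", {
  set.seed(3)
  grid <- tidyr::expand_grid(
    rho_AP = c(0.003, 0.009), k_AP_CLA = c(0.0012, 0.003),
    k_CLA_CLA = 0.083, dG_coop = c(-1.2, -2.4), dG_strain = c(3, 6.9),
    h = 30, V = 991, A = 1, CLA_bulk = c(0.08, 0.2))
  truth <- theory_coefficients()
  obs <- purrr::pmap_dfr(grid, function(...) {
    inp <- theory_inputs(...)
    tibble::tibble(tau_obs = lag_time(inp, truth)$tau,
                   kE_obs = growth_steepness(inp, truth)$kE)
  })
  fit <- fit_coefficients(dplyr::bind_cols(grid, obs), start = truth)
  expect_equal(fit$coefficients$lag_loc, 3.2, tolerance = 1e-4)
  expect_equal(fit$coefficients$lag_DF_exp, 8.2, tolerance = 1e-3)
  expect_equal(fit$coefficients$kE_pref, 0.0012, tolerance = 1e-4)
  expect_equal(max(abs(log(fit$residuals$tau_pred / fit$residuals$tau_obs))),
               0, tolerance = 1e-6)
})

test_that("prefactor is recovered within 25% under 10% lognormal noise", {
  set.seed(11)
  grid <- tidyr::expand_grid(
    rho_AP = c(0.0014, 0.005, 0.012), k_AP_CLA = c(0.0008, 0.0024),
    k_CLA_CLA = 0.083, dG_coop = c(-1.1, -3), dG_strain = c(3, 6.9),
    h = c(10, 30), V = 991, A = 1, CLA_bulk = 0.08)
  grid <- grid[seq_len(30), ]
  truth <- theory_coefficients()
  recov <- vapply(1:20, function(rep) {
    obs <- purrr::pmap_dfr(grid, function(...) {
      inp <- theory_inputs(...)
      tibble::tibble(
        tau_obs = lag_time(inp, truth)$tau * exp(rnorm(1, 0, 0.1)),
        kE_obs = growth_steepness(inp, truth)$kE * exp(rnorm(1, 0, 0.1)))
    })
    fit_coefficients(dplyr::bind_cols(grid, obs),
                     start = truth)$coefficients$lag_loc
  }, 0)
  expect_lt(abs(stats::median(recov) - 3.2) / 3.2, 0.25)
})
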