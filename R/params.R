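## The reaction network and its parameterization. Fixed equilibrium constants
## come from solution biochemistry (clathrin-clathrin K_D = 120 uM,
## clathrin-adaptor K_D = 25 uM); the cooperativity, strain, membrane
## length-scale, rates and adaptor density are the fitted model optimum.

#' Model parameters
#'
#' All energetic, kinetic and geometric parameters of the assembly model, with
#' defaults at the optimal fitted values. Derived quantities (bond free
#' energies, the cooperativity factor `f_coop`) are recomputed from the
#' primary fields.
#'
#' @param KD_CC Clathrin-clathrin dissociation constant (no adaptor), uM.
#' @param KD_AC Clathrin-adaptor dissociation constant, uM.
#' @param dG_coop Cooperative stabilization when a participating clathrin is
#'   adaptor-bound, k_B T (negative strengthens).
#' @param dG_strain Ring-closure strain penalty, k_B T.
#' @param h Dimensional-reduction length scale, nm (2D rate = 3D rate / h).
#' @param rho_AP In vitro adaptor surface density, nm^-2.
#' @param k_AP_CLA,k_CLA_CLA,k_AP_lipid Intrinsic association rates,
#'   uM^-1 s^-1.
#' @param KD_AP_lipid Adaptor-lipid dissociation constant, uM.
#' @param dt Propagator time step, us.
#' @param bond_cutoff_nm Maximal site separation for (re)forming an
#'   intra-complex bond (imperfect contacts), nm.
#' @param coop_symmetric Apply cooperativity when EITHER partner of a
#'   clathrin-clathrin bond carries a bound adaptor (default), or only when
#'   the site-owning partner does.
#' @param max_rotation_nm Rotation-rejection threshold for snaps, nm.
#' @return A `model_params` list including derived `dG_CC_free` (= -9 k_B T at
#'   defaults), `dG_CC_coop` (= -11.4), `f_coop`, and per-reaction off-rates.
#' @export
model_params <- function(KD_CC = 120, KD_AC = 25, dG_coop = -2.4,
                         dG_strain = 6.9, h = 30, rho_AP = 0.009,
                         k_AP_CLA = 0.0012, k_CLA_CLA = 0.083,
                         k_AP_lipid = 0.3, KD_AP_lipid = 1,
                         dt = 3, bond_cutoff_nm = 5.5,
                         coop_symmetric = TRUE, max_rotation_nm = 17) {
  if (any(c(KD_CC, KD_AC, h, k_AP_CLA, k_CLA_CLA, k_AP_lipid, KD_AP_lipid,
            dt, bond_cutoff_nm) <= 0)) {
    abort("dissociation constants, rates, h, dt and cutoffs must be positive")
  }
  c0 <- unit_constants()$c0_uM
  p <- list(KD_CC = KD_CC, KD_AC = KD_AC, dG_coop = dG_coop,
            dG_strain = dG_strain, h = h, rho_AP = rho_AP,
            k_AP_CLA = k_AP_CLA, k_CLA_CLA = k_CLA_CLA,
            k_AP_lipid = k_AP_lipid, KD_AP_lipid = KD_AP_lipid,
            dt = dt, bond_cutoff_nm = bond_cutoff_nm,
            coop_symmetric = coop_symmetric,
            max_rotation_nm = max_rotation_nm,
            sigma_CC = 5, sigma_AC = 1, sigma_AL = 1,
            dG_CC_free = -log(c0 / KD_CC),
            dG_CC_coop = -log(c0 / KD_CC) + dG_coop,
            f_coop = exp(-dG_coop))
  structure(p, class = "model_params")
}

#' Derive the reaction table from model parameters
#'
#' One row per reaction channel: clathrin-clathrin without and with adaptor
#' cooperativity (same off-rate, on-rate accelerated by
#' `f_coop = exp(-dG_coop)`), clathrin-adaptor, and adaptor-lipid. 3D rates in
#' uM^-1 s^-1, with a 2D variant `ka_2D = ka_3D / h` (um^2/s after unit
#' conversion) and `kb_2D = kb_3D` for membrane-restricted channels.
#'
#' @param params A [model_params()] object.
#' @param extra_dG_bond Uniform clathrin-clathrin bond stabilization, k_B T
#'   (solution-cage scenarios; applied to the on-rate).
#' @return A tibble of `reaction_spec` rows: `class1`, `class2`, `ka_3D`
#'   (uM^-1 s^-1), `kb` (s^-1), `sigma` (nm), `coop_variant`, `dimensionality`.
#' @export
#' @examples
#' derive_rates(model_params())
derive_rates <- function(params = model_params(), extra_dG_bond = 0) {
  stopifnot(inherits(params, "model_params"))
  boost <- exp(extra_dG_bond)          # >1 strengthens clathrin bonds
  ka_cc <- params$k_CLA_CLA * boost
  kb_cc <- params$k_CLA_CLA * params$KD_CC   # off-rate fixed by K_D
  tibble(
    reaction = c("CC", "CC_coop", "AC", "AL"),
    class1 = c("cla_leg", "cla_leg", "cla_ap", "ap_lip"),
    class2 = c("cla_leg", "cla_leg", "ap_cla", "lipid"),
    ka_3D = c(ka_cc, ka_cc * params$f_coop, params$k_AP_CLA,
              params$k_AP_lipid),
    kb = c(kb_cc, kb_cc, params$k_AP_CLA * params$KD_AC,
           params$k_AP_lipid * params$KD_AP_lipid),
    sigma = c(params$sigma_CC, params$sigma_CC, params$sigma_AC,
              params$sigma_AL),
    coop_variant = c(FALSE, TRUE, FALSE, FALSE),
    dimensionality = c("3D/2D", "3D/2D", "3D/2D", "3D->2D"),
    ka_2D = c(ka_cc, ka_cc * params$f_coop, params$k_AP_CLA, NA) / params$h
  )
}

#' Diffusion-corrected macroscopic association rate
#'
#' `k_on = (1/k_a + 1/(4 pi sigma D))^-1`: the macroscopic rate combines the
#' intrinsic (reaction) resistance with the diffusional encounter resistance.
#'
#' @param ka Intrinsic rate, uM^-1 s^-1. @param sigma Binding radius, nm.
#' @param D Relative translational diffusion constant, um^2/s.
#' @return `k_on` in uM^-1 s^-1.
#' @export
#' @examples
#' kon_macroscopic(0.083, 5, 26)  # reaction-limited: k_on ~ k_a
kon_macroscopic <- function(ka, sigma, D) {
  if (any(c(ka, sigma, D) <= 0)) abort("ka, sigma and D must be positive")
  u <- unit_constants()
  kD_nm3us <- 4 * pi * sigma * D          # D um^2/s == nm^2/us
  kD <- kD_nm3us / u$ka_uMs_to_nm3us     # back to uM^-1 s^-1
  1 / (1 / ka + 1 / kD)
}

# ---- scenario builders -------------------------------------------------------

new_scenario <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "scenario_config")
}

#' In vitro assembly scenario
#'
#' Flat 1 um^2 membrane under a 1 um solution column; implicit fixed adaptor
#' sites at density `rho_AP`; clathrin introduced at t = 0 by a 0th-order
#' reaction and maintained at a constant (stochastically fluctuating) solution
#' concentration of 80 nM (48 copies) by a reservoir. The experimental
#' V/A = 991 um enters the kinetics through the reservoir, not the box height.
#'
#' @param rho_AP Adaptor site density, nm^-2. Values outside the
#'   chelator-occupancy estimate \[0.0014, 0.012\] warn.
#' @param params A [model_params()].
#' @param area_um2 Membrane area. @param height_um Box height.
#' @param CLA_bulk Maintained solution clathrin concentration, uM.
#' @param alpha Pucker angle (flat lattice on membranes).
#' @return A `scenario_config`.
#' @export
make_invitro_scenario <- function(rho_AP = 0.009, params = model_params(),
                                  area_um2 = 1, height_um = 1,
                                  CLA_bulk = 0.08, alpha = 90) {
  if (rho_AP < 0) abort("rho_AP must be non-negative")
  if (rho_AP > 0 && (rho_AP < 0.0014 || rho_AP > 0.012)) {
    warn("rho_AP outside the estimated surface-occupancy bounds [0.0014, 0.012] nm^-2")
  }
  V <- area_um2 * height_um
  target <- concentration_geometry("copies_in_volume", conc_uM = CLA_bulk,
                                   volume_um3 = V)
  new_scenario("invitro",
    params = params, alpha = alpha,
    area_um2 = area_um2, height_um = height_um, V_um3 = V,
    CLA_bulk = CLA_bulk,
    adaptor_mode = "implicit",
    n_implicit_sites = round(rho_AP * 1e6 * area_um2),  # nm^-2 -> um^-2
    rho_AP = rho_AP,
    reservoir = TRUE, reservoir_target = target,
    solution_AC_binding = FALSE,   # adaptors exist only as membrane sites
    lipid_sites_per_um2 = 0,
    CLA_copies = 0, AP_copies = 0)
}

#' Physiologic-like assembly scenario
#'
#' Closed system at cellular V/A = 1 um: 0.7 x 0.7 um membrane, 1 um height,
#' fixed total copies (no reservoir). Clathrin at 0.65 uM; explicit adaptors
#' at `ap_conc` bind lipid sites reversibly; solution clathrin-adaptor binding
#' is disabled (inhibited before membrane localization); implicit lipid sites
#' at ~1% coverage (20000 um^-2).
#'
#' @param ap_conc Adaptor concentration, uM.
#' @param params A [model_params()].
#' @param area_um2,height_um Box geometry. @param CLA_conc Clathrin, uM.
#' @param alpha Pucker angle.
#' @return A `scenario_config`.
#' @export
make_physiologic_scenario <- function(ap_conc = 0.2, params = model_params(),
                                      area_um2 = 0.49, height_um = 1,
                                      CLA_conc = 0.65, alpha = 90) {
  if (ap_conc < 0) abort("ap_conc must be non-negative")
  V <- area_um2 * height_um
  new_scenario("physiologic",
    params = params, alpha = alpha,
    area_um2 = area_um2, height_um = height_um, V_um3 = V,
    CLA_bulk = CLA_conc, AP_bulk = ap_conc,
    adaptor_mode = "explicit",
    n_implicit_sites = round(2e4 * area_um2),   # lipid sites, 1% coverage
    rho_AP = NA_real_,
    reservoir = FALSE, reservoir_target = 0,
    solution_AC_binding = FALSE,
    lipid_sites_per_um2 = 2e4,
    CLA_copies = round(concentration_geometry("copies_in_volume",
                                              conc_uM = CLA_conc,
                                              volume_um3 = V)),
    AP_copies = round(concentration_geometry("copies_in_volume",
                                             conc_uM = ap_conc,
                                             volume_um3 = V)))
}

#' Solution (no-membrane) cage-assembly scenario
#'
#' The physiologic-like system with no membrane binding sites: puckered
#' clathrin (`alpha` 96 or 98 for cage-forming runs) plus adaptors that CAN
#' bind clathrin in solution. Optionally stabilizes all clathrin-clathrin
#' bonds by `dG_bonus` and reduces the ring strain by `strain_reduction`
#' (the calibrated solution-cage model uses ~2 and 2.3 k_B T).
#'
#' @param ap_conc Adaptor concentration, uM. @param alpha Pucker angle.
#' @param dG_bonus Bond stabilization, k_B T.
#' @param strain_reduction Reduction of `dG_strain`, k_B T.
#' @param params A [model_params()].
#' @param area_um2,height_um Box geometry. @param CLA_conc Clathrin, uM.
#' @return A `scenario_config`.
#' @export
make_solution_scenario <- function(ap_conc = 0.2, alpha = 98, dG_bonus = 0,
                                   strain_reduction = 0,
                                   params = model_params(),
                                   area_um2 = 0.49, height_um = 1,
                                   CLA_conc = 0.65) {
  if (!alpha %in% c(96, 98)) {
    warn("cage-forming runs use alpha of 96 or 98 degrees")
  }
  params$dG_strain <- params$dG_strain - strain_reduction
  V <- area_um2 * height_um
  new_scenario("solution",
    params = params, alpha = alpha, dG_bonus = dG_bonus,
    area_um2 = area_um2, height_um = height_um, V_um3 = V,
    CLA_bulk = CLA_conc, AP_bulk = ap_conc,
    adaptor_mode = "explicit",
    n_implicit_sites = 0, rho_AP = NA_real_,
    reservoir = FALSE, reservoir_target = 0,
    solution_AC_binding = TRUE,
    lipid_sites_per_um2 = 0,
    CLA_copies = round(concentration_geometry("copies_in_volume",
                                              conc_uM = CLA_conc,
                                              volume_um3 = V)),
    AP_copies = round(concentration_geometry("copies_in_volume",
                                             conc_uM = ap_conc,
                                             volume_um3 = V)))
}
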