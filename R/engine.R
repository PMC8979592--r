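## R surface of the stochastic propagator. Scenario configurations are
## compiled into the engine's internal representation (nm / us units) and the
## core advances the system in fixed time steps, returning frame-level
## observables plus cluster censuses.

CLASS_IDS <- c(cla_leg = 0L, cla_ap = 1L, ap_cla = 2L, ap_lip = 3L,
               A = 4L, B = 5L)

#' Pairwise association probability for a 3D diffusional encounter
#'
#' Probability that an isolated pair at separation `r_nm` associates within
#' one time step, from the Green's function of the radiation-boundary
#' (Smoluchowski) pair problem with intrinsic rate `ka`.
#'
#' @param r_nm Separation (>= sigma), nm. @param ka Intrinsic rate,
#'   uM^-1 s^-1. @param D Relative diffusion constant, um^2/s.
#' @param sigma_nm Binding radius, nm. @param dt_us Time step, us.
#' @return Probability in \[0, 1\] (vectorized over `r_nm`).
#' @export
#' @examples
#' p_bind_3d(6, ka = 0.083, D = 26, sigma_nm = 5, dt_us = 3)
p_bind_3d <- function(r_nm, ka, D, sigma_nm, dt_us) {
  ka_nm <- ka * unit_constants()$ka_uMs_to_nm3us
  vapply(r_nm, function(r)
    p_bind_3d_cpp(r, ka_nm, D, sigma_nm, dt_us), 0)
}

#' Pairwise association probability for a 2D (membrane) encounter
#'
#' The 2D Green's function has no closed form; the propagator uses a
#' calibrated reactive-annulus scheme: a pair whose in-plane separation falls
#' in `[sigma, sigma + delta]` reacts at rate density `ka_2D / A_annulus`,
#' and dissociation re-places partners uniformly in the annulus, making the
#' scheme detailed-balanced with the area dissociation constant
#' `K_D,2D = K_D,3D * h`.
#'
#' @param r_nm In-plane separation, nm. @param ka_2D 2D rate, um^2/s.
#' @param sigma_nm Binding radius, nm. @param dt_us Time step, us.
#' @param delta_nm Annulus width, nm.
#' @return Probability in \[0, 1\] (vectorized over `r_nm`).
#' @export
p_bind_2d <- function(r_nm, ka_2D, sigma_nm, dt_us, delta_nm = 1) {
  a_ann <- pi * ((sigma_nm + delta_nm)^2 - sigma_nm^2)
  p <- 1 - exp(-ka_2D * dt_us / a_ann)   # um^2/s == nm^2/us
  ifelse(r_nm >= sigma_nm & r_nm < sigma_nm + delta_nm, p, 0)
}

#' Ring-closure attempt probability
#'
#' An unbound pair of clathrin legs inside one complex may close a polygon if
#' within the imperfect-contact cutoff (5.5 nm); the per-step closure
#' probability is `k_b * dt * (c0/K_D) * f_coop[adaptor] * exp(-dG_strain)`,
#' so the realized rebinding-to-unbinding rate ratio equals
#' `exp(-dG_CC) * exp(-dG_strain)`.
#'
#' @param params A [model_params()]. @param separation_nm Site separation.
#' @param adaptor_bound Does cooperativity apply?
#' @return A list: `eligible`, `probability` (per step of `params$dt`).
#' @export
#' @examples
#' ring_closure_probability(model_params(), 5.2)
ring_closure_probability <- function(params, separation_nm,
                                     adaptor_bound = FALSE) {
  stopifnot(inherits(params, "model_params"))
  if (separation_nm > params$bond_cutoff_nm) {
    return(list(eligible = FALSE, probability = 0))
  }
  kb_us <- params$k_CLA_CLA * params$KD_CC * 1e-6
  ratio <- rebinding_ratio(params$KD_CC, adaptor_bound, params$dG_coop,
                           params$dG_strain)
  list(eligible = TRUE, probability = min(1, kb_us * params$dt * ratio))
}

# ---- scenario -> engine configuration ---------------------------------------

tpl_to_cfg <- function(tpl, anchored = FALSE) {
  ifs <- tpl$interfaces
  list(local = t(as.matrix(ifs[, c("x", "y", "z")])),
       cls = unname(CLASS_IDS[ifs$class]),
       excl = ifs$exclusion_nm,
       com_excl = tpl$com_exclusion_nm,
       D = tpl$D_trans, DR = tpl$D_rot,
       anchored = anchored)
}

chan_cfg <- function(c1, c2, ka_uMs, kb_s, sigma, coop = FALSE,
                     ring = FALSE, memonly = FALSE, ka2_nm2us = -1) {
  list(c1 = CLASS_IDS[[c1]], c2 = CLASS_IDS[[c2]],
       ka3 = ka_uMs * unit_constants()$ka_uMs_to_nm3us,
       ka2 = ka2_nm2us, kb = kb_s * 1e-6, sigma = sigma,
       coop = coop, ring = ring, memonly = memonly)
}

base_cfg <- function(box_nm, params, delta2d_nm = 1) {
  list(box_nm = box_nm, dt_us = params$dt, periodic_z = FALSE,
       delta2d_nm = delta2d_nm,
       max_rotation_nm = params$max_rotation_nm, f_coop = params$f_coop,
       coop_either = isTRUE(params$coop_symmetric),
       ring_cutoff_nm = params$bond_cutoff_nm,
       exp_neg_strain = exp(-params$dG_strain),
       coop_marker_class = CLASS_IDS[["cla_ap"]],
       n_implicit_sites = 0, implicit_class = -1L, implicit_ka = 0,
       implicit_kb = 0, implicit_h_nm = 4, implicit_site_z_nm = 4,
       reservoir_type = -1L, reservoir_target = 0,
       reservoir_kdestroy_us = 0,
       templates = list(), channels = list(),
       init_type = integer(), init_pos = matrix(0, 3, 0),
       census_type = 0L)
}

scenario_to_cfg <- function(scenario, kdestroy_s = 1, delta2d_nm = 1) {
  stopifnot(inherits(scenario, "scenario_config"))
  p <- scenario$params
  u <- unit_constants()
  side <- sqrt(scenario$area_um2) * 1e3
  cfg <- base_cfg(c(side, side, scenario$height_um * 1e3), p, delta2d_nm)
  ka_nm <- u$ka_uMs_to_nm3us
  kb_cc <- p$k_CLA_CLA * p$KD_CC
  kb_ac <- p$k_AP_CLA * p$KD_AC
  boost <- if (!is.null(scenario$dG_bonus)) exp(scenario$dG_bonus) else 1
  cc2d <- p$k_CLA_CLA * boost * ka_nm / p$h
  ac2d <- p$k_AP_CLA * ka_nm / p$h
  if (scenario$kind %in% c("invitro", "physiologic", "solution")) {
    cla <- build_clathrin_template(scenario$alpha)
    ap <- build_adaptor_template()
  }

  if (scenario$kind == "invitro") {
    cfg$templates <- list(tpl_to_cfg(cla))
    cfg$channels <- list(
      chan_cfg("cla_leg", "cla_leg", p$k_CLA_CLA, kb_cc, p$sigma_CC,
               coop = TRUE, ring = TRUE, ka2_nm2us = cc2d))
    cfg$n_implicit_sites <- scenario$n_implicit_sites
    cfg$implicit_class <- CLASS_IDS[["cla_ap"]]
    cfg$implicit_ka <- p$k_AP_CLA * ka_nm
    cfg$implicit_kb <- kb_ac * 1e-6
    cfg$implicit_h_nm <- 4
    cfg$implicit_site_z_nm <- 4
    cfg$reservoir_type <- 0L
    cfg$reservoir_target <- scenario$reservoir_target
    cfg$reservoir_kdestroy_us <- kdestroy_s * 1e-6
  } else if (scenario$kind %in% c("physiologic", "solution")) {
    cfg$templates <- list(tpl_to_cfg(cla), tpl_to_cfg(ap))
    cfg$channels <- list(
      chan_cfg("cla_leg", "cla_leg", p$k_CLA_CLA * boost, kb_cc, p$sigma_CC,
               coop = TRUE, ring = TRUE, ka2_nm2us = cc2d),
      chan_cfg("cla_ap", "ap_cla", p$k_AP_CLA, kb_ac, p$sigma_AC,
               memonly = !isTRUE(scenario$solution_AC_binding),
               ka2_nm2us = ac2d))
    if (scenario$n_implicit_sites > 0) {
      cfg$n_implicit_sites <- scenario$n_implicit_sites
      cfg$implicit_class <- CLASS_IDS[["ap_lip"]]
      cfg$implicit_ka <- p$k_AP_lipid * ka_nm
      cfg$implicit_kb <- p$k_AP_lipid * p$KD_AP_lipid * 1e-6
      cfg$implicit_h_nm <- 2
      cfg$implicit_site_z_nm <- 0
    }
    n_cla <- scenario$CLA_copies
    n_ap <- scenario$AP_copies
    cfg$init_type <- c(rep(0L, n_cla), rep(1L, n_ap))
    cfg$init_pos <- rbind(stats::runif(n_cla + n_ap) * side,
                          stats::runif(n_cla + n_ap) * side,
                          stats::runif(n_cla + n_ap) *
                            scenario$height_um * 1e3)
  } else if (scenario$kind == "fixture") {
    cfg <- fixture_to_cfg(scenario, cfg)
  } else {
    abort(paste("unknown scenario kind:", scenario$kind))
  }
  cfg
}

fixture_to_cfg <- function(sc, cfg) {
  u <- unit_constants()
  anch <- identical(sc$dim, "2D")
  ta <- build_point_template("A", "A", sc$D_A, sc$D_rot,
                             exclusion_nm = sc$sigma_nm)
  tb <- build_point_template("B", "B", sc$D_B, sc$D_rot,
                             exclusion_nm = sc$sigma_nm)
  cfg$templates <- list(tpl_to_cfg(ta, anchored = anch),
                        tpl_to_cfg(tb, anchored = anch))
  side <- cfg$box_nm[1]
  nA <- sc$A_copies; nB <- sc$B_copies
  zs <- if (anch) rep(0, nA + nB) else stats::runif(nA + nB) * cfg$box_nm[3]
  cfg$init_type <- c(rep(0L, nA), rep(1L, nB))
  cfg$init_pos <- rbind(stats::runif(nA + nB) * side,
                        stats::runif(nA + nB) * cfg$box_nm[2], zs)
  if (identical(sc$dim, "3D")) cfg$periodic_z <- TRUE
  if (identical(sc$dim, "langmuir")) {
    cfg$init_type <- rep(0L, nA)
    cfg$init_pos <- cfg$init_pos[, seq_len(nA), drop = FALSE]
    cfg$n_implicit_sites <- sc$n_sites
    cfg$implicit_class <- CLASS_IDS[["A"]]
    cfg$implicit_ka <- sc$ka * u$ka_uMs_to_nm3us
    cfg$implicit_kb <- sc$kb * 1e-6
    cfg$implicit_h_nm <- sc$h_site_nm
    cfg$implicit_site_z_nm <- 0
  } else {
    ka2 <- if (identical(sc$dim, "2D"))
      sc$ka * u$ka_uMs_to_nm3us / sc$h_nm else -1
    cfg$channels <- list(
      chan_cfg("A", "B", sc$ka, sc$kb, sc$sigma_nm, ka2_nm2us = ka2))
  }
  cfg$census_type <- 0L
  cfg
}

#' Run a stochastic reaction-diffusion trajectory
#'
#' Compiles a [make_invitro_scenario()], [make_physiologic_scenario()],
#' [make_solution_scenario()] or fixture scenario into the propagator
#' configuration and advances it with time step `params$dt`.
#'
#' @param scenario A `scenario_config`.
#' @param t_end_s Simulated time, seconds.
#' @param seed Integer RNG seed (trajectories are bitwise reproducible for a
#'   fixed seed and build).
#' @param output_every_s Frame cadence, seconds.
#' @param kdestroy_s Reservoir destruction rate for free solution monomers,
#'   s^-1 (the matched 0th-order creation maintains the target copy number).
#' @param delta2d_nm Width of the 2D reactive annulus, nm.
#' @return An `rd_trajectory`: `frames` tibble (time, solution and membrane
#'   copies per species, bond count, largest cluster, cluster count),
#'   `census` (list of per-frame cluster-size vectors), `scenario`, `meta`.
#' @export
run_simulation <- function(scenario, t_end_s, seed = NULL, output_every_s = 0.05,
                     kdestroy_s = 1, delta2d_nm = 1) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- scenario_to_cfg(scenario, kdestroy_s, delta2d_nm)
  dt_s <- cfg$dt_us * 1e-6
  n_steps <- max(1L, as.integer(round(t_end_s / dt_s)))
  every <- max(1L, as.integer(round(output_every_s / dt_s)))
  raw <- simulate_core(cfg, n_steps, every)
  frames <- tibble(
    time_s = raw$time_s,
    sol_clathrin = raw$sol_type0, mem_clathrin = raw$mem_type0,
    sol_adaptor = raw$sol_type1, mem_adaptor = raw$mem_type1,
    n_bonds = raw$n_bonds,
    largest = vapply(raw$cluster_sizes, function(v)
      if (length(v)) max(v) else 0L, 0L),
    n_clusters = vapply(raw$cluster_sizes, length, 0L))
  area <- if (inherits(scenario, "scenario_config") &&
              !is.null(scenario$area_um2)) scenario$area_um2 else NA_real_
  if (!is.na(area)) {
    frames$mem_clathrin_per_um2 <- frames$mem_clathrin / area
  }
  structure(list(
    frames = frames, census = raw$cluster_sizes, scenario = scenario,
    final = list(type = raw$final_type, comp = raw$final_comp,
                 pos = raw$final_pos, quat = raw$final_quat),
    meta = list(seed = seed, dt_us = cfg$dt_us, n_steps = n_steps,
                implicit_occupied = raw$implicit_occupied,
                n_events = raw$n_events,
                n_rej_steric = raw$n_rej_steric,
                n_rej_rot = raw$n_rej_rot,
                n_bind_accept = raw$n_bind_accept,
                n_snap_fail = raw$n_snap_fail,
                prof = raw$prof)),
    class = "rd_trajectory")
}

#' @export
print.rd_trajectory <- function(x, ...) {
  cat("<rd_trajectory> ", nrow(x$frames), " frames, ",
      format(max(x$frames$time_s), digits = 4), " s simulated (dt = ",
      x$meta$dt_us, " us, seed = ",
      if (is.null(x$meta$seed)) "none" else x$meta$seed, ")\n", sep = "")
  print(utils::tail(x$frames, 3))
  invisible(x)
}
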