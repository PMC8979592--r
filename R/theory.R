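## Phenomenological macroscopic model for membrane clathrin accumulation:
## a closed-form lag time (sum of localization + nucleation (+ adaptor
## localization) timescales) and an initial growth steepness kE motivated by
## mass-action recruitment fluxes. Coefficients are empirical and refittable.

#' Inputs for the macroscopic lag/steepness model
#'
#' Collects the microscopic parameters the closed-form expressions depend on.
#' Defaults reproduce the optimal in vitro model (fitted parameter table).
#'
#' @param rho_AP Adaptor density on the membrane, nm^-2.
#' @param k_AP_CLA Adaptor-clathrin association rate, uM^-1 s^-1.
#' @param k_CLA_CLA Clathrin-clathrin association rate (no adaptor), uM^-1 s^-1.
#' @param dG_coop Cooperative free energy from adaptor binding, k_B T (< 0
#'   strengthens clathrin-clathrin bonds).
#' @param dG_strain Strain free-energy penalty for closed polygons, k_B T.
#' @param h Dimensional-reduction length scale, nm.
#' @param V Solution volume, um^3. @param A Membrane area, um^2.
#' @param CLA_bulk Bulk clathrin concentration, uM.
#' @param AP_bulk Bulk adaptor concentration, uM (physiologic-like runs).
#' @param lipid_density Lipid binding-site density, um^-2.
#' @param k_AP_lipid Adaptor-lipid association rate, uM^-1 s^-1.
#' @return A `theory_inputs` list with derived `DF = V/(A h)` and
#'   `f_coop = exp(-dG_coop)`.
#' @export
theory_inputs <- function(rho_AP = 0.009, k_AP_CLA = 0.0012,
                          k_CLA_CLA = 0.083, dG_coop = -2.4, dG_strain = 6.9,
                          h = 30, V = 991, A = 1, CLA_bulk = 0.08,
                          AP_bulk = 0, lipid_density = 2e4,
                          k_AP_lipid = 0.3) {
  if (V <= 0 || A <= 0 || h <= 0) abort("V, A and h must be positive")
  if (any(c(rho_AP, k_AP_CLA, k_CLA_CLA, CLA_bulk, AP_bulk,
            lipid_density, k_AP_lipid) < 0)) {
    abort("rates and concentrations must be non-negative")
  }
  structure(list(
    rho_AP = rho_AP, k_AP_CLA = k_AP_CLA, k_CLA_CLA = k_CLA_CLA,
    dG_coop = dG_coop, dG_strain = dG_strain, h = h, V = V, A = A,
    CLA_bulk = CLA_bulk, AP_bulk = AP_bulk, lipid_density = lipid_density,
    k_AP_lipid = k_AP_lipid,
    DF = dimensionality_factor(V, A, h),
    f_coop = exp(-dG_coop)
  ), class = "theory_inputs")
}

#' Coefficients of the lag-time and steepness expressions
#'
#' The empirical coefficients of the two closed-form observables. Lag time:
#' prefactor `lag_loc` on the localization term, dimensionality-factor
#' exponent `1/lag_DF_exp` and strain denominator `lag_strain` on the
#' nucleation term, and a free adaptor-localization coefficient `lag_AP`
#' (physiologic-like only). Steepness: DF exponent `1/kE_DF1_exp` (adaptor
#' recruitment), prefactor `kE_pref`, DF exponent `1/kE_DF2_exp` and strain
#' denominator `kE_strain` (clathrin-clathrin recruitment), and a free
#' adaptor-recruitment coefficient `kE_AP`.
#'
#' The adaptor terms (`lag_AP`, `kE_AP`) use a stand-in functional form
#' (inverse / proportional to `k_AP_lipid * AP_bulk * lipid_density`); their
#' published closed form is not reproduced here, so physiologic predictions at
#' low adaptor concentration carry that caveat.
#'
#' @param lag_loc,lag_DF_exp,lag_strain,lag_AP Lag-time coefficients.
#' @param kE_DF1_exp,kE_pref,kE_DF2_exp,kE_strain,kE_AP Steepness coefficients.
#' @return A `theory_coefficients` list.
#' @export
theory_coefficients <- function(lag_loc = 3.2, lag_DF_exp = 8.2,
                                lag_strain = 8.3, lag_AP = 1,
                                kE_DF1_exp = 3.2, kE_pref = 0.0012,
                                kE_DF2_exp = 2.5, kE_strain = 3.3,
                                kE_AP = 1) {
  vals <- c(lag_loc = lag_loc, lag_DF_exp = lag_DF_exp,
            lag_strain = lag_strain, lag_AP = lag_AP,
            kE_DF1_exp = kE_DF1_exp, kE_pref = kE_pref,
            kE_DF2_exp = kE_DF2_exp, kE_strain = kE_strain, kE_AP = kE_AP)
  if (any(vals <= 0)) abort("all coefficients must be positive")
  structure(as.list(vals), class = "theory_coefficients")
}

#' Dimensionality factor DF = V/(A h)
#'
#' Quantifies the equilibrium enhancement of membrane-localized binding over
#' solution binding; `DF > 1` means dimensional reduction favors the membrane.
#'
#' @param V Volume, um^3. @param A Area, um^2. @param h Length scale, nm.
#' @return Dimensionless DF.
#' @export
#' @examples
#' dimensionality_factor(991, 1, 30)  # in vitro, ~3.3e4
dimensionality_factor <- function(V, A, h) {
  if (any(c(V, A, h) <= 0)) abort("V, A and h must be positive")
  V / (A * h * 1e-3)  # h nm -> um
}

#' Lag time of membrane clathrin accumulation
#'
#' Closed-form lag time as a sum of timescales: clathrin localization to the
#' membrane, nucleation of clathrin-clathrin contacts, and (physiologic-like
#' only) adaptor localization to the membrane. Each term varies inversely with
#' a rate times a concentration.
#'
#' @param inputs A [theory_inputs()] object.
#' @param coeffs A [theory_coefficients()] object.
#' @param physiologic Include the adaptor-localization term?
#' @return A tibble with one row: `tau` (s), per-term columns `t_localization`,
#'   `t_nucleation`, `t_AP_localization`, and an `infinite_lag` flag.
#' @export
#' @examples
#' lag_time(theory_inputs(), theory_coefficients())  # ~12.5 s at the optimum
lag_time <- function(inputs, coeffs = theory_coefficients(),
                     physiologic = FALSE) {
  stopifnot(inherits(inputs, "theory_inputs"))
  loc_rate <- inputs$rho_AP * 1e6 * inputs$A *      # adaptor copies on A
    inputs$k_AP_CLA * inputs$CLA_bulk               # 1/s
  t_loc <- if (loc_rate > 0) coeffs$lag_loc / loc_rate else Inf
  nuc_rate <- inputs$f_coop * inputs$k_CLA_CLA * inputs$CLA_bulk *
    inputs$DF^(1 / coeffs$lag_DF_exp) *
    exp(-inputs$dG_strain / coeffs$lag_strain)
  t_nuc <- if (nuc_rate > 0) 1 / nuc_rate else Inf
  t_ap <- 0
  if (physiologic) {
    ap_rate <- inputs$k_AP_lipid * inputs$AP_bulk *
      inputs$lipid_density * inputs$A
    t_ap <- if (ap_rate > 0) coeffs$lag_AP / ap_rate else Inf
  }
  tau <- t_loc + t_nuc + t_ap
  tibble(tau = tau, t_localization = t_loc, t_nucleation = t_nuc,
         t_AP_localization = t_ap, infinite_lag = !is.finite(tau))
}

#' Initial growth steepness kE of membrane clathrin accumulation
#'
#' Closed-form steepness of the initial (approximately linear) growth of
#' membrane-bound clathrin, as a sum of mass-action recruitment fluxes:
#' clathrin recruited by membrane adaptors, clathrin recruited by
#' membrane clathrin, and (physiologic-like) adaptor recruitment. Reported in
#' copies um^-2 s^-1 for the dominant adaptor term; the clathrin-clathrin term
#' carries its empirical fitted coefficient, whose canonical unit convention
#' (leftover concentration factor in molar) is documented in the vignette.
#'
#' @inheritParams lag_time
#' @return A tibble with `kE` and per-term columns `kE_adaptor`,
#'   `kE_clathrin`, `kE_AP`.
#' @export
growth_steepness <- function(inputs, coeffs = theory_coefficients(),
                             physiologic = FALSE) {
  stopifnot(inherits(inputs, "theory_inputs"))
  term1 <- inputs$k_AP_CLA * inputs$rho_AP * 1e6 * inputs$CLA_bulk *
    inputs$DF^(1 / coeffs$kE_DF1_exp)              # copies um^-2 s^-1
  cla_M <- inputs$CLA_bulk * 1e-6                  # uM -> M (fit convention)
  k_M <- inputs$k_CLA_CLA * 1e6                    # uM^-1 -> M^-1
  term2 <- coeffs$kE_pref * inputs$f_coop * k_M * cla_M^2 *
    inputs$DF^(1 / coeffs$kE_DF2_exp) *
    exp(inputs$dG_strain / coeffs$kE_strain) * (inputs$V / inputs$A)
  term3 <- 0
  if (physiologic) {
    term3 <- coeffs$kE_AP * inputs$k_AP_lipid * inputs$AP_bulk *
      inputs$lipid_density * 1e-6                  # scaled stand-in form
  }
  tibble(kE = term1 + term2 + term3, kE_adaptor = term1,
         kE_clathrin = term2, kE_AP = term3)
}

#' Rebinding-to-unbinding ratio for a loop bond
#'
#' For a clathrin-clathrin bond inside a closed polygon, breaking the bond
#' does not fragment the lattice; the held geometry rebinds much faster than
#' it escapes. The ratio of rebinding to unbinding rates is
#' `(c0/K_D) * exp(-dG_coop) [adaptor bound] * exp(-dG_strain)` with standard
#' state `c0` = 1 M.
#'
#' @param KD_uM Pairwise dissociation constant, uM.
#' @param adaptor_bound Is either clathrin adaptor-bound (cooperativity)?
#' @param dG_coop,dG_strain Free energies in k_B T.
#' @return The dimensionless ratio.
#' @export
#' @examples
#' rebinding_ratio(120)                        # 8.3e3
#' rebinding_ratio(120, adaptor_bound = TRUE)  # 9.2e4
rebinding_ratio <- function(KD_uM, adaptor_bound = FALSE, dG_coop = -2.4,
                            dG_strain = 0) {
  if (KD_uM <= 0) abort("KD_uM must be positive")
  r <- (unit_constants()$c0_uM / KD_uM) * exp(-dG_strain)
  if (adaptor_bound) r <- r * exp(-dG_coop)
  r
}

#' Effective ideal-bond count of a strained hexagon
#'
#' A closed hexagon holds 6 bonds plus one strain penalty; its free energy
#' corresponds to `(6 dG_CC + dG_strain)/dG_CC` ideal bonds.
#'
#' @param dG_CC Pairwise bond free energy, k_B T (must be negative).
#' @param dG_strain Strain penalty, k_B T.
#' @return Effective number of ideal bonds.
#' @export
#' @examples
#' effective_bond_count(-11.4, 6.9)  # 5.4 rather than 6
effective_bond_count <- function(dG_CC, dG_strain) {
  if (dG_CC >= 0) abort("dG_CC must be negative (a favorable bond)")
  (6 * dG_CC + dG_strain) / dG_CC
}

#' Globally fit the lag/steepness coefficients to observed kinetics
#'
#' Nonlinear least squares, in log-time / log-steepness space, of the
#' closed-form lag and steepness expressions against a set of scenarios with
#' observed `tau` and/or `kE`. Scenarios are rows of a data frame holding the
#' [theory_inputs()] fields plus `tau_obs` and `kE_obs` (NA to omit) and an
#' optional logical `physiologic` column.
#'
#' @param data A data frame of scenarios and observations.
#' @param start Starting [theory_coefficients()].
#' @param fit_lag,fit_kE Fit the lag and/or steepness coefficients.
#' @return A list with `coefficients` (a [theory_coefficients()]),
#'   `residuals` (per-scenario tibble of observed/predicted), and the
#'   underlying `nls` objects.
#' @export
fit_coefficients <- function(data, start = theory_coefficients(),
                             fit_lag = TRUE, fit_kE = TRUE) {
  stopifnot(is.data.frame(data), nrow(data) >= 4)
  if (!"physiologic" %in% names(data)) data$physiologic <- FALSE
  inp <- lapply(seq_len(nrow(data)), function(i) {
    r <- data[i, ]
    theory_inputs(rho_AP = r$rho_AP, k_AP_CLA = r$k_AP_CLA,
                  k_CLA_CLA = r$k_CLA_CLA, dG_coop = r$dG_coop,
                  dG_strain = r$dG_strain, h = r$h, V = r$V, A = r$A,
                  CLA_bulk = r$CLA_bulk,
                  AP_bulk = if ("AP_bulk" %in% names(r)) r$AP_bulk else 0,
                  lipid_density = if ("lipid_density" %in% names(r))
                    r$lipid_density else 2e4,
                  k_AP_lipid = if ("k_AP_lipid" %in% names(r))
                    r$k_AP_lipid else 0.3)
  })
  co <- start
  fit_tau <- fit_ke <- NULL

  if (fit_lag) {
    keep <- which(!is.na(data$tau_obs) & data$tau_obs > 0)
    if (length(keep) < 3) abort("need >= 3 scenarios with tau_obs to fit lag")
    pred_log_tau <- function(p, idx) {
      cf <- theory_coefficients(lag_loc = p[1], lag_DF_exp = p[2],
                                lag_strain = p[3],
                                lag_AP = if (length(p) > 3) p[4] else 1)
      log(vapply(idx, function(i)
        lag_time(inp[[i]], cf, physiologic = data$physiologic[i])$tau, 0))
    }
    use_ap <- any(data$physiologic[keep])
    p0 <- c(co$lag_loc, co$lag_DF_exp, co$lag_strain,
            if (use_ap) co$lag_AP)
    fit_tau <- minpack.lm::nls.lm(
      par = p0,
      fn = function(p) pred_log_tau(abs(p), keep) - log(data$tau_obs[keep]),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    p <- abs(fit_tau$par)
    co$lag_loc <- p[1]; co$lag_DF_exp <- p[2]; co$lag_strain <- p[3]
    if (use_ap) co$lag_AP <- p[4]
  }

  if (fit_kE) {
    keep <- which(!is.na(data$kE_obs) & data$kE_obs > 0)
    if (length(keep) < 3) abort("need >= 3 scenarios with kE_obs to fit kE")
    pred_log_ke <- function(p, idx) {
      cf <- theory_coefficients(kE_DF1_exp = p[1], kE_pref = p[2],
                                kE_DF2_exp = p[3], kE_strain = p[4],
                                kE_AP = if (length(p) > 4) p[5] else 1,
                                lag_loc = co$lag_loc,
                                lag_DF_exp = co$lag_DF_exp,
                                lag_strain = co$lag_strain, lag_AP = co$lag_AP)
      log(vapply(idx, function(i)
        growth_steepness(inp[[i]], cf,
                         physiologic = data$physiologic[i])$kE, 0))
    }
    use_ap <- any(data$physiologic[keep])
    p0 <- c(co$kE_DF1_exp, co$kE_pref, co$kE_DF2_exp, co$kE_strain,
            if (use_ap) co$kE_AP)
    fit_ke <- minpack.lm::nls.lm(
      par = p0,
      fn = function(p) pred_log_ke(abs(p), keep) - log(data$kE_obs[keep]),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    p <- abs(fit_ke$par)
    co$kE_DF1_exp <- p[1]; co$kE_pref <- p[2]; co$kE_DF2_exp <- p[3]
    co$kE_strain <- p[4]
    if (use_ap) co$kE_AP <- p[5]
  }

  res <- dplyr::bind_rows(lapply(seq_len(nrow(data)), function(i) {
    tibble(
      scenario = i,
      tau_obs = data$tau_obs[i],
      tau_pred = lag_time(inp[[i]], co,
                          physiologic = data$physiologic[i])$tau,
      kE_obs = data$kE_obs[i],
      kE_pred = growth_steepness(inp[[i]], co,
                                 physiologic = data$physiologic[i])$kE)
  }))
  list(coefficients = co, residuals = res, fit_lag = fit_tau, fit_kE = fit_ke)
}
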