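## Synthetic validation fixtures: every fixture carries its closed-form
## reference so simulator and analysis contracts can be checked without any
## external data.

#' Bimolecular fixture scenario (A + B <-> C)
#'
#' A two-species point-particle system in 3D solution, confined to the 2D
#' membrane plane, or binding implicit membrane sites from solution
#' ("langmuir"). Used to validate association kinetics and equilibria against
#' closed-form mass action.
#'
#' @param dim `"3D"`, `"2D"`, or `"langmuir"`.
#' @param ka Intrinsic rate, uM^-1 s^-1. @param KD Dissociation constant, uM
#'   (`kb = ka * KD`).
#' @param A_copies,B_copies Copy numbers.
#' @param box_um Box side lengths, um (length 3).
#' @param sigma_nm Binding radius. @param h_nm 2D conversion length scale.
#' @param D_A,D_B Diffusion constants, um^2/s. @param D_rot rad^2/us.
#' @param n_sites,h_site_nm Implicit-site count and interaction height
#'   (langmuir only).
#' @param params A [model_params()] (supplies the time step).
#' @return A `scenario_config` of kind `"fixture"`.
#' @export
make_bimolecular_scenario <- function(dim = "3D", ka = 10, KD = 20,
                                      A_copies = 100, B_copies = 100,
                                      box_um = c(0.25, 0.25, 0.25),
                                      sigma_nm = 1, h_nm = 30,
                                      D_A = 20, D_B = 20, D_rot = 0.1,
                                      n_sites = 500, h_site_nm = 2,
                                      params = model_params()) {
  dim <- match.arg(dim, c("3D", "2D", "langmuir"))
  new_scenario("fixture",
    params = params, dim = dim, ka = ka, KD = KD, kb = ka * KD,
    A_copies = A_copies, B_copies = B_copies,
    area_um2 = box_um[1] * box_um[2], height_um = box_um[3],
    V_um3 = prod(box_um), sigma_nm = sigma_nm, h_nm = h_nm,
    D_A = D_A, D_B = D_B, D_rot = D_rot,
    n_sites = n_sites, h_site_nm = h_site_nm,
    n_implicit_sites = if (dim == "langmuir") n_sites else 0)
}

#' Closed-form equilibrium of a bimolecular fixture
#'
#' Mass-action equilibrium of `A + B <-> C` in a closed box, from the
#' quadratic formula, in whichever dimensionality the fixture specifies:
#' 3D uses `K_D` in uM; 2D uses the area constant `K_D,2D = K_D * h`;
#' langmuir treats the implicit sites as species B.
#'
#' @param sc A [make_bimolecular_scenario()] fixture.
#' @return A list: `bound_copies`, `bound_fraction_A`, `KD_copies` (the
#'   dissociation constant converted to copies in the fixture geometry).
#' @export
#' @examples
#' eq <- fixture_equilibrium(make_bimolecular_scenario("3D", KD = 120,
#'   A_copies = 48, B_copies = 48, box_um = c(1, 1, 1)))
#' eq$bound_copies
fixture_equilibrium <- function(sc) {
  stopifnot(identical(sc$kind, "fixture"))
  u <- unit_constants()
  if (identical(sc$dim, "2D")) {
    # K_D,2D = K_D,3D * h, in copies per membrane area
    KD_um2 <- sc$KD * u$copies_per_uM_um3 * sc$h_nm * 1e-3
    Kc <- KD_um2 * sc$area_um2
    A0 <- sc$A_copies; B0 <- sc$B_copies
  } else if (identical(sc$dim, "langmuir")) {
    Kc <- sc$KD * u$copies_per_uM_um3 * sc$V_um3
    A0 <- sc$A_copies; B0 <- sc$n_sites
  } else {
    Kc <- sc$KD * u$copies_per_uM_um3 * sc$V_um3
    A0 <- sc$A_copies; B0 <- sc$B_copies
  }
  s <- A0 + B0 + Kc
  c_eq <- (s - sqrt(s^2 - 4 * A0 * B0)) / 2
  list(bound_copies = c_eq, bound_fraction_A = c_eq / A0, KD_copies = Kc)
}

#' Synthetic lag/exponential growth curve
#'
#' Samples the four-parameter lag + saturating-exponential growth form
#' `y(t) = b + E (1 - exp(-k (t - tau))) H(t - tau)` with optional Gaussian
#' noise (fractional, relative to `E`).
#'
#' @param b,tau,k,E Curve parameters (offset, lag s, rate 1/s, extent).
#' @param t_max Duration, s. @param n Points. @param noise_frac Gaussian
#'   noise sd as a fraction of `E`. @param seed RNG seed.
#' @return A tibble `(time_s, value)` with the truth in attributes.
#' @export
generate_growth_curve <- function(b = 10, tau = 13, k = 1 / 121, E = 5000,
                                  t_max = 400, n = 200, noise_frac = 0,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, t_max, length.out = n)
  y <- b + E * (1 - exp(-k * (t - tau))) * (t >= tau)
  if (noise_frac > 0) y <- y + stats::rnorm(n, 0, noise_frac * E)
  out <- tibble(time_s = t, value = y)
  attr(out, "truth") <- c(b = b, tau = tau, k = k, E = E)
  out
}

#' Synthetic cluster-census stream with a known size landscape
#'
#' Builds per-frame cluster censuses whose number-weighted size distribution
#' reproduces a piecewise -ln P(n) landscape: a linear barrier rising to
#' `barrier_kBT` at `n1`, a flat plateau to `n2`, and a linear well falling
#' by `well_kBT` beyond, so that plateau-intercept extraction has an exact
#' constructed answer.
#'
#' @param n1,n2 Plateau onset and end (trimers).
#' @param barrier_kBT Plateau level above the monomer baseline.
#' @param well_kBT Depth of the well below the plateau at `n_max`.
#' @param n_max Largest cluster size. @param n_frames Frames to emit.
#' @param frame_clusters Clusters drawn per frame. @param seed RNG seed.
#' @return A list: `census` (list of integer vectors), `landscape_true`
#'   (tibble `n`, `minus_log_p`), `n1`, `n2`.
#' @export
generate_landscape_census <- function(n1 = 25, n2 = 60, barrier_kBT = 4,
                                      well_kBT = 3, n_max = 90,
                                      n_frames = 400, frame_clusters = 60,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- seq_len(n_max)
  g <- numeric(n_max)
  g[n <= n1] <- barrier_kBT * (n[n <= n1] - 1) / (n1 - 1)
  g[n > n1 & n <= n2] <- barrier_kBT
  idx <- n > n2
  g[idx] <- barrier_kBT - well_kBT * (n[idx] - n2) / (n_max - n2)
  p <- exp(-g); p <- p / sum(p)
  census <- lapply(seq_len(n_frames), function(i)
    sort(sample(n, frame_clusters, replace = TRUE, prob = p)))
  list(census = census,
       landscape_true = tibble(n = n, minus_log_p = -log(p)),
       n1 = n1, n2 = n2)
}

#' Generate a validation fixture with its analytic reference
#'
#' Dispatcher over the fixture kinds used by the validation suite. Each
#' result is self-contained: the input (scenario or dataset) plus the exact
#' expected observable.
#'
#' @param type One of `"bimolecular_3d"`, `"bimolecular_2d"`,
#'   `"membrane_localization"`, `"timestep_check"`, `"growth_curve"`,
#'   `"landscape_curve"`.
#' @param seed RNG seed. @param ... Overrides passed to the underlying
#'   generator.
#' @return A list with `input` and `reference`.
#' @export
generate_fixture <- function(type, seed = 1, ...) {
  type <- match.arg(type, c("bimolecular_3d", "bimolecular_2d",
                            "membrane_localization", "timestep_check",
                            "growth_curve", "landscape_curve"))
  switch(type,
    bimolecular_3d = {
      sc <- make_bimolecular_scenario("3D", ...)
      list(input = sc, reference = fixture_equilibrium(sc))
    },
    bimolecular_2d = {
      sc <- make_bimolecular_scenario("2D", ...)
      list(input = sc, reference = fixture_equilibrium(sc))
    },
    membrane_localization = {
      sc <- make_bimolecular_scenario("langmuir", ...)
      list(input = sc, reference = fixture_equilibrium(sc))
    },
    timestep_check = {
      sc <- make_bimolecular_scenario("3D", ...)
      list(input = sc, reference = fixture_equilibrium(sc))
    },
    growth_curve = {
      d <- generate_growth_curve(seed = seed, ...)
      list(input = d, reference = attr(d, "truth"))
    },
    landscape_curve = {
      d <- generate_landscape_census(seed = seed, ...)
      list(input = d$census, reference = list(n1 = d$n1, n2 = d$n2,
                                              truth = d$landscape_true))
    })
}
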