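#' @keywords internal
"_PACKAGE"

#' @importFrom Rcpp sourceCpp
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data abort warn
#' @useDynLib clathrid, .registration = TRUE
NULL

## Canonical unit system used throughout:
##   length nm (meshes, molecule geometry) / um (boxes, areas),
##   time s (user-facing) / us (propagator), energy k_B*T,
##   concentration uM, 3D rates uM^-1 s^-1, 2D rates um^2/s.

#' Unit conversion constants
#'
#' Named constants used across the package. `copies_per_uM_um3` converts a
#' micromolar concentration in a cubic-micron volume to molecule copies
#' (Avogadro's number scaled); `ka_uMs_to_nm3us` converts a bimolecular rate
#' from uM^-1 s^-1 to nm^3/us, the internal propagator units;
#' `kcalmol_per_kBT` is evaluated at T = 298 K.
#'
#' @return A named list of conversion factors.
#' @export
#' @examples
#' unit_constants()$copies_per_uM_um3 * 0.08  # copies at 80 nM in 1 um^3
unit_constants <- function() {
  list(
    copies_per_uM_um3 = 602.214076,    # N_A * 1e-6 mol/L * 1e-15 L/um^3
    ka_uMs_to_nm3us   = 1e3 / 602.214076, # 1 uM^-1 s^-1 = 1.6606 nm^3/us
    D_um2s_to_nm2us   = 1,              # 1 um^2/s == 1 nm^2/us
    kcalmol_per_kBT   = 0.59248,        # k_B * 298 K in kcal/mol
    c0_uM             = 1e6             # standard state 1 M in uM
  )
}

#' Concentration and geometry bookkeeping
#'
#' Worked conversions between bulk concentrations, copy numbers, surface
#' densities, and volume-to-area ratios for the simulation scenarios.
#'
#' * `copies_in_volume`: `conc_uM * volume_um3 * N_A` (copies).
#' * `max_surface_density`: copies/um^2 if every molecule of a solution species
#'   at `conc_uM` in a column of `height_um` binds the membrane.
#' * `va_ratio`: volume (uL) over area (um^2), reported in um.
#' * `langmuir_surface_density`: equilibrium density of a ligand at
#'   concentration `conc_uM` on `sites_per_nm2` binding sites with
#'   dissociation constant `KD_uM`, i.e. `sites * C / (C + KD)` (nm^-2).
#'
#' @param kind One of `"copies_in_volume"`, `"max_surface_density"`,
#'   `"va_ratio"`, `"langmuir_surface_density"`.
#' @param ... Arguments of the selected conversion (see Details).
#' @return A single numeric value.
#' @export
#' @examples
#' concentration_geometry("copies_in_volume", conc_uM = 0.08, volume_um3 = 1)
#' concentration_geometry("va_ratio", volume_uL = 200, area_um2 = 2.017e8)
concentration_geometry <- function(kind, ...) {
  args <- list(...)
  chk <- function(x, nm) {
    if (is.null(x) || !is.numeric(x) || any(x < 0)) {
      abort(sprintf("'%s' must be a non-negative number", nm))
    }
    x
  }
  switch(match.arg(kind, c("copies_in_volume", "max_surface_density",
                           "va_ratio", "langmuir_surface_density")),
    copies_in_volume = chk(args$conc_uM, "conc_uM") *
      chk(args$volume_um3, "volume_um3") * unit_constants()$copies_per_uM_um3,
    max_surface_density = chk(args$conc_uM, "conc_uM") *
      chk(args$height_um, "height_um") * unit_constants()$copies_per_uM_um3,
    va_ratio = {
      v_um3 <- chk(args$volume_uL, "volume_uL") * 1e9  # 1 uL = 1e9 um^3
      v_um3 / chk(args$area_um2, "area_um2")
    },
    langmuir_surface_density = {
      conc <- chk(args$conc_uM, "conc_uM")
      chk(args$sites_per_nm2, "sites_per_nm2") * conc /
        (conc + chk(args$KD_uM, "KD_uM"))
    }
  )
}
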