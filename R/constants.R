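#' Physical constants used by the glide force balance
#'
#' Returns the fixed physical constants of the hydrodynamic model: the
#' gravitational acceleration, the atmosphere-to-Pascal conversion, the density
#' of air at the surface, and the tissue compressibility. Pressure at depth
#' `d` metres is taken as `(1 + 0.1 d)` atmospheres throughout, so gas volumes
#' follow Boyle's law on that scale.
#'
#' @param g Gravitational acceleration, m s^-2.
#' @param atm_to_pa Conversion factor from atmospheres to Pascals.
#' @param rho_air_surface Air density at the surface, kg m^-3. Not specified by
#'   the force balance itself; standard air (1.225) is the default and its
#'   effect on the gas term is below 0.2 percent.
#' @param r Tissue compressibility on the 1e-9 Pa^-1 scale (i.e. `r = 0.38`
#'   means 0.38e-9 Pa^-1), the value estimated for northern bottlenose whales.
#'
#' @return A named list with components `g`, `atm_to_pa`, `rho_air_surface`
#'   and `r`.
#' @examples
#' physical_constants()$g
#' @export
physical_constants <- function(g = 9.8, atm_to_pa = 101325,
                               rho_air_surface = 1.225, r = 0.38) {
  stopifnot(g > 0, atm_to_pa > 0, rho_air_surface >= 0, r >= 0)
  list(g = g, atm_to_pa = atm_to_pa, rho_air_surface = rho_air_surface, r = r)
}

#' Lipid / lipid-free tissue density mixture
#'
#' Component densities of the two-compartment body-composition model used to
#' convert tissue density into a lipid fraction: lipid at 900.7 kg m^-3 and
#' lipid-free tissue at 1114.6 kg m^-3 (values derived from elephant seals).
#'
#' @param rho_lipid Lipid density, kg m^-3.
#' @param rho_lipid_free Lipid-free tissue density, kg m^-3.
#' @return A named list with components `rho_lipid` and `rho_lipid_free`.
#' @examples
#' lipid_mixture()
#' @export
lipid_mixture <- function(rho_lipid = 900.7, rho_lipid_free = 1114.6) {
  stopifnot(rho_lipid > 0, rho_lipid < rho_lipid_free)
  list(rho_lipid = rho_lipid, rho_lipid_free = rho_lipid_free)
}
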