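#' Tissue density at depth
#'
#' Body tissues compress slightly with hydrostatic pressure. With
#' compressibility `r` (on the 1e-9 Pa^-1 scale) and pressure `(1 + 0.1 d)`
#' atmospheres at depth `d`, the non-gas tissue density is
#' `rho_tissue(d) = rho_tissue0 / (1 - r * (1 + 0.1 d) * 101325 * 1e-9)`.
#'
#' @param rho_tissue0 Tissue density at surface pressure, kg m^-3.
#' @param d Depth, m (positive down). Vectorised.
#' @param constants Output of [physical_constants()]; supplies `r` and the
#'   atmosphere-to-Pascal factor.
#' @return Tissue density at depth, kg m^-3. Equal to `rho_tissue0` when
#'   `r = 0`, and strictly larger for `r > 0`.
#' @examples
#' tissue_density_at_depth(1030, d = 100)
#' @export
tissue_density_at_depth <- function(rho_tissue0, d,
                                    constants = physical_constants()) {
  stopifnot(all(is.finite(rho_tissue0)), all(is.finite(d)))
  denom <- 1 - constants$r * (1 + 0.1 * d) * constants$atm_to_pa * 1e-9
  if (any(denom <= 0))
    stop("non-physical compressibility: denominator of the density-depth ",
         "relation is <= 0")
  rho_tissue0 / denom
}

#' Glide force-balance forward model
#'
#' Predicts acceleration along the swimming path during a glide from the
#' balance of drag and buoyancy forces:
#' \deqn{a = -0.5 \cdot C_D A m^{-1} \cdot \rho_{sw} v^2
#'       + (\rho_{sw}/\rho_{tissue}(d) - 1) \, g \sin p
#'       + V_{air} m^{-1} g \sin p \,
#'         \frac{\rho_{sw} - \rho_{air}(1 + 0.1 d)}{1 + 0.1 d}}
#' The first term is (parasite plus any lift-induced) drag, the second the net
#' buoyancy of body tissue, and the third the net buoyancy of the diving gas,
#' compressed with depth by Boyle's law.
#'
#' All glide-state arguments are vectorised and recycled against each other.
#'
#' @param rho_tissue0 Tissue density at the surface, kg m^-3.
#' @param cdam Combined drag term \eqn{C_D A m^{-1}}, m^2 kg^-1.
#' @param vair_per_mass Mass-specific diving gas volume at the surface,
#'   ml kg^-1 (converted internally to m^3 kg^-1).
#' @param d Mean glide depth, m.
#' @param v Mean glide speed, m s^-1 (must be >= 0).
#' @param p Mean glide pitch, radians, positive nose-up; |p| <= pi/2.
#' @param rho_sw Seawater density at the glide depth, kg m^-3.
#' @param constants Output of [physical_constants()].
#' @return Predicted acceleration along the path, m s^-2.
#' @examples
#' # a neutrally buoyant whale with no gas decelerates by drag alone
#' glide_acceleration(rho_tissue0 = 1027 * (1 - 0.38 * 1.1 * 101325 * 1e-9),
#'                    cdam = 11.8e-6, vair_per_mass = 0,
#'                    d = 10, v = 1.5, p = -0.6, rho_sw = 1027)
#' @export
glide_acceleration <- function(rho_tissue0, cdam, vair_per_mass,
                               d, v, p, rho_sw,
                               constants = physical_constants()) {
  stopifnot(all(v >= 0), all(d >= 0), all(abs(p) <= pi / 2 + 1e-12),
            all(cdam > 0), all(vair_per_mass >= 0))
  g <- constants$g
  rho_air <- constants$rho_air_surface
  press <- 1 + 0.1 * d
  rho_t <- tissue_density_at_depth(rho_tissue0, d, constants)
  vair_si <- vair_per_mass * 1e-6  # ml kg^-1 -> m^3 kg^-1
  drag <- -0.5 * cdam * rho_sw * v^2
  tissue <- (rho_sw / rho_t - 1) * g * sin(p)
  gas <- vair_si * g * sin(p) * (rho_sw - rho_air * press) / press
  drag + tissue + gas
}

#' Whale body mass from body length
#'
#' Humpback length-mass allometry `m = 0.016473 L^2.95 x 1000` (kg for L in
#' metres).
#'
#' @param L Body length, m.
#' @return Mass, kg.
#' @examples
#' mass_from_length(c(6, 15))
#' @export
mass_from_length <- function(L) {
  stopifnot(all(L > 0))
  0.016473 * L^2.95 * 1000
}

#' Body surface area from mass
#'
#' Mass-area allometry `A = 0.08 m^0.65` (m^2 for m in kg), derived from
#' bottlenose dolphins.
#'
#' @param m Mass, kg.
#' @return Surface area, m^2.
#' @examples
#' area_from_mass(mass_from_length(6))
#' @export
area_from_mass <- function(m) {
  stopifnot(all(m > 0))
  0.08 * m^0.65
}

#' Expected combined drag term
#'
#' The combined drag term treated as a single unknown in the force balance:
#' \eqn{C_D A / m}, m^2 kg^-1. Used to construct the informative drag prior
#' from a drag coefficient and allometric area and mass.
#'
#' @param C_D Drag coefficient (dimensionless); 0.0026 is the fin-whale value
#'   used for the prior.
#' @param A Reference surface area, m^2.
#' @param m Mass, kg.
#' @return \eqn{C_D A / m}, m^2 kg^-1.
#' @examples
#' expected_drag_term(0.0026, area_from_mass(3253), 3253)
#' @export
expected_drag_term <- function(C_D, A, m) {
  stopifnot(all(C_D > 0), all(A > 0), all(m > 0))
  C_D * A / m
}

#' Mass-specific total lung capacity
#'
#' Marine-mammal allometry `TLC = 0.10 m^0.96 x 1000` (ml), returned per unit
#' mass: `100 m^-0.04` ml kg^-1. Bounds the plausible diving gas volume.
#'
#' @param m Mass, kg.
#' @return Total lung capacity per unit mass, ml kg^-1.
#' @examples
#' lung_capacity_per_mass(mass_from_length(c(6, 15)))
#' @export
lung_capacity_per_mass <- function(m) {
  stopifnot(all(m > 0))
  0.10 * m^0.96 * 1000 / m
}

#' Lift-induced drag contribution to the combined drag term
#'
#' Both parasite and induced drag scale with speed squared, so induced drag
#' from lift generated by the flippers adds
#' \eqn{A_{Flipper} C_L^2 / (\pi \, AR \, m)} to the combined drag term of the
#' force balance.
#'
#' @param flipper_area Flipper surface area, m^2.
#' @param aspect_ratio Flipper aspect ratio (dimensionless).
#' @param C_L Lift coefficient (dimensionless; 0-0.9 from wind-tunnel
#'   measurements of a humpback flipper).
#' @param m Mass, kg.
#' @return Induced-drag term, m^2 kg^-1, additive to \eqn{C_D A m^{-1}}.
#' @examples
#' induced_drag_term(12.20, 5.67, 0.9, mass_from_length(12))
#' @export
induced_drag_term <- function(flipper_area, aspect_ratio, C_L, m) {
  stopifnot(all(flipper_area >= 0), all(aspect_ratio > 0), all(C_L >= 0),
            all(m > 0))
  flipper_area * C_L^2 / (pi * aspect_ratio * m)
}

#' Lipid fraction from tissue density
#'
#' Inverts the two-compartment mixing relation
#' `rho_tissue = rho_lipid * P + rho_lipid_free * (1 - P)` to obtain the body
#' lipid proportion `P` from an estimated tissue density. Lower tissue density
#' means a fatter animal.
#'
#' @param rho_tissue Tissue density, kg m^-3. Must lie between the lipid and
#'   lipid-free component densities.
#' @param mixture Output of [lipid_mixture()].
#' @return Lipid proportion in \[0, 1\].
#' @examples
#' lipid_fraction_from_density(c(1037.0, 1031.2))
#' @export
lipid_fraction_from_density <- function(rho_tissue, mixture = lipid_mixture()) {
  if (any(rho_tissue < mixture$rho_lipid | rho_tissue > mixture$rho_lipid_free))
    stop("tissue density outside the lipid / lipid-free component range [",
         mixture$rho_lipid, ", ", mixture$rho_lipid_free, "]")
  (mixture$rho_lipid_free - rho_tissue) /
    (mixture$rho_lipid_free - mixture$rho_lipid)
}

#' Tissue density from lipid fraction
#'
#' Forward direction of the mixing relation; inverse of
#' [lipid_fraction_from_density()].
#'
#' @param p_lipid Lipid proportion in \[0, 1\].
#' @param mixture Output of [lipid_mixture()].
#' @return Tissue density, kg m^-3.
#' @export
density_from_lipid_fraction <- function(p_lipid, mixture = lipid_mixture()) {
  stopifnot(all(p_lipid >= 0), all(p_lipid <= 1))
  mixture$rho_lipid * p_lipid + mixture$rho_lipid_free * (1 - p_lipid)
}
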