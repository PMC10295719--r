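#' Intramyocardial pressure of a myocardial layer
#'
#' Vessels embedded in the myocardium are compressed by a tissue pressure
#' proportional to the driving chamber pressure, graded linearly across the
#' wall: the subepicardium feels the smallest fraction and the subendocardium
#' the largest. Negative chamber pressures do not suck the wall open, so the
#' chamber pressure is floored at zero.
#'
#' @param gamma transmural fraction in `[0, 1]` (defaults across the wall are
#'   1/6, 1/2, 5/6 for subepicardium, mid-wall, subendocardium).
#' @param p_chamber driving chamber pressure (mmHg).
#' @return intramyocardial pressure in mmHg (vectorised).
#' @export
#' @examples
#' intramyocardial_pressure(5 / 6, 120)  # subendocardium at peak systole
intramyocardial_pressure <- function(gamma, p_chamber) {
  gamma * pmax(p_chamber, 0)
}

#' Epicardial stenosis element
#'
#' A focal narrowing characterised by diameter stenosis DS (1 minus the ratio
#' of minimal to reference lumen diameter). The stenotic lumen area scales as
#' `(1 - DS)^2` of the reference area; the element adds a flow-separation
#' (Bernoulli) loss of the same form as the valve orifice plus the extra
#' Poiseuille resistance of the narrowed throat.
#'
#' @param ds diameter stenosis, `0 <= ds < 1`.
#' @param ref_diameter_mm reference lumen diameter (mm).
#' @param length_mm throat length used for the viscous term (mm).
#' @return object of class `stenosis_element`.
#' @export
stenosis_element <- function(ds, ref_diameter_mm = 3, length_mm = 10) {
  if (ds < 0 || ds >= 1) stop("need 0 <= DS < 1", call. = FALSE)
  if (ref_diameter_mm <= 0) stop("reference diameter must be positive",
                                 call. = FALSE)
  structure(list(ds = ds, ref_diameter_mm = ref_diameter_mm,
                 length_mm = length_mm), class = "stenosis_element")
}

#' Lumped coefficients of a stenosis element
#'
#' @param elem a [stenosis_element()].
#' @param blood list with `rho` (kg/m^3) and `mu` (Pa s).
#' @return list with `b` (Bernoulli coefficient, mmHg s^2/mL^2) and `r_extra`
#'   (viscous resistance added by the narrowing, mmHg s/mL); both are exactly
#'   zero when DS = 0.
#' @export
stenosis_coefficients <- function(elem, blood) {
  mmhg <- 133.322
  if (elem$ds == 0) return(list(b = 0, r_extra = 0))
  r_ref <- elem$ref_diameter_mm / 2 * 1e-3
  a_ref <- pi * r_ref^2
  a_st <- a_ref * (1 - elem$ds)^2
  b_si <- 0.5 * blood$rho * (1 / a_st - 1 / a_ref)^2
  len <- elem$length_mm * 1e-3
  r_pois <- function(a) 8 * blood$mu * len * pi / a^2   # 8 mu l / (pi r^4)
  r_si <- r_pois(a_st) - r_pois(a_ref)
  list(b = b_si * 1e-12 / mmhg, r_extra = r_si * 1e-6 / mmhg)
}

#' Pressure drop across a stenosis
#'
#' \eqn{\Delta P = R_{throat} Q + B Q |Q|}: zero at zero flow and strictly
#' increasing in |Q|. Returned in mmHg for flow in mL/s.
#'
#' @param q flow (mL/s), vectorised.
#' @param elem a [stenosis_element()].
#' @param blood list with `rho`, `mu`.
#' @export
stenosis_pressure_drop <- function(q, elem, blood) {
  co <- stenosis_coefficients(elem, blood)
  co$r_extra * q + co$b * q * abs(q)
}

#' Per-layer coronary flows (reference implementation)
#'
#' Computes, for one coronary branch, the instantaneous inflow and outflow of
#' each of the three intramyocardial layers given the epicardial and venous
#' pressures and the driving chamber pressure. Each layer's intravascular
#' pressure is its stored (transmural) volume over its compliance plus the
#' layer's intramyocardial pressure, so systole squeezes the subendocardium
#' hardest. This R implementation mirrors the compiled network right-hand
#' side and is used to cross-check it.
#'
#' @param branch a branch list from `cv_config()$coronary$branches`.
#' @param gamma length-3 transmural fractions.
#' @param layer_volumes length-3 stored volumes (mL).
#' @param p_epi,p_ven epicardial and venous compartment pressures (mmHg).
#' @param p_chamber driving chamber pressure (mmHg).
#' @return list with vectors `q_in`, `q_out`, `dv` (per layer) and `p_layer`.
#' @export
coronary_layer_flows <- function(branch, gamma, layer_volumes, p_epi, p_ven,
                                 p_chamber) {
  p_im <- intramyocardial_pressure(gamma, p_chamber)
  p_layer <- layer_volumes / branch$c_layer + p_im
  q_in <- (p_epi - p_layer) / (branch$r_in * branch$r_mult)
  q_out <- (p_layer - p_ven) / branch$r_out
  list(q_in = q_in, q_out = q_out, dv = q_in - q_out, p_layer = p_layer)
}
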