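#' Aortic valve geometry
#'
#' Container for the geometric parameterization of a valve: effective orifice
#' areas in systole/diastole, nominal outflow-tract area, effective leaflet
#' length, and the three loss coefficients. The defaults describe a normal
#' aortic valve whose systolic orifice equals the outflow tract (no
#' flow-separation loss).
#'
#' @param eoa_systole_cm2,eoa_diastole_cm2 effective orifice areas (cm^2).
#' @param ado_cm2 nominal distal outflow-tract area (cm^2).
#' @param leaflet_length_cm effective leaflet length (cm).
#' @param alpha_r,alpha_b,alpha_l dimensionless coefficients of the viscous,
#'   Bernoulli and inertial terms (defaults 0.01, 1.0, 1.0).
#' @return object of class `valve_geometry`.
#' @export
valve_geometry <- function(eoa_systole_cm2 = 4.0, eoa_diastole_cm2 = 0.0,
                           ado_cm2 = 4.0, leaflet_length_cm = 1.0,
                           alpha_r = 0.01, alpha_b = 1.0, alpha_l = 1.0) {
  if (ado_cm2 <= 0 || leaflet_length_cm <= 0)
    stop("Ado and leaflet length must be positive", call. = FALSE)
  if (eoa_systole_cm2 < 0 || eoa_systole_cm2 > ado_cm2 ||
      eoa_diastole_cm2 < 0 || eoa_diastole_cm2 > ado_cm2)
    stop("need 0 <= EOA <= Ado", call. = FALSE)
  structure(list(eoa_systole_cm2 = eoa_systole_cm2,
                 eoa_diastole_cm2 = eoa_diastole_cm2,
                 ado_cm2 = ado_cm2, leaflet_length_cm = leaflet_length_cm,
                 alpha_r = alpha_r, alpha_b = alpha_b, alpha_l = alpha_l),
            class = "valve_geometry")
}

#' Trans-valvular resistance, Bernoulli coefficient and inertance
#'
#' Computes the three lumped parameters of the valve pressure-drop relation
#' from geometry:
#' \deqn{R = 8 \alpha_R \pi \mu l / EOA^2}
#' \deqn{B = (\alpha_B \rho / 2) (1/EOA - 1/A_{do})^2}
#' \deqn{L = (2 \alpha_L \rho / \sqrt{\pi}) (1/\sqrt{EOA} - 1/\sqrt{A_{do}})}
#' evaluated in SI and returned in internal units (mmHg, mL, s). When the
#' orifice equals the outflow tract (EOA = Ado) there is no flow-separation
#' loss and B = L = 0.
#'
#' @param geom a [valve_geometry()].
#' @param blood list with `rho` (kg/m^3) and `mu` (Pa s).
#' @param phase_eoa_cm2 the orifice area of the current valve phase (cm^2);
#'   must be strictly positive (a closed valve enforces zero flow instead of
#'   evaluating these formulas).
#' @return list with `R` (mmHg s/mL), `B` (mmHg s^2/mL^2), `L` (mmHg s^2/mL).
#' @export
#' @examples
#' vp <- valve_params(valve_geometry(), list(rho = 1050, mu = 0.0035), 1.0)
valve_params <- function(geom, blood, phase_eoa_cm2) {
  if (phase_eoa_cm2 <= 0)
    stop("valve closed: EOA = 0 requires the caller to enforce zero flow",
         call. = FALSE)
  if (phase_eoa_cm2 > geom$ado_cm2)
    stop("need phase EOA <= Ado", call. = FALSE)
  mmhg <- 133.322
  eoa <- phase_eoa_cm2 * 1e-4; ado <- geom$ado_cm2 * 1e-4
  l <- geom$leaflet_length_cm * 0.01
  r_si <- 8 * geom$alpha_r * pi * blood$mu * l / eoa^2
  b_si <- 0.5 * blood$rho * geom$alpha_b * (1 / eoa - 1 / ado)^2
  l_si <- (2 * blood$rho * geom$alpha_l / sqrt(pi)) *
    (1 / sqrt(eoa) - 1 / sqrt(ado))
  list(R = r_si * 1e-6 / mmhg, B = b_si * 1e-12 / mmhg, L = l_si * 1e-6 / mmhg)
}

#' Trans-valvular pressure drop
#'
#' \eqn{\Delta P = R Q + B Q |Q| + L \, dQ/dt}. The Bernoulli term is
#' sign-preserving (odd in Q), so reversed flow produces a reversed
#' separation loss.
#'
#' @param q flow (mL/s). @param dqdt flow derivative (mL/s^2).
#' @param params list with `R`, `B`, `L` as returned by [valve_params()].
#' @return pressure drop in mmHg (vectorised).
#' @export
valve_pressure_drop <- function(q, dqdt, params) {
  params$R * q + params$B * q * abs(q) + params$L * dqdt
}

#' Aortic valve phase schedule
#'
#' Advances the valve opening state by one time step and returns the current
#' effective orifice area. The valve opens when the upstream (ventricular)
#' pressure exceeds the downstream (aortic) pressure and closes when the
#' trans-valvular flow reverses during pressure decay; the EOA moves linearly
#' between the systolic and diastolic values over `ramp_s` seconds so the
#' pressure drop stays continuous in time. Under the AR preset the "closed"
#' orifice is the regurgitant diastolic EOA and flow continues (negatively)
#' through it; with a competent valve (diastolic EOA 0) closure enforces
#' exactly zero flow.
#'
#' @param valve_state list with `open` (logical) and `eoa` (cm^2); use
#'   `list(open = FALSE, eoa = 0)` to start in diastole.
#' @param p_upstream,p_downstream ventricular and aortic pressure (mmHg).
#' @param q current trans-valvular flow (mL/s).
#' @param preset a [disease_preset()] (or any list with the two EOA fields).
#' @param dt time step (s).
#' @param ramp_s ramp duration (s).
#' @return updated `valve_state` with fields `open`, `eoa` and `q_forced_zero`
#'   (TRUE when the caller must hold Q = 0).
#' @export
eoa_schedule <- function(valve_state, p_upstream, p_downstream, q, preset,
                         dt = 0.001, ramp_s = 0.005) {
  open <- isTRUE(valve_state$open)
  closing_snap <- FALSE
  if (!open && p_upstream > p_downstream + 0.05) open <- TRUE
  else if (open && q < 0 && p_upstream < p_downstream) {
    open <- FALSE
    # a competent valve (diastolic EOA = 0) seals right at the flow-reversal
    # trigger, where Q ~ 0 keeps the pressure drop continuous; a regurgitant
    # orifice is reached through the ramp instead
    closing_snap <- preset$eoa_diastole_cm2 <= 0
  }
  eoa <- valve_state$eoa
  if (closing_snap) {
    eoa <- 0
  } else {
    target <- if (open) preset$eoa_systole_cm2 else preset$eoa_diastole_cm2
    span <- abs(preset$eoa_systole_cm2 - preset$eoa_diastole_cm2)
    step <- span / ramp_s * dt
    eoa <- if (eoa < target) min(eoa + step, target) else max(eoa - step, target)
    if (eoa < 1e-12) eoa <- 0
  }
  list(open = open, eoa = eoa, q_forced_zero = (!open && eoa <= 0))
}
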