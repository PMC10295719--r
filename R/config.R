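#' @useDynLib corovalve, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optim fft setNames approx
#' @importFrom utils modifyList write.csv
NULL

# state vector layout; must match the enum in src/core.cpp
.state_names <- c(
  "v_la", "v_lv", "v_ra", "v_rv",
  "q_av",
  "v_ao",
  "q_ub", "v_uba", "v_ubc", "v_ubv",
  "q_lb", "v_lba", "v_lbc", "v_lbv",
  "v_pa", "v_pc", "v_pv",
  "q_lad",
  "v_epi_lad", "v_l1_lad", "v_l2_lad", "v_l3_lad", "v_ven_lad",
  "v_epi_lcx", "v_l1_lcx", "v_l2_lcx", "v_l3_lcx", "v_ven_lcx",
  "v_epi_rca", "v_l1_rca", "v_l2_rca", "v_l3_rca", "v_ven_rca")

.aux_names <- c(
  "p_lv", "p_la", "p_rv", "p_ra", "p_ao", "q_av_obs", "eoa", "valve_open",
  "q_mi", "q_pul", "q_lad_in", "q_lcx_in", "q_rca_in",
  "p_epi_lad", "p_epi_lcx", "p_epi_rca",
  "q_lad_l1", "q_lad_l2", "q_lad_l3", "q_cor_ven",
  "p_seg_in", "q_seg_out", "p_ao_root")

.volume_states <- .state_names[!grepl("^q_", .state_names)]

#' Build a model configuration
#'
#' Returns the full nested configuration of the closed-loop model: blood
#' properties, cycle timing, chamber elastances, systemic/pulmonary
#' compartments, the aortic valve geometry, the three coronary branches with
#' their intramyocardial layers, the autoregulation controller and the
#' distributed coronary-segment stand-in. Defaults describe a resting adult
#' with a normal aortic valve and reproduce the model's control operating
#' point (cardiac output near 4.9 L/min, aortic pressure near 115/76 mmHg,
#' mean LAD flow near 1.25 mL/s).
#'
#' @param ... named overrides merged recursively into the defaults, e.g.
#'   `cv_config(valve = list(scenario = "AS"))`.
#' @return an object of class `cv_config` (a nested list).
#' @export
#' @examples
#' cfg <- cv_config(timeline = list(n_cycles = 5))
#' cfg$valve$eoa_systole_cm2
cv_config <- function(...) {
  cfg <- list(
    blood = list(rho = 1050, mu = 0.0035),   # kg/m^3, Pa s
    timeline = list(period = 0.8, dt = 0.001, n_cycles = 20),
    chambers = list(
      lv = list(emax = 2.69, emin = 0.070, v0 = 10, onset = 0.00, dur = 0.61, peak_frac = 0.615),
      la = list(emax = 0.25, emin = 0.130, v0 = 5,  onset = 0.61, dur = 0.16, peak_frac = 0.5),
      rv = list(emax = 0.569, emin = 0.045, v0 = 10, onset = 0.00, dur = 0.61, peak_frac = 0.615),
      ra = list(emax = 0.22, emin = 0.110, v0 = 5,  onset = 0.61, dur = 0.16, peak_frac = 0.5)),
    valve = list(
      scenario = "control",
      eoa_systole_cm2 = 4.0, eoa_diastole_cm2 = 0.0,
      ado_cm2 = 4.0, leaflet_length_cm = 1.0,
      alpha_r = 0.01, alpha_b = 1.0, alpha_l = 1.0,
      r_base = 0.053, l_base = 0.004,      # root characteristic impedance / blood inertance
      ramp_s = 0.005, eoa_min_cm2 = 0.02,  # opening ramp and evaluation floor
      mitral_r = 0.004, tricuspid_r = 0.004, pulmonic_r = 0.006),
    systemic = list(
      c_ao = 0.832,
      upper = list(r_art = 0.06, l_art = 0.0008, c_art = 1.526,
                   r_cap = 2.337, c_cap = 0.4,
                   r_ven = 0.12, c_ven = 60, r_out = 0.04),
      lower = list(r_art = 0.035, l_art = 0.0005, c_art = 2.635,
                   r_cap = 1.365, c_cap = 0.7,
                   r_ven = 0.08, c_ven = 90, r_out = 0.03)),
    pulmonary = list(c_pa = 4.0, r_cap_in = 0.045, c_cap = 6.0,
                     r_cap_out = 0.025, c_ven = 9.0, r_out = 0.015),
    coronary = list(
      gamma = c(0.102, 0.537, 0.972),      # subepi, mid-wall, subendo
      branches = list(
        lad = list(r_prox = 1.0, l_prox = 0.002, c_epi = 0.001,
                   r_in = c(77.7, 73.5, 69.5), r_out = c(116.5, 116.5, 116.5),
                   c_layer = c(0.018, 0.018, 0.018),
                   c_ven = 0.35, r_v_out = 2.0, r_mult = 1.0,
                   drive = "lv", reference_flow = 1.27,
                   stenosis = list(ds = 0, ref_diameter_mm = 3, length_mm = 10)),
        lcx = list(r_prox = 1.4, l_prox = 0.002, c_epi = 0.0007,
                   r_in = c(108.7, 102.8, 97.3), r_out = c(163.2, 163.2, 163.2),
                   c_layer = c(0.0126, 0.0126, 0.0126),
                   c_ven = 0.25, r_v_out = 2.8, r_mult = 1.0,
                   drive = "lv", reference_flow = 0.91,
                   stenosis = list(ds = 0, ref_diameter_mm = 3, length_mm = 10)),
        rca = list(r_prox = 1.1, l_prox = 0.002, c_epi = 0.0009,
                   r_in = c(86.7, 82.0, 77.5), r_out = c(130.0, 130.0, 130.0),
                   c_layer = c(0.0162, 0.0162, 0.0162),
                   c_ven = 0.31, r_v_out = 2.2, r_mult = 1.0,
                   drive = "rv", reference_flow = 1.14,
                   stenosis = list(ds = 0, ref_diameter_mm = 3, length_mm = 10)))),
    autoreg = list(enabled = TRUE, gain = 0.5, tolerance = 0.01, max_iter = 50,
                   curve = list(pressure = c(20, 60, 140, 200),
                                flow = c(0.3, 1.0, 1.0, 1.5),
                                plateau = c(60, 140)),
                   shift = 1.0),
    segment = list(n_compartments = 20, length_mm = 60, inlet_radius_mm = 1.5,
                   c_node_ml_per_mmhg = 1e-6,
                   stenosis = list(ds = 0, at_compartment = 10)),
    init = list(venous_pressure = 6.29, arterial_pressure = 80,
                chamber_fill = 1.0),
    scenario = "control")
  overrides <- list(...)
  if (length(overrides)) cfg <- modifyList(cfg, overrides)
  structure(cfg, class = "cv_config")
}

#' @export
print.cv_config <- function(x, ...) {
  cat("<cv_config>\n")
  cat(sprintf("  scenario: %s (EOA systole %.2f cm^2, diastole %.2f cm^2)\n",
              x$valve$scenario, x$valve$eoa_systole_cm2, x$valve$eoa_diastole_cm2))
  cat(sprintf("  cycle: T = %.3g s, dt = %.3g s, %d cycles\n",
              x$timeline$period, x$timeline$dt, x$timeline$n_cycles))
  cat(sprintf("  autoregulation: %s (gain %.2f, tol %.1f%%)\n",
              if (isTRUE(x$autoreg$enabled)) "on" else "off",
              x$autoreg$gain, 100 * x$autoreg$tolerance))
  cat(sprintf("  segment: %d compartments, %.0f mm, r = %.2f mm, DS = %.0f%%\n",
              x$segment$n_compartments, x$segment$length_mm,
              x$segment$inlet_radius_mm, 100 * x$segment$stenosis$ds))
  invisible(x)
}

#' Validate a model configuration
#'
#' Checks positivity/ordering invariants (R > 0, C > 0, L >= 0,
#' E_max > E_min > 0, 0 <= EOA <= Ado, dt divides the period, transmural
#' gamma gradient increasing) and stops with an informative message on the
#' first violation.
#'
#' @param config a [cv_config()] object.
#' @return the config, invisibly, if valid.
#' @export
validate_config <- function(config) {
  tl <- config$timeline
  if (tl$period <= 0) stop("cycle period must be positive", call. = FALSE)
  if (tl$dt <= 0) stop("time step must be positive", call. = FALSE)
  steps <- tl$period / tl$dt
  if (abs(steps - round(steps)) > 1e-6 * steps)
    stop("time step must divide the cycle period", call. = FALSE)
  for (nm in names(config$chambers)) {
    ch <- config$chambers[[nm]]
    if (!(ch$emax > ch$emin && ch$emin > 0))
      stop(sprintf("chamber '%s': need E_max > E_min > 0", nm), call. = FALSE)
    if (ch$onset < 0 || ch$onset >= tl$period || ch$dur >= tl$period)
      stop(sprintf("chamber '%s': activation timing outside the cycle", nm),
           call. = FALSE)
  }
  v <- config$valve
  if (v$ado_cm2 <= 0 || v$leaflet_length_cm <= 0)
    stop("valve geometry: Ado and leaflet length must be positive", call. = FALSE)
  if (v$eoa_systole_cm2 < 0 || v$eoa_systole_cm2 > v$ado_cm2 ||
      v$eoa_diastole_cm2 < 0 || v$eoa_diastole_cm2 > v$ado_cm2)
    stop("valve geometry: need 0 <= EOA <= Ado", call. = FALSE)
  if (config$blood$rho <= 0 || config$blood$mu <= 0)
    stop("blood density and viscosity must be positive", call. = FALSE)
  g <- config$coronary$gamma
  if (!(g[1] >= 0 && g[1] < g[2] && g[2] < g[3] && g[3] <= 1))
    stop("intramyocardial gamma must increase from subepicardium to subendocardium",
         call. = FALSE)
  if (abs(g[2] - (g[1] + g[3]) / 2) > 1e-9)
    stop("mid-wall gamma must be the mean of the subepicardial and subendocardial values",
         call. = FALSE)
  for (nm in names(config$coronary$branches)) {
    b <- config$coronary$branches[[nm]]
    if (any(c(b$r_prox, b$r_in, b$r_out, b$r_v_out) <= 0))
      stop(sprintf("coronary branch '%s': resistances must be positive", nm),
           call. = FALSE)
    if (b$stenosis$ds < 0 || b$stenosis$ds >= 1)
      stop(sprintf("coronary branch '%s': need 0 <= DS < 1", nm), call. = FALSE)
  }
  if (config$segment$stenosis$ds < 0 || config$segment$stenosis$ds >= 1)
    stop("segment stenosis: need 0 <= DS < 1", call. = FALSE)
  invisible(config)
}

# flatten the nested config into the named numeric vector the C++ core reads
flatten_config <- function(config) {
  cfg <- config
  p <- c(rho = cfg$blood$rho, mu = cfg$blood$mu, period = cfg$timeline$period)
  for (nm in c("lv", "la", "rv", "ra")) {
    ch <- cfg$chambers[[nm]]
    v <- c(ch$emax, ch$emin, ch$v0, ch$onset, ch$dur, ch$peak_frac)
    names(v) <- paste0(nm, c("_emax", "_emin", "_v0", "_onset", "_dur", "_pf"))
    p <- c(p, v)
  }
  v <- cfg$valve
  p <- c(p,
         av_eoa_s = v$eoa_systole_cm2, av_eoa_d = v$eoa_diastole_cm2,
         av_ado = v$ado_cm2, av_leaflet = v$leaflet_length_cm,
         av_ar = v$alpha_r, av_ab = v$alpha_b, av_al = v$alpha_l,
         av_rbase = v$r_base, av_lbase = v$l_base,
         av_ramp = v$ramp_s, av_eoa_min = v$eoa_min_cm2,
         mi_r = v$mitral_r, tri_r = v$tricuspid_r, pul_r = v$pulmonic_r,
         c_ao = cfg$systemic$c_ao)
  for (side in c("ub", "lb")) {
    s <- cfg$systemic[[if (side == "ub") "upper" else "lower"]]
    v <- c(s$r_art, s$l_art, s$c_art, s$r_cap, s$c_cap, s$r_ven, s$c_ven, s$r_out)
    names(v) <- paste0(side, c("_rart", "_lart", "_cart", "_rcap", "_ccap",
                               "_rven", "_cven", "_rout"))
    p <- c(p, v)
  }
  pl <- cfg$pulmonary
  p <- c(p, c_pa = pl$c_pa, p_rc = pl$r_cap_in, c_pc = pl$c_cap,
         p_rcv = pl$r_cap_out, c_pvn = pl$c_ven, p_rout = pl$r_out,
         gam1 = cfg$coronary$gamma[1], gam2 = cfg$coronary$gamma[2],
         gam3 = cfg$coronary$gamma[3])
  for (nm in c("lad", "lcx", "rca")) {
    b <- cfg$coronary$branches[[nm]]
    st <- stenosis_coefficients(
      stenosis_element(b$stenosis$ds, b$stenosis$ref_diameter_mm,
                       b$stenosis$length_mm), cfg$blood)
    v <- c(b$r_prox, b$l_prox, b$c_epi,
           b$r_in[1], b$r_in[2], b$r_in[3],
           b$r_out[1], b$r_out[2], b$r_out[3],
           b$c_layer[1], b$c_layer[2], b$c_layer[3],
           b$c_ven, b$r_v_out, st$b, st$r_extra, b$r_mult,
           if (identical(b$drive, "rv")) 2 else 1)
    names(v) <- paste0(nm, c("_rprox", "_lprox", "_cepi",
                             "_rin1", "_rin2", "_rin3",
                             "_rout1", "_rout2", "_rout3",
                             "_cl1", "_cl2", "_cl3",
                             "_cven", "_rvout", "_sten_b", "_sten_rex",
                             "_rmult", "_drive"))
    p <- c(p, v)
  }
  eq <- segment_equivalents(segment_build(segment_geometry_from_config(cfg),
                                          cfg$blood))
  p <- c(p, seg_req = eq$req, seg_leq = eq$leq, seg_beq = eq$beq)
  p
}

#' Initial model state
#'
#' Builds a physiologically plausible starting state (chamber volumes,
#' compartment volumes from typical pressures, zero inertial flows). The model
#' is integrated to a periodic steady state before any quantity is reported,
#' so the starting state only fixes the total stressed blood volume of the
#' closed loop.
#'
#' @param config a [cv_config()] object.
#' @return named numeric state vector.
#' @export
initial_state <- function(config) {
  cfg <- config
  ini <- if (is.null(cfg$init)) list() else cfg$init
  pv <- if (is.null(ini$venous_pressure)) 4.9 else ini$venous_pressure
  pa <- if (is.null(ini$arterial_pressure)) 80 else ini$arterial_pressure
  fill <- if (is.null(ini$chamber_fill)) 1.0 else ini$chamber_fill
  s <- setNames(numeric(length(.state_names)), .state_names)
  s["v_la"] <- 47 * fill; s["v_lv"] <- 115 * fill
  s["v_ra"] <- 47 * fill; s["v_rv"] <- 115 * fill
  s["v_ao"] <- pa * cfg$systemic$c_ao
  up <- cfg$systemic$upper; lo <- cfg$systemic$lower
  s["v_uba"] <- pa * up$c_art; s["v_ubc"] <- 28 * up$c_cap
  s["v_ubv"] <- pv * up$c_ven
  s["v_lba"] <- pa * lo$c_art; s["v_lbc"] <- 28 * lo$c_cap
  s["v_lbv"] <- pv * lo$c_ven
  pl <- cfg$pulmonary
  s["v_pa"] <- 16 * pl$c_pa; s["v_pc"] <- 12 * pl$c_cap; s["v_pv"] <- 9 * pl$c_ven
  for (nm in c("lad", "lcx", "rca")) {
    b <- cfg$coronary$branches[[nm]]
    s[paste0("v_epi_", nm)] <- 75 * b$c_epi
    for (l in 1:3) s[paste0("v_l", l, "_", nm)] <- 30 * b$c_layer[l]
    s[paste0("v_ven_", nm)] <- 7 * b$c_ven
  }
  s
}

#' Disease presets for the aortic valve
#'
#' `control` is the normal valve (systolic EOA 4.0 cm^2, fully competent in
#' diastole); `AS` is severe stenosis (systolic EOA reduced to 1.0 cm^2, 25%
#' of normal); `AR` is severe regurgitation (diastolic EOA 0.3 cm^2).
#'
#' @param scenario one of `"control"`, `"AS"`, `"AR"`.
#' @return list with `scenario`, `eoa_systole_cm2`, `eoa_diastole_cm2`.
#' @export
#' @examples
#' disease_preset("AS")
disease_preset <- function(scenario = c("control", "AS", "AR")) {
  scenario <- match.arg(scenario)
  eoa <- switch(scenario,
                control = c(4.0, 0.0),
                AS = c(1.0, 0.0),
                AR = c(4.0, 0.3))
  list(scenario = scenario, eoa_systole_cm2 = eoa[1], eoa_diastole_cm2 = eoa[2])
}

#' Apply a valve disease preset to a configuration
#'
#' @param config a [cv_config()] object.
#' @param scenario `"control"`, `"AS"` or `"AR"`.
#' @return the modified configuration.
#' @export
apply_scenario <- function(config, scenario) {
  ps <- disease_preset(scenario)
  config$valve$scenario <- ps$scenario
  config$valve$eoa_systole_cm2 <- ps$eoa_systole_cm2
  config$valve$eoa_diastole_cm2 <- ps$eoa_diastole_cm2
  config$scenario <- ps$scenario
  config
}

#' Read / write a configuration as YAML
#'
#' @param path file path.
#' @return `read_config` returns a `cv_config`; `write_config` returns the
#'   path invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- modifyList(unclass(cv_config()), raw)
  structure(cfg, class = "cv_config")
}

#' @rdname read_config
#' @param config a [cv_config()] object.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
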