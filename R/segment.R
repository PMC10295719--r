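#' Distributed coronary-segment geometry
#'
#' The epicardial segment of interest (the LAD trunk in the study setup) is
#' represented by a chain of `n` short compartments, each with the Poiseuille
#' resistance and blood inertance of its slice of lumen and a small numerical
#' nodal capacitance that makes the flow-in/pressure-out boundary pair
#' solvable. The wall is rigid: the capacitance is a solver regularisation
#' (default 1e-6 mL/mmHg), not a physiological compliance. An optional focal
#' stenosis narrows one compartment and adds a flow-separation loss.
#'
#' @param n_compartments number of compartments (>= 3).
#' @param length_mm total segment length (mm).
#' @param inlet_radius_mm lumen radius (mm), uniform along the segment.
#' @param c_node_ml_per_mmhg numerical nodal capacitance (mL/mmHg).
#' @param stenosis `NULL` or `list(ds =, at_compartment =)`.
#' @return object of class `segment_geometry`.
#' @export
segment_geometry <- function(n_compartments = 20, length_mm = 60,
                             inlet_radius_mm = 1.5,
                             c_node_ml_per_mmhg = 1e-6, stenosis = NULL) {
  if (n_compartments < 3) stop("need at least 3 compartments", call. = FALSE)
  if (inlet_radius_mm <= 0 || length_mm <= 0)
    stop("segment dimensions must be positive", call. = FALSE)
  if (!is.null(stenosis) && (stenosis$ds < 0 || stenosis$ds >= 1))
    stop("segment stenosis: need 0 <= DS < 1", call. = FALSE)
  structure(list(n = n_compartments, length_mm = length_mm,
                 inlet_radius_mm = inlet_radius_mm,
                 c_node = c_node_ml_per_mmhg, stenosis = stenosis),
            class = "segment_geometry")
}

segment_geometry_from_config <- function(config) {
  st <- config$segment$stenosis
  segment_geometry(config$segment$n_compartments, config$segment$length_mm,
                   config$segment$inlet_radius_mm,
                   config$segment$c_node_ml_per_mmhg,
                   if (!is.null(st) && st$ds > 0) st else NULL)
}

#' Build the runnable segment state
#'
#' Converts a [segment_geometry()] into the per-compartment R/L/B vectors
#' (internal mmHg-mL-s units) plus initial nodal pressures and link flows.
#'
#' @param geom a [segment_geometry()].
#' @param blood list with `rho` (kg/m^3), `mu` (Pa s).
#' @param p0 initial uniform pressure (mmHg). @param q0 initial flow (mL/s).
#' @return list with `n`, `R`, `L`, `B`, `Cn`, `P`, `Q`, `radius_mm`,
#'   `dx_mm` (class `cv_segment`).
#' @export
segment_build <- function(geom, blood, p0 = 80, q0 = 0) {
  mmhg <- 133.322
  n <- geom$n
  dx <- geom$length_mm / n * 1e-3                  # m
  r <- rep(geom$inlet_radius_mm * 1e-3, n)         # m
  B <- numeric(n)
  if (!is.null(geom$stenosis) && geom$stenosis$ds > 0) {
    k <- geom$stenosis$at_compartment
    if (is.null(k) || k < 1 || k > n)
      stop("stenosis compartment index out of range", call. = FALSE)
    a_ref <- pi * r[k]^2
    r[k] <- r[k] * (1 - geom$stenosis$ds)
    a_st <- pi * r[k]^2
    B[k] <- 0.5 * blood$rho * (1 / a_st - 1 / a_ref)^2 * 1e-12 / mmhg
  }
  R <- 8 * blood$mu * dx / (pi * r^4) * 1e-6 / mmhg
  L <- blood$rho * dx / (pi * r^2) * 1e-6 / mmhg
  structure(list(n = n, R = R, L = L, B = B, Cn = rep(geom$c_node, n),
                 P = rep(p0, n), Q = rep(q0, n),
                 radius_mm = r * 1e3, dx_mm = dx * 1e3),
            class = "cv_segment")
}

# lumped equivalents used when the closed loop runs without the distributed
# segment (series resistance/inertance, summed Bernoulli coefficients)
segment_equivalents <- function(seg) {
  list(req = sum(seg$R), leq = sum(seg$L), beq = sum(seg$B))
}

#' Advance the segment one time step
#'
#' Implicit (backward-Euler) update of the distributed chain under an imposed
#' inlet flow and outlet pressure — the role the 3D sub-model plays in the
#' partitioned coupling. Returns the computed inlet pressure and outlet flow,
#' the boundary data handed back to the closed-loop model.
#'
#' @param seg a `cv_segment` from [segment_build()].
#' @param q_in imposed inlet flow (mL/s).
#' @param p_out imposed outlet pressure (mmHg).
#' @param dt time step (s).
#' @return list with `p_in` (mmHg), `q_out` (mL/s) and the updated `seg`.
#' @export
segment_step <- function(seg, q_in, p_out, dt = 0.001) {
  out <- seg_step_cpp(unclass(seg), q_in, p_out, dt)
  new_seg <- seg
  new_seg[c("n", "R", "L", "B", "Cn", "P", "Q")] <-
    out$seg[c("n", "R", "L", "B", "Cn", "P", "Q")]
  list(p_in = out$p_in, q_out = out$q_out, seg = new_seg)
}

#' Wall shear stress waveforms along the segment
#'
#' Poiseuille closure for the stand-in segment: \eqn{\tau = 4 \mu Q /(\pi r^3)},
#' signed by the instantaneous flow direction, evaluated per compartment.
#'
#' @param seg_q matrix of per-compartment flows (rows = time samples,
#'   columns = compartments), in mL/s.
#' @param radius_mm per-compartment radii (mm), recycled if scalar.
#' @param mu dynamic viscosity (Pa s).
#' @return matrix of wall shear stress in Pa, same shape as `seg_q`.
#' @export
#' @examples
#' wall_shear_waveform(matrix(1.25, 1, 1), 1.5, 0.0035)  # ~1.65 Pa
wall_shear_waveform <- function(seg_q, radius_mm, mu = 0.0035) {
  seg_q <- as.matrix(seg_q)
  r <- rep(radius_mm, length.out = ncol(seg_q)) * 1e-3
  sweep(seg_q * 1e-6, 2, 4 * mu / (pi * r^3), `*`)
}
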