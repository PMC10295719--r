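#' Coronary autoregulation pressure-flow curve
#'
#' Piecewise-linear relation between coronary perfusion pressure and the
#' normalized target mean flow: a rising limb at low pressure, a plateau at
#' 1.0 across the autoregulatory range, and a rising limb above it.
#' Normalized flow 1.0 corresponds to each branch's resting reference flow;
#' valve disease shifts the whole flow axis up multiplicatively.
#'
#' @param pressure,flow knot coordinates (mmHg, normalized flow); flow must be
#'   non-decreasing.
#' @param plateau pressure range (mmHg) of the autoregulatory plateau.
#' @return object of class `pq_curve`.
#' @export
pq_curve <- function(pressure = c(20, 60, 140, 200),
                     flow = c(0.3, 1.0, 1.0, 1.5),
                     plateau = c(60, 140)) {
  if (length(pressure) != length(flow) || length(pressure) < 2)
    stop("need matching pressure/flow knots", call. = FALSE)
  if (is.unsorted(pressure, strictly = TRUE))
    stop("pressure knots must be strictly increasing", call. = FALSE)
  if (any(diff(flow) < 0))
    stop("target flow must be non-decreasing in pressure", call. = FALSE)
  structure(list(pressure = pressure, flow = flow, plateau = plateau),
            class = "pq_curve")
}

pq_curve_from_config <- function(config) {
  cu <- config$autoreg$curve
  pq_curve(cu$pressure, cu$flow, cu$plateau)
}

#' Target flow from the autoregulation curve
#'
#' Linear interpolation between knots, scaled by the demand shift factor.
#' Pressures below the lowest knot are clamped to it with a warning;
#' pressures above the highest knot are clamped to the top knot.
#'
#' @param perfusion_pressure perfusion pressure (mmHg, >= 0).
#' @param curve a [pq_curve()].
#' @param shift multiplicative upward shift of the flow axis (>= 1 under
#'   valve disease; 1 for control).
#' @return normalized target flow (vectorised).
#' @export
#' @examples
#' target_flow(100, pq_curve())          # on the plateau -> 1
#' target_flow(100, pq_curve(), 1.3)     # shifted demand -> 1.3
target_flow <- function(perfusion_pressure, curve, shift = 1) {
  if (any(perfusion_pressure < 0))
    stop("perfusion pressure must be non-negative", call. = FALSE)
  if (any(perfusion_pressure < min(curve$pressure)))
    warning("perfusion pressure below the lowest knot; clamping")
  f <- approx(curve$pressure, curve$flow, xout = perfusion_pressure,
              rule = 2)$y
  shift * f
}

#' Pressure-volume area of a ventricular loop
#'
#' Decomposes one steady-state pressure-volume loop into stroke work (the
#' signed area enclosed by the loop, by the shoelace formula) and potential
#' energy (the triangle between the end-systolic point, the unstressed
#' volume and the volume axis). Their sum, the pressure-volume area, indexes
#' myocardial oxygen demand and drives the autoregulation shift under valve
#' disease.
#'
#' @param volume,pressure loop samples over exactly one cycle (mL, mmHg); the
#'   loop is closed between the last and first samples.
#' @param v0 unstressed volume of the chamber (mL).
#' @return list with `stroke_work`, `potential_energy`, `pva` (mmHg mL) and
#'   the end-systolic point (`v_es`, `p_es`).
#' @export
#' @examples
#' # rectangular 40 mL x 80 mmHg loop traversed counterclockwise in (V, P)
#' v <- c(120, 120, 80, 80); p <- c(10, 90, 90, 10)
#' pva_from_loop(v, p, v0 = 10)$stroke_work  # 3200
pva_from_loop <- function(volume, pressure, v0 = 0) {
  if (length(volume) != length(pressure) || length(volume) < 3)
    stop("need matching volume/pressure samples of one closed loop",
         call. = FALSE)
  v2 <- c(volume[-1], volume[1]); p2 <- c(pressure[-1], pressure[1])
  sw <- abs(sum(volume * p2 - v2 * pressure)) / 2
  # end-systole: maximal pressure-to-stressed-volume ratio
  stressed <- pmax(volume - v0, 1e-9)
  ies <- which.max(pressure / stressed)
  pe <- 0.5 * pressure[ies] * (volume[ies] - v0)
  pe <- max(pe, 0)
  list(stroke_work = sw, potential_energy = pe, pva = sw + pe,
       v_es = volume[ies], p_es = pressure[ies])
}

#' Autoregulation shift factor from perfusion demand
#'
#' The ratio of diseased to control pressure-volume area; applied
#' multiplicatively to the flow axis of the P-Q curve so that resting
#' coronary flow scales with myocardial demand.
#'
#' @param pva_disease,pva_control pressure-volume areas (mmHg mL, > 0).
#' @return dimensionless multiplier.
#' @export
shift_factor <- function(pva_disease, pva_control) {
  if (pva_disease <= 0 || pva_control <= 0)
    stop("pressure-volume areas must be positive", call. = FALSE)
  pva_disease / pva_control
}

#' Linear negative-feedback update of microvascular resistance
#'
#' One controller iteration: the arteriolar resistance multiplier of each
#' branch moves proportionally to the relative flow error,
#' `mult_new = mult_old * (1 + gain * (q_measured / q_target - 1))`,
#' so flow above target constricts (raises resistance) and flow below target
#' dilates. Multipliers are kept within physiological dilation/constriction
#' bounds `[0.1, 10]` with a warning when a bound is hit.
#'
#' @param q_measured,q_target measured and target mean branch flows (mL/s),
#'   vectorised over branches.
#' @param mult current multipliers.
#' @param gain feedback gain per iteration (> 0).
#' @return updated multipliers.
#' @export
#' @examples
#' update_resistances(1.5, 1.0, 1, gain = 0.5)  # flow too high -> constrict
update_resistances <- function(q_measured, q_target, mult, gain = 0.5) {
  if (gain <= 0) stop("feedback gain must be positive", call. = FALSE)
  new <- mult * (1 + gain * (q_measured / q_target - 1))
  if (any(new < 0.1 | new > 10))
    warning("microvascular resistance multiplier clamped to [0.1, 10]")
  pmin(pmax(new, 0.1), 10)
}

#' Run coronary flow autoregulation to convergence
#'
#' Iterates cardiac cycles, adjusting each branch's arteriolar resistance
#' multiplier by linear negative feedback until every branch's mean flow is
#' within the controller tolerance of its target. The target is the branch
#' reference flow times the P-Q curve value at the current perfusion
#' pressure (cycle-mean epicardial pressure distal to any stenosis minus
#' cycle-mean right-atrial pressure) times the demand `shift`. If the flow
#' error grows for three consecutive iterations the gain is halved with a
#' warning.
#'
#' @param config a [cv_config()].
#' @param shift demand shift factor (default from the config).
#' @param init,valve warm-start state (recommended: a settled run).
#' @param cycles_per_iter cardiac cycles integrated per controller iteration.
#' @return list with the updated `config` (converged multipliers), final
#'   `run` (a `cv_run` at the converged resistances), `multipliers`,
#'   `history` (per-iteration flows and errors), `converged`, `iterations`.
#' @export
autoregulate <- function(config, shift = config$autoreg$shift, init = NULL,
                         valve = NULL, cycles_per_iter = 2) {
  ar <- config$autoreg
  curve <- pq_curve_from_config(config)
  branches <- names(config$coronary$branches)
  mult <- vapply(config$coronary$branches, function(b) b$r_mult, numeric(1))
  gain <- ar$gain
  y <- init; v <- valve
  history <- NULL
  err_prev <- Inf; n_growing <- 0
  converged <- FALSE
  run <- NULL
  for (it in seq_len(ar$max_iter)) {
    for (i in seq_along(branches))
      config$coronary$branches[[i]]$r_mult <- mult[i]
    run <- run_cycles(config, n_cycles = cycles_per_iter, init = y,
                      valve = v, record = "last")
    y <- run$state; v <- run$valve
    sm <- run$summaries[nrow(run$summaries), ]
    q_meas <- c(lad = sm$q_lad, lcx = sm$q_lcx, rca = sm$q_rca)
    p_perf <- c(lad = sm$p_epi_lad, lcx = sm$p_epi_lcx, rca = sm$p_epi_rca) -
      sm$p_ra
    refs <- vapply(config$coronary$branches, function(b) b$reference_flow,
                   numeric(1))
    q_tgt <- refs * target_flow(pmax(p_perf, 0), curve, shift)
    rel_err <- abs(q_meas / q_tgt - 1)
    history <- rbind(history,
                     c(iter = it, q_meas, target = q_tgt, err = max(rel_err)))
    if (all(rel_err < ar$tolerance)) { converged <- TRUE; break }
    if (max(rel_err) > err_prev) {
      n_growing <- n_growing + 1
      if (n_growing >= 3) {
        gain <- gain / 2
        n_growing <- 0
        warning("autoregulation error increasing; halving feedback gain")
      }
    } else n_growing <- 0
    err_prev <- max(rel_err)
    mult <- update_resistances(q_meas, q_tgt, mult, gain)
  }
  if (!converged)
    warning(sprintf("autoregulation did not converge in %d iterations",
                    ar$max_iter))
  rownames(history) <- NULL
  list(config = config, run = run, multipliers = mult,
       history = as.data.frame(history), converged = converged,
       iterations = if (is.null(history)) 0L else nrow(history))
}
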