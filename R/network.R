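#' Right-hand side of the closed-loop network
#'
#' Evaluates the governing ordinary differential equations of the 0D model at
#' one instant: every compliance volume changes by net inflow minus outflow,
#' and every inertial flow accelerates under the pressure difference minus
#' resistive and Bernoulli losses over the inertance. The aortic valve state
#' (current effective orifice area, open/closed) is held fixed during the
#' evaluation, as it is across one integrator step.
#'
#' @param state named state vector (see [initial_state()]).
#' @param t time (s).
#' @param config a [cv_config()].
#' @param eoa effective aortic orifice area right now (cm^2); default: the
#'   configured systolic EOA (valve open).
#' @param valve_closed logical; when TRUE the aortic valve enforces zero flow.
#' @param seg_boundary `NULL`, or `list(p_in =, q_out =)` with the
#'   segment-returned boundary data when the distributed segment is coupled in.
#' @return list with `dy` (state derivative) and `aux` (named observables:
#'   pressures, valve flow, branch inflows, per-layer LAD inflows).
#' @export
#' @examples
#' cfg <- cv_config()
#' d <- network_derivatives(initial_state(cfg), 0, cfg)
#' names(d$aux)[1:5]
network_derivatives <- function(state, t, config, eoa = NULL,
                                valve_closed = FALSE, seg_boundary = NULL) {
  if (length(state) != length(.state_names))
    stop(sprintf("state vector must have length %d", length(.state_names)),
         call. = FALSE)
  if (is.null(eoa)) eoa <- config$valve$eoa_systole_cm2
  p <- flatten_config(config)
  coupled <- !is.null(seg_boundary)
  out <- cv_derivs_cpp(as.numeric(state), t, p, eoa, valve_closed, coupled,
                       if (coupled) seg_boundary$p_in else 0,
                       if (coupled) seg_boundary$q_out else 0)
  names(out$dy) <- .state_names
  out
}

#' One classical fourth-order Runge-Kutta step
#'
#' Explicit 4-stage update; no implicit solves. The derivative function is
#' called at `t`, twice at `t + dt/2`, and at `t + dt`.
#'
#' @param y state vector. @param t time. @param dt step size (> 0).
#' @param f derivative function `f(y, t, ...)` returning dy/dt.
#' @param ... passed through to `f`.
#' @return the state at `t + dt`.
#' @export
#' @examples
#' rk4_step(1, 0, 0.001, function(y, t) -y)  # exp(-0.001) to machine precision
rk4_step <- function(y, t, dt, f, ...) {
  if (dt <= 0) stop("step size must be positive", call. = FALSE)
  k1 <- f(y, t, ...)
  k2 <- f(y + dt / 2 * k1, t + dt / 2, ...)
  k3 <- f(y + dt / 2 * k2, t + dt / 2, ...)
  k4 <- f(y + dt * k3, t + dt, ...)
  out <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  if (any(!is.finite(out)))
    stop(sprintf("integration failure: non-finite state at t = %.6g", t),
         call. = FALSE)
  out
}

# summaries of one recorded cycle (trace rows covering exactly one period)
cycle_summary <- function(trace) {
  co <- mean(trace[, "q_av_obs"]) * 60 / 1000
  c(co = co,
    sbp = max(trace[, "p_ao_root"]), dbp = min(trace[, "p_ao_root"]),
    map = mean(trace[, "p_ao_root"]),
    q_lad = mean(trace[, "q_lad_in"]),
    q_lcx = mean(trace[, "q_lcx_in"]),
    q_rca = mean(trace[, "q_rca_in"]),
    p_ra = mean(trace[, "p_ra"]),
    p_epi_lad = mean(trace[, "p_epi_lad"]),
    p_epi_lcx = mean(trace[, "p_epi_lcx"]),
    p_epi_rca = mean(trace[, "p_epi_rca"]),
    stroke_volume = max(trace[, "v_lv"]) - min(trace[, "v_lv"]))
}

.trace_colnames <- function() c("time_s", .state_names, .aux_names)

#' Run the closed-loop model for a number of cardiac cycles
#'
#' Integrates the full network with the explicit fourth-order Runge-Kutta
#' method at the configured time step, advancing the aortic-valve state
#' machine once per step. Per-cycle summaries (cardiac output, systolic and
#' diastolic aortic pressure, mean coronary flows) are reported, and periodic
#' steady state is flagged when all summaries change by less than `tol`
#' between consecutive cycles.
#'
#' @param config a [cv_config()].
#' @param n_cycles number of cardiac cycles (default from the config).
#' @param init optional initial state (default [initial_state()]).
#' @param valve optional initial valve state `list(open =, eoa =)`.
#' @param record `"last"` keeps the final cycle's trace, `"all"` every cycle,
#'   `"none"` summaries only.
#' @param tol relative change defining periodic steady state (default 0.001).
#' @return object of class `cv_run`: list with `trace` (matrix, columns
#'   `time_s`, states, observables), `summaries` (one row per cycle), `state`,
#'   `valve`, `converged`, `config`.
#' @export
#' @examples
#' \donttest{
#' run <- run_cycles(cv_config(), n_cycles = 3, record = "last")
#' run$summaries[, c("co", "sbp", "dbp")]
#' }
run_cycles <- function(config, n_cycles = config$timeline$n_cycles,
                       init = NULL, valve = NULL, record = c("last", "all", "none"),
                       tol = 0.001) {
  record <- match.arg(record)
  validate_config(config)
  p <- flatten_config(config)
  dt <- config$timeline$dt
  steps <- round(config$timeline$period / dt)
  y <- if (is.null(init)) initial_state(config) else init
  v <- if (is.null(valve)) list(open = FALSE, eoa = config$valve$eoa_diastole_cm2)
       else valve
  summaries <- NULL
  traces <- list()
  t0 <- 0
  converged <- FALSE
  for (cyc in seq_len(n_cycles)) {
    keep <- record == "all" || (record == "last" && cyc == n_cycles) ||
      !converged  # summaries always need the trace
    out <- cv_advance_cpp(as.numeric(y), p, v, steps, dt, t0,
                          FALSE, NULL, TRUE)
    colnames(out$trace) <- .trace_colnames()
    y <- setNames(out$state, .state_names)
    v <- out$valve
    t0 <- out$t
    sm <- cycle_summary(out$trace)
    summaries <- rbind(summaries, sm)
    if (record == "all" || cyc == n_cycles) traces[[length(traces) + 1]] <- out$trace
    if (cyc > 1) {
      prev <- summaries[cyc - 1, c("co", "sbp", "dbp", "q_lad", "q_lcx", "q_rca")]
      now <- summaries[cyc, c("co", "sbp", "dbp", "q_lad", "q_lcx", "q_rca")]
      converged <- all(abs(now - prev) <= tol * pmax(abs(prev), 1e-6))
    }
  }
  rownames(summaries) <- NULL
  structure(list(trace = if (record == "none") NULL
                         else do.call(rbind, traces),
                 summaries = as.data.frame(summaries),
                 state = y, valve = v, t = t0,
                 converged = converged, config = config),
            class = "cv_run")
}

#' @export
print.cv_run <- function(x, ...) {
  n <- nrow(x$summaries)
  last <- x$summaries[n, ]
  cat(sprintf("<cv_run> %d cycles (%s periodic steady state)\n", n,
              if (isTRUE(x$converged)) "reached" else "not yet at"))
  cat(sprintf("  CO %.2f L/min | BP %.1f/%.1f mmHg | Q lad/lcx/rca %.2f/%.2f/%.2f mL/s\n",
              last$co, last$sbp, last$dbp, last$q_lad, last$q_lcx, last$q_rca))
  invisible(x)
}

# last full cycle of a recorded trace
last_cycle <- function(run) {
  steps <- round(run$config$timeline$period / run$config$timeline$dt)
  tr <- run$trace
  tr[(nrow(tr) - steps + 1):nrow(tr), , drop = FALSE]
}
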