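#' Calibration targets
#'
#' The six resting summaries the model is calibrated against: cardiac output,
#' systolic and diastolic aortic pressure, and the mean flows of the three
#' large coronary arteries. Defaults are population means measured in normal
#' subjects (CO 5.19 L/min, SBP 113.0 mmHg, DBP 74.0 mmHg, LAD 1.27, RCA
#' 1.14, LCX 0.91 mL/s).
#'
#' @param co,sbp,dbp,q_lad,q_rca,q_lcx target values.
#' @param weights optional per-target weights (default equal).
#' @return named list of class `calibration_targets`.
#' @export
calibration_targets <- function(co = 5.19, sbp = 113.0, dbp = 74.0,
                                q_lad = 1.27, q_rca = 1.14, q_lcx = 0.91,
                                weights = NULL) {
  tg <- c(co = co, sbp = sbp, dbp = dbp, q_lad = q_lad, q_rca = q_rca,
          q_lcx = q_lcx)
  if (is.null(weights)) weights <- rep(1, length(tg))
  structure(list(targets = tg, weights = weights),
            class = "calibration_targets")
}

# the six calibrated summaries of a settled run
model_summaries <- function(run) {
  sm <- run$summaries[nrow(run$summaries), ]
  c(co = sm$co, sbp = sm$sbp, dbp = sm$dbp,
    q_lad = sm$q_lad, q_rca = sm$q_rca, q_lcx = sm$q_lcx)
}

# free parameters are multipliers on config entries; theta is unconstrained
# and mapped into [lo, hi] through a logistic in log space (theta = 0 -> the
# geometric mid-point, which equals 1 for hi = 1/lo)
theta_to_mult <- function(theta, bounds) {
  p <- 1 / (1 + exp(-theta))
  exp(log(bounds[1]) + p * (log(bounds[2]) - log(bounds[1])))
}

apply_free_params <- function(config, theta, bounds = c(0.7, 1 / 0.7)) {
  m <- theta_to_mult(theta, bounds)
  names(m) <- names(theta)
  for (nm in names(m)) {
    f <- m[[nm]]
    config <- switch(nm,
      r_upper = { config$systemic$upper$r_cap <-
                    config$systemic$upper$r_cap * f; config },
      r_lower = { config$systemic$lower$r_cap <-
                    config$systemic$lower$r_cap * f; config },
      c_art = {
        config$systemic$c_ao <- config$systemic$c_ao * f
        config$systemic$upper$c_art <- config$systemic$upper$c_art * f
        config$systemic$lower$c_art <- config$systemic$lower$c_art * f
        config
      },
      emax_lv = { config$chambers$lv$emax <- config$chambers$lv$emax * f; config },
      emax_rv = { config$chambers$rv$emax <- config$chambers$rv$emax * f; config },
      r_lad = , r_lcx = , r_rca = {
        b <- sub("^r_", "", nm)
        br <- config$coronary$branches[[b]]
        br$r_prox <- br$r_prox * f
        br$r_in <- br$r_in * f
        br$r_out <- br$r_out * f
        config$coronary$branches[[b]] <- br
        config
      },
      stop(sprintf("unknown free parameter '%s'", nm), call. = FALSE))
  }
  config
}

#' Calibrate the model by Nelder-Mead
#'
#' Minimizes the root-mean-squared relative error between the model's
#' periodic-steady-state summaries and the targets over a set of named
#' multiplicative free parameters (searched on the log scale). Each objective
#' evaluation integrates the closed loop warm-started from the running state
#' until the per-cycle summaries settle (at most `n_cycles` cycles). After
#' the simplex search, if `polish_autoreg` is on, the coronary feedback
#' controller trims the branch resistance multipliers so mean coronary flows
#' track the targets within the controller tolerance.
#'
#' @param config starting [cv_config()].
#' @param free character vector of free-parameter names among `r_upper`,
#'   `r_lower`, `c_art`, `emax_lv`, `emax_rv`, `r_lad`, `r_lcx`, `r_rca`.
#' @param targets a [calibration_targets()].
#' @param bounds length-2 multiplicative bounds for every free parameter
#'   (default `c(0.85, 1/0.85)`): the search stays in a physiological
#'   neighbourhood of the literature-based defaults rather than re-deriving
#'   the model from scratch.
#' @param maxit Nelder-Mead iteration cap.
#' @param n_cycles cycles per objective evaluation.
#' @param polish_autoreg run the flow controller after the simplex search.
#' @return object of class `cv_calibration`: `config` (fitted), `achieved`,
#'   `targets`, `par` (fitted multipliers), `objective` (final RMSE),
#'   `objective_trace`, `iterations`, `converged`, `run` (final settled run).
#' @export
calibrate <- function(config,
                      free = c("r_upper", "r_lower", "c_art",
                               "emax_lv", "emax_rv",
                               "r_lad", "r_lcx", "r_rca"),
                      targets = calibration_targets(),
                      bounds = c(0.85, 1 / 0.85),
                      maxit = 150, n_cycles = 14, polish_autoreg = TRUE) {
  if (!length(free)) stop("free parameter list is empty", call. = FALSE)
  tg <- targets$targets; wt <- targets$weights
  # persistent warm start across objective evaluations
  env <- new.env()
  base <- run_cycles(config, n_cycles = 12, record = "last")
  env$y <- base$state; env$v <- base$valve
  trace <- numeric(0)
  objective <- function(theta) {
    names(theta) <- free
    cfg <- apply_free_params(config, theta, bounds)
    run <- try(run_cycles(cfg, n_cycles = n_cycles, init = env$y,
                          valve = env$v, record = "last"), silent = TRUE)
    if (inherits(run, "try-error")) return(1e3)
    sm <- model_summaries(run)
    if (any(!is.finite(sm))) return(1e3)
    err <- sqrt(mean((wt * (sm - tg) / tg)^2))
    trace <<- c(trace, err)
    err
  }
  theta0 <- setNames(rep(0, length(free)), free)
  f0 <- objective(theta0)
  fit <- if (f0 < 1e-6) {
    list(par = theta0, value = f0, counts = c(1, NA), convergence = 0)
  } else {
    optim(theta0, objective, method = "Nelder-Mead",
          control = list(maxit = maxit, reltol = 1e-4))
  }
  if (!is.finite(fit$value) || is.na(fit$value))
    stop("objective not finite at the returned simplex", call. = FALSE)
  names(fit$par) <- free
  fitted_cfg <- apply_free_params(config, fit$par, bounds)
  run <- run_cycles(fitted_cfg, n_cycles = 12, init = env$y, valve = env$v,
                    record = "last")
  if (polish_autoreg) {
    # retarget the flow controller at the coronary calibration targets
    for (b in c("lad", "lcx", "rca"))
      fitted_cfg$coronary$branches[[b]]$reference_flow <-
        tg[[paste0("q_", b)]]
    ar <- autoregulate(fitted_cfg, init = run$state, valve = run$valve)
    fitted_cfg <- ar$config
    run <- run_cycles(fitted_cfg, n_cycles = 6, init = ar$run$state,
                      valve = ar$run$valve, record = "last")
  }
  achieved <- model_summaries(run)
  structure(list(config = fitted_cfg, achieved = achieved, targets = tg,
                 par = theta_to_mult(fit$par, bounds), objective = fit$value,
                 objective_trace = trace,
                 iterations = unname(fit$counts[1]),
                 converged = fit$convergence == 0, run = run),
            class = "cv_calibration")
}

#' @export
print.cv_calibration <- function(x, ...) {
  cat("<cv_calibration>\n")
  m <- rbind(target = x$targets, achieved = x$achieved,
             `rel err %` = 100 * (x$achieved / x$targets - 1))
  print(round(m, 2))
  cat(sprintf("  objective (RMSE of relative errors): %.4f after %s evaluations\n",
              x$objective, x$iterations))
  invisible(x)
}
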