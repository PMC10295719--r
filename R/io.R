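#' Write a run's trace as CSV
#'
#' One row per time step, header `time_s` followed by one column per state
#' and derived observable.
#'
#' @param run a `cv_run` or `cv_coupled` object with a recorded trace.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_trace_csv <- function(run, path) {
  if (is.null(run$trace)) stop("run has no recorded trace", call. = FALSE)
  write.csv(as.data.frame(run$trace), path, row.names = FALSE)
  invisible(path)
}

#' Write scenario metrics as JSON
#'
#' Exports the headline indices of a scenario (velocity-time integrals, S/D
#' ratio, space-averaged TAWSS/OSI, mean LAD flow, PVA, demand shift) and the
#' harmonic spectrum as `{n, modulus, phase}` records.
#'
#' @param scenario_result a `cv_scenario`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_metrics_json <- function(scenario_result, path) {
  m <- scenario_result$metrics
  sp <- m$spectrum
  out <- list(scenario = scenario_result$scenario,
              vtis_cm = m$vtis, vtid_cm = m$vtid, sd_ratio = m$sd_ratio,
              tawss_pa = m$tawss, osi = m$osi,
              q_lad_mean_mls = m$q_lad_mean,
              pva_mmhg_ml = scenario_result$pva$pva,
              demand_shift = scenario_result$shift,
              harmonics = data.frame(n = seq_len(sp$n),
                                     modulus = sp$modulus,
                                     phase = sp$phase))
  if (!is.null(scenario_result$report))
    out$coupling <- list(cycles_run = scenario_result$report$cycles_run,
                         converged = scenario_result$report$converged)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write a coupling convergence report as JSON
#'
#' `{cycles_run, errors_per_cycle, converged}` in the layout used by the
#' per-run logs.
#'
#' @param report the `report` element of a `cv_coupled`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_convergence_json <- function(report, path) {
  err <- report$errors_per_cycle
  out <- list(cycles_run = report$cycles_run,
              errors_per_cycle = if (is.null(err)) list() else
                lapply(seq_len(nrow(err)), function(i)
                  list(zero_d = err[i, 1], segment = err[i, 2])),
              converged = report$converged)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
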