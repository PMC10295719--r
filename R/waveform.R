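#' Uniformly sampled single-period waveform
#'
#' Container for post-processing: sample times over exactly one period, the
#' sampled values (flow, velocity or wall shear stress), and the systolic
#' window used to split velocity-time integrals. The last sample is the one
#' before the period repeats (times cover `[t0, t0 + T)`).
#'
#' @param time sample times (s), uniform spacing.
#' @param values samples (mL/s, cm/s or Pa).
#' @param kind one of `"flow"`, `"velocity"`, `"shear"`.
#' @param systole_window `c(start, end)` seconds relative to the first
#'   sample, or `NULL` when not needed.
#' @return object of class `waveform_record`.
#' @export
waveform_record <- function(time, values, kind = c("flow", "velocity", "shear"),
                            systole_window = NULL) {
  kind <- match.arg(kind)
  if (length(time) != length(values) || length(time) < 4)
    stop("need matching time/value samples", call. = FALSE)
  dt <- diff(time)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1])
    stop("sampling must be uniform", call. = FALSE)
  period <- dt[1] * length(time)
  if (!is.null(systole_window)) {
    if (systole_window[1] < 0 || systole_window[2] > period ||
        systole_window[1] >= systole_window[2])
      stop("systole window must lie inside one period", call. = FALSE)
  }
  structure(list(time = time, values = values, kind = kind,
                 period = period, dt = dt[1],
                 systole_window = systole_window),
            class = "waveform_record")
}

#' Velocity-time integrals and the S/D ratio
#'
#' VTIS is the time integral of the waveform over the systolic window, VTID
#' over the rest of the period (trapezoidal rule); the S/D ratio is their
#' quotient. For a velocity waveform in cm/s the integrals are in cm.
#'
#' @param w a [waveform_record()] with a systolic window set (in the
#'   simulator the window is the aortic-valve open interval).
#' @return list with `vtis`, `vtid`, `sd_ratio`.
#' @export
#' @examples
#' t <- seq(0, 0.8 - 0.001, by = 0.001)
#' w <- waveform_record(t, rep(10, length(t)), "velocity",
#'                      systole_window = c(0, 0.3))
#' vti_metrics(w)  # 3, 5, 0.6
vti_metrics <- function(w) {
  if (is.null(w$systole_window))
    stop("systole window is not set", call. = FALSE)
  rel <- w$time - w$time[1]
  sys <- rel >= w$systole_window[1] & rel < w$systole_window[2]
  # rectangle rule on uniform samples == trapezoid on the periodic extension
  vtis <- sum(w$values[sys]) * w$dt
  vtid <- sum(w$values[!sys]) * w$dt
  if (abs(vtid) < .Machine$double.eps * length(w$values))
    stop("diastolic integral is zero; S/D ratio undefined", call. = FALSE)
  list(vtis = vtis, vtid = vtid, sd_ratio = vtis / vtid)
}

#' Fourier harmonic decomposition of a periodic waveform
#'
#' Writes the sampled period as
#' \eqn{Q(t) = Q_0 + \sum_{n=1}^{N} Q_n \sin(n \omega t + \psi_n)}
#' with \eqn{Q_0} the mean, \eqn{Q_n \ge 0} the modulus and \eqn{\psi_n} the
#' phase of the n-th harmonic, via the discrete Fourier transform of one
#' period. Moduli are invariant to the phase origin. With `n_harmonics` at
#' the Nyquist limit the reconstruction reproduces the samples to numerical
#' precision (for an even number of samples the Nyquist bin is kept with its
#' full, unhalved weight and flagged).
#'
#' @param w a [waveform_record()] (or plain numeric vector sampled over one
#'   period with `dt` supplied).
#' @param n_harmonics number of harmonics N (default 10; capped at Nyquist).
#' @param dt sample spacing, only when `w` is a bare vector.
#' @return object of class `harmonic_spectrum`: `q0`, `modulus`, `phase`,
#'   `omega`, `n`, `nyquist` (logical per harmonic), `period`.
#' @export
#' @examples
#' t <- seq(0, 1 - 1 / 256, by = 1 / 256)
#' sp <- fourier_decompose(waveform_record(t, 5 + 2 * sin(2 * pi * t + 0.3)),
#'                         n_harmonics = 3)
#' round(c(sp$q0, sp$modulus[1]), 10)  # 5, 2
fourier_decompose <- function(w, n_harmonics = 10, dt = NULL) {
  if (inherits(w, "waveform_record")) {
    x <- w$values; dt <- w$dt
  } else {
    x <- as.numeric(w)
    if (is.null(dt)) stop("dt required for a bare sample vector", call. = FALSE)
  }
  m <- length(x)
  nyq <- floor(m / 2)
  if (n_harmonics > nyq)
    stop(sprintf("n_harmonics (%d) above the Nyquist limit (%d)",
                 n_harmonics, nyq), call. = FALSE)
  period <- m * dt
  f <- fft(x)
  q0 <- Re(f[1]) / m
  n <- seq_len(n_harmonics)
  a <- 2 * Re(f[n + 1]) / m       # cos coefficients
  b <- -2 * Im(f[n + 1]) / m      # sin coefficients
  is_nyq <- (m %% 2 == 0) & (n == m / 2)
  a[is_nyq] <- a[is_nyq] / 2      # Nyquist bin is not double-counted
  modulus <- sqrt(a^2 + b^2)
  phase <- atan2(a, b)            # A sin(n w t + psi): b = A cos psi, a = A sin psi
  structure(list(q0 = q0, modulus = modulus, phase = phase,
                 omega = 2 * pi / period, n = n_harmonics,
                 nyquist = is_nyq, period = period),
            class = "harmonic_spectrum")
}

#' Reconstruct samples from a harmonic spectrum
#'
#' @param spec a `harmonic_spectrum`. @param t times (s).
#' @return reconstructed values.
#' @export
reconstruct_waveform <- function(spec, t) {
  out <- rep(spec$q0, length(t))
  for (n in seq_len(spec$n))
    out <- out + spec$modulus[n] * sin(n * spec$omega * t + spec$phase[n])
  out
}

#' Mean square implied by a harmonic spectrum (Parseval)
#'
#' `q0^2 + sum(modulus^2) / 2`, with the Nyquist harmonic (present only for
#' an even sample count at the Nyquist limit) contributing its full square.
#' Equals the mean square of the samples when the spectrum is complete.
#'
#' @param spec a `harmonic_spectrum`.
#' @return mean-square value.
#' @export
spectrum_mean_square <- function(spec) {
  w <- ifelse(spec$nyquist, 1, 0.5)
  spec$q0^2 + sum(w * spec$modulus^2)
}

#' Time-averaged wall shear stress and oscillatory shear index
#'
#' For a signed one-dimensional shear waveform over one period:
#' \deqn{TAWSS = \frac{1}{T}\int_0^T |\tau| dt, \quad
#'       OSI = \frac{1}{2}\left(1 - \frac{|\int_0^T \tau\,dt|}
#'                                       {\int_0^T |\tau|\,dt}\right)}
#' OSI is 0 when the shear never changes sign and 0.5 for a zero-mean
#' reversing waveform. An identically zero waveform returns OSI 0 with a
#' warning.
#'
#' @param w a [waveform_record()] of kind `"shear"` (or numeric vector).
#' @return list with `tawss` (Pa) and `osi` (dimensionless, in `[0, 0.5]`).
#' @export
#' @examples
#' t <- seq(0, 1 - 1 / 512, by = 1 / 512)
#' tawss_osi(waveform_record(t, sin(2 * pi * t), "shear"))  # 2/pi, 0.5
tawss_osi <- function(w) {
  x <- if (inherits(w, "waveform_record")) w$values else as.numeric(w)
  int_abs <- mean(abs(x))
  if (int_abs == 0) {
    warning("identically zero shear waveform; OSI defined as 0")
    return(list(tawss = 0, osi = 0))
  }
  osi <- 0.5 * (1 - abs(mean(x)) / int_abs)
  list(tawss = int_abs, osi = osi)
}

#' Waveform metrics of a coupled scenario cycle
#'
#' Convenience wrapper that extracts, from one steady-state coupled cycle,
#' the segment-inlet velocity waveform (cross-sectional mean, `v = Q / (pi
#' r^2)`), the systolic window (mechanical systole: from mitral valve
#' closure to aortic valve closure, both exported by the simulator), and
#' returns VTI metrics, the harmonic spectrum of the inlet flow, and
#' space-averaged TAWSS/OSI over the segment compartments.
#'
#' @param trace one cycle of a coupled trace (rows covering one period).
#' @param seg_q per-compartment segment flows for the same cycle.
#' @param segment the `cv_segment` used in the run.
#' @param config the run's `cv_config`.
#' @param n_harmonics harmonics to report (default 10).
#' @return list with `vtis`, `vtid`, `sd_ratio`, `tawss`, `osi` (space
#'   averages), `per_compartment` (TAWSS/OSI vectors), `spectrum`,
#'   `systole_window`, `velocity` (the waveform record).
#' @export
waveform_metrics <- function(trace, seg_q, segment, config, n_harmonics = 10) {
  t <- trace[, "time_s"]
  rel <- t - t[1]
  open <- trace[, "valve_open"] > 0.5
  if (!any(open)) stop("no systole found: aortic valve never opened",
                       call. = FALSE)
  # mechanical systole: mitral closure (ventricular pressure overtaking
  # atrial pressure before ejection) to aortic valve closure
  io <- which(open)[1]
  pre <- seq_len(io)
  still_open <- which(trace[pre, "p_la"] >= trace[pre, "p_lv"])
  i0 <- if (length(still_open)) min(max(still_open) + 1L, io) else 1L
  sys_win <- c(rel[i0], rel[rev(which(open))[1]] + config$timeline$dt)
  q_in <- trace[, "q_lad_in"]
  area_cm2 <- pi * (config$segment$inlet_radius_mm / 10)^2
  vel <- waveform_record(t, q_in / area_cm2, "velocity",
                         systole_window = sys_win)
  vti <- vti_metrics(vel)
  spec <- fourier_decompose(waveform_record(t, q_in, "flow"), n_harmonics)
  tau <- wall_shear_waveform(seg_q, segment$radius_mm, config$blood$mu)
  per <- apply(tau, 2, function(col) unlist(tawss_osi(col)))
  list(vtis = vti$vtis, vtid = vti$vtid, sd_ratio = vti$sd_ratio,
       tawss = mean(per["tawss", ]), osi = mean(per["osi", ]),
       per_compartment = per, spectrum = spec,
       systole_window = sys_win, velocity = vel)
}
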