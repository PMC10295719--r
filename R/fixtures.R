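#' Deterministic test fixtures
#'
#' Generates small, seeded fixtures used by the test-suite and examples:
#' `toy_circuit` — a two-compartment RC circuit with its closed-form
#' solution; `toy_waveform` — sinusoid, square and half-rectified sample
#' sets; `toy_loop` — a rectangular pressure-volume loop of known area.
#' Identical seeds give identical fixtures (byte-identical files when `dir`
#' is given).
#'
#' @param kind one of `"toy_circuit"`, `"toy_waveform"`, `"toy_loop"`.
#' @param seed integer seed.
#' @param dir optional directory; when given, fixtures are also written as
#'   CSV and the paths returned in the result.
#' @return a list describing the fixture (see details per kind).
#' @export
#' @examples
#' fx <- generate_fixtures("toy_loop", seed = 1)
#' fx$expected_stroke_work
generate_fixtures <- function(kind = c("toy_circuit", "toy_waveform",
                                       "toy_loop"),
                              seed = 42, dir = NULL) {
  kind <- match.arg(kind)
  set.seed(seed)
  fx <- switch(kind,
    toy_circuit = {
      # dV/dt = q_in - V/(R C): exponential relaxation to R C q_in
      r <- round(runif(1, 0.5, 2), 3)
      cc <- round(runif(1, 0.5, 2), 3)
      q_in <- round(runif(1, 1, 5), 3)
      v0 <- round(runif(1, 0, 1), 3)
      tt <- seq(0, 2, by = 0.001)
      v_exact <- r * cc * q_in + (v0 - r * cc * q_in) * exp(-tt / (r * cc))
      list(kind = kind, r = r, c = cc, q_in = q_in, v0 = v0,
           time = tt, v_exact = v_exact,
           derivative = function(v, t) q_in - v / (r * cc))
    },
    toy_waveform = {
      m <- 512
      tt <- seq(0, 1 - 1 / m, by = 1 / m)
      amp <- round(runif(1, 1, 3), 3)
      phase <- round(runif(1, -1, 1), 3)
      offset <- round(runif(1, 2, 8), 3)
      list(kind = kind, time = tt, amplitude = amp, phase = phase,
           offset = offset,
           sinusoid = offset + amp * sin(2 * pi * tt + phase),
           square = ifelse(tt < 0.5, 1, -1),
           half_rectified = pmax(sin(2 * pi * tt), 0))
    },
    toy_loop = {
      v_lo <- round(runif(1, 50, 70)); v_hi <- v_lo + round(runif(1, 30, 50))
      p_lo <- round(runif(1, 5, 15)); p_hi <- p_lo + round(runif(1, 60, 100))
      list(kind = kind,
           volume = c(v_hi, v_hi, v_lo, v_lo),
           pressure = c(p_lo, p_hi, p_hi, p_lo),
           expected_stroke_work = (v_hi - v_lo) * (p_hi - p_lo))
    })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(dir, paste0(kind, "_seed", seed, ".csv"))
    df <- switch(kind,
      toy_circuit = data.frame(time = fx$time, v_exact = fx$v_exact),
      toy_waveform = data.frame(time = fx$time, sinusoid = fx$sinusoid,
                                square = fx$square,
                                half_rectified = fx$half_rectified),
      toy_loop = data.frame(volume = fx$volume, pressure = fx$pressure))
    write.csv(df, path, row.names = FALSE)
    fx$path <- path
  }
  fx
}
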