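#' Time-varying chamber elastance
#'
#' The pumping action of each cardiac chamber is represented by a time-varying
#' elastance E(t) that rises from `emin` to `emax` during the chamber's
#' activation window and returns to `emin` outside it. The activation shape is
#' a two-limb cosine pulse: exactly 0 outside the window and exactly 1 at
#' its peak (placed at fraction `peak_frac` of the duration). The upstroke
#' is a fast-foot cosine, `(1 - cos(pi * sqrt(t/tp))) / 2`, whose
#' near-linear onset gives a brisk isovolumic pressure rise (the early
#' behaviour of Hill-type activation functions); relaxation is a plain
#' raised cosine. The waveform is continuous everywhere and smooth at the
#' peak, which keeps the right-hand side well-behaved for the explicit
#' integrator.
#'
#' @param t time (s); any non-negative value, the waveform is periodic.
#' @param chamber list with `emax`, `emin` (mmHg/mL), `v0` (mL), `onset` (s),
#'   `dur` (s), `peak_frac` (0-1), as in `cv_config()$chambers`.
#' @param timeline list with at least `period` (s).
#' @return elastance in mmHg/mL (vectorised over `t`).
#' @export
#' @examples
#' cfg <- cv_config()
#' t_peak <- cfg$chambers$lv$peak_frac * cfg$chambers$lv$dur
#' elastance(t_peak, cfg$chambers$lv, cfg$timeline)  # the ceiling E_max
elastance <- function(t, chamber, timeline) {
  if (timeline$period <= 0) stop("cycle period must be positive", call. = FALSE)
  tt <- (t - chamber$onset) %% timeline$period
  pf <- if (is.null(chamber$peak_frac)) 0.5 else chamber$peak_frac
  tp <- pf * chamber$dur
  act <- ifelse(tt >= chamber$dur, 0,
                ifelse(tt < tp, 0.5 * (1 - cos(pi * sqrt(tt / tp))),
                       0.5 * (1 + cos(pi * (tt - tp) / (chamber$dur - tp)))))
  chamber$emin + (chamber$emax - chamber$emin) * act
}

#' Chamber pressure from the elastance relation
#'
#' P = E(t) (V - V0): pressure is linear in volume above the unstressed
#' volume, with the time-varying elastance as the slope.
#'
#' @param v chamber volume (mL).
#' @param t time (s).
#' @param chamber,timeline as in [elastance()].
#' @return pressure in mmHg.
#' @export
chamber_pressure <- function(v, t, chamber, timeline) {
  elastance(t, chamber, timeline) * (v - chamber$v0)
}
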