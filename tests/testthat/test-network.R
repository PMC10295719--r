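test_that("the network right-hand side vanishes at the zero-pressure equilibrium", {
  cfg <- cv_config()
  y <- initial_state(cfg)
  y[] <- 0
  # unstressed chambers hold exactly their unstressed volume
  y["v_la"] <- cfg$chambers$la$v0; y["v_lv"] <- cfg$chambers$lv$v0
  y["v_ra"] <- cfg$chambers$ra$v0; y["v_rv"] <- cfg$chambers$rv$v0
  d <- network_derivatives(y, 0.7, cfg, eoa = 0, valve_closed = TRUE)
  expect_equal(max(abs(d$dy)), 0)
})

test_that("volume is conserved by construction: compliance derivatives sum to zero", {
  cfg <- cv_config()
  vols <- corovalve:::.volume_states
  set.seed(42)
  for (i in 1:25) {
    y <- initial_state(cfg) * runif(length(initial_state(cfg)), 0.5, 1.5)
    t <- runif(1, 0, cfg$timeline$period)
    closed <- runif(1) < 0.5
    if (closed) y["q_av"] <- 0
    d <- network_derivatives(y, t, cfg, eoa = if (closed) 0 else 4,
                             valve_closed = closed)
    expect_lt(abs(sum(d$dy[vols])), 1e-10)
  }
})

test_that("dimension mismatches are rejected", {
  cfg <- cv_config()
  expect_error(network_derivatives(1:5, 0, cfg), "length")
})

test_that("one RK4 step reproduces the exponential to near machine precision", {
  y1 <- rk4_step(1, 0, 0.001, function(y, t) -y)
  expect_lt(abs(y1 - exp(-0.001)), 1e-15)
  # identity field leaves the state untouched
  expect_identical(rk4_step(c(a = 2, b = -1), 0, 0.01,
                            function(y, t) 0 * y),
                   c(a = 2, b = -1))
  expect_error(rk4_step(1, 0, -0.1, function(y, t) -y), "positive")
  expect_error(rk4_step(1, 0, 0.1, function(y, t) NaN), "non-finite")
})

test_that("RK4 empirical convergence order is at least 3.9", {
  err <- sapply(c(0.01, 0.005), function(h) {
    y <- 1
    for (i in seq_len(round(1 / h))) y <- rk4_step(y, (i - 1) * h, h,
                                                   function(y, t) -y)
    abs(y - exp(-1))
  })
  order <- log2(err[1] / err[2])
  expect_gte(order, 3.9)
})

test_that("RK4 matches a hand-written RC relaxation and an analytic RL loop", {
  # RC compartment with constant inflow: V(t) = RCq + (V0 - RCq) exp(-t/RC)
  fx <- generate_fixtures("toy_circuit", seed = 7)
  y <- fx$v0
  tt <- fx$time
  h <- diff(tt)[1]
  num <- numeric(length(tt)); num[1] <- y
  for (i in seq_along(tt)[-1]) {
    y <- rk4_step(y, tt[i - 1], h, fx$derivative)
    num[i] <- y
  }
  expect_lt(max(abs(num - fx$v_exact)), 1e-8)

  # two-state pressure/flow loop: dP/dt = -Q/C, L dQ/dt = P - RQ
  R <- 0.5; C <- 1.2; L <- 0.05
  f <- function(y, t) c(-y[2] / C, (y[1] - R * y[2]) / L)
  # eigen-solution as the independent closed form
  A <- matrix(c(0, -1 / C, 1 / L, -R / L), 2, 2, byrow = TRUE)
  eg <- eigen(A)
  y0 <- c(1, 0)
  coef <- solve(eg$vectors, y0)
  exact <- function(t)
    Re(eg$vectors %*% (coef * exp(eg$values * t)))
  y <- y0; h <- 1e-3
  worst <- 0
  for (i in 1:1000) {
    y <- rk4_step(y, (i - 1) * h, h, f)
    worst <- max(worst, max(abs(y - exact(i * h))))
  }
  expect_lt(worst, 1e-8)
})

test_that("RK4 agrees with an independent fixed-step integrator on the toy circuit", {
  skip_if_not_installed("deSolve")
  fx <- generate_fixtures("toy_circuit", seed = 13)
  sol <- deSolve::ode(y = c(v = fx$v0), times = fx$time,
                      func = function(t, y, p) list(fx$derivative(y, t)),
                      parms = NULL, method = "rk4")
  y <- fx$v0
  h <- diff(fx$time)[1]
  for (i in seq_along(fx$time)[-1]) y <- rk4_step(y, fx$time[i - 1], h,
                                                  fx$derivative)
  expect_equal(unname(sol[nrow(sol), "v"]), unname(y), tolerance = 1e-12)
})

test_that("the compiled cycle advance equals repeated R-level RK4 stepping", {
  cfg <- cv_config()
  p <- corovalve:::flatten_config(cfg)
  y <- initial_state(cfg)
  v <- list(open = FALSE, eoa = 0)
  n <- 40
  out <- corovalve:::cv_advance_cpp(as.numeric(y), p, v, n, 0.001, 0,
                                    FALSE, NULL, TRUE)
  # replay in R: valve schedule advanced per step, then one RK4 step
  yy <- as.numeric(y)
  st <- v
  preset <- disease_preset("control")
  tl <- cfg$timeline
  for (s in seq_len(n)) {
    t <- (s - 1) * 0.001
    p_lv <- chamber_pressure(yy[2], t, cfg$chambers$lv, tl)
    p_ao <- yy[6] / cfg$systemic$c_ao
    st <- eoa_schedule(st, p_lv, p_ao, yy[5], preset, dt = 0.001,
                       ramp_s = cfg$valve$ramp_s)
    if (st$q_forced_zero) yy[5] <- 0
    f <- function(y, t) corovalve:::cv_derivs_cpp(y, t, p, st$eoa,
                                                  st$q_forced_zero)$dy
    yy <- rk4_step(yy, t, 0.001, f)
    if (st$q_forced_zero) yy[5] <- 0
  }
  expect_equal(unname(out$state), yy, tolerance = 1e-12)
})

test_that("a closed loop conserves total blood volume over full cycles", {
  run <- settled_control()
  tr <- corovalve:::last_cycle(run)
  vols <- corovalve:::.volume_states
  total <- rowSums(tr[, vols])
  expect_lt(max(total) - min(total) , 1e-6 + 1e-9 * total[1])
})

test_that("the default configuration reaches a periodic steady state within 20 cycles", {
  run <- run_cycles(cv_config(), n_cycles = 20, record = "none")
  expect_true(run$converged)
  sm <- run$summaries
  expect_lt(abs(sm$co[20] / sm$co[19] - 1), 0.001)
  # every recorded trace column repeats to < 0.5% of its dynamic range once
  # the slow intramyocardial stores have settled
  run2 <- run_cycles(cv_config(), n_cycles = 28, record = "all")
  steps <- 800
  tr <- run2$trace
  keep <- !colnames(tr) %in% c("time_s", "p_seg_in", "q_seg_out")
  a <- tr[(nrow(tr) - 2 * steps + 1):(nrow(tr) - steps), keep]
  b <- tr[(nrow(tr) - steps + 1):nrow(tr), keep]
  rng <- apply(b, 2, function(x) max(abs(x), 1e-6))
  expect_lt(max(abs(a - b) / rep(rng, each = steps)), 0.005)
})

test_that("without elastance activation the pump output decays toward zero", {
  cfg <- cv_config(chambers = list(
    lv = list(emax = 0.0701), rv = list(emax = 0.0451),
    la = list(emax = 0.1301), ra = list(emax = 0.1101)))
  run <- run_cycles(cfg, n_cycles = 12, record = "none")
  co <- run$summaries$co
  expect_lt(co[12], 0.2)
  expect_lte(co[12], co[2])
})

test_that("divergence aborts with a time-stamped error", {
  # an unresolvably stiff arterial branch blows the explicit integrator up
  cfg <- cv_config(systemic = list(upper = list(l_art = 1e-8)))
  expect_error(run_cycles(cfg, n_cycles = 20),
               "divergence|non-finite|integration")
})
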