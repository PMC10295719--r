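test_that("pressure-volume area decomposes a rectangular loop exactly", {
  fx <- generate_fixtures("toy_loop", seed = 3)
  res <- pva_from_loop(fx$volume, fx$pressure, v0 = 0)
  expect_equal(res$stroke_work, fx$expected_stroke_work)
  expect_equal(res$pva, res$stroke_work + res$potential_energy)
  expect_gte(res$potential_energy, 0)
  # isovolumic beating: zero loop area, demand is potential energy only
  iso <- pva_from_loop(c(80, 80, 80, 80), c(5, 60, 90, 20), v0 = 10)
  expect_equal(iso$stroke_work, 0)
  expect_equal(iso$pva, iso$potential_energy)
  expect_equal(iso$potential_energy, 0.5 * 90 * 70)
  expect_error(pva_from_loop(1:2, 1:3), "matching")
})

test_that("valve disease raises the ventricular pressure-volume area", {
  study <- reference_study()
  expect_gt(study$AS$pva$pva, study$control$pva$pva)
  expect_gt(study$AR$pva$pva, study$control$pva$pva)
  expect_gt(study$AS$shift, 1)
  expect_gt(study$AR$shift, 1)
})

test_that("the demand shift is the PVA ratio and scales the target multiplicatively", {
  expect_equal(shift_factor(5000, 5000), 1)
  expect_equal(shift_factor(6500, 5000), 1.3)
  expect_error(shift_factor(-1, 5000), "positive")
  cu <- pq_curve()
  expect_equal(target_flow(100, cu, shift = 2), 2 * target_flow(100, cu))
  # control target mean flow 1.25 mL/s with shift 1.3 -> 1.625 target
  expect_equal(1.25 * target_flow(100, cu, 1.3), 1.625)
})

test_that("the P-Q curve interpolates its knots with a flat plateau", {
  cu <- pq_curve(pressure = c(20, 60, 140, 200), flow = c(0.3, 1, 1, 1.5))
  expect_equal(target_flow(100, cu), 1)       # plateau
  expect_equal(target_flow(60, cu), 1)        # knot
  expect_equal(target_flow(40, cu), 0.65)     # midpoint of the rising limb
  expect_equal(target_flow(170, cu), 1.25)    # above the plateau
  expect_warning(tf <- target_flow(5, cu), "clamp")
  expect_equal(tf, 0.3)
  expect_error(target_flow(-1, cu), "non-negative")
  expect_error(pq_curve(flow = c(1, 0.5, 1, 1.5)), "non-decreasing")
})

test_that("the linear negative-feedback update has the right fixed point and sign", {
  expect_equal(update_resistances(1.0, 1.0, 1.5), 1.5)    # on target: no move
  expect_gt(update_resistances(1.5, 1.0, 1.0), 1.0)       # too much flow: constrict
  expect_lt(update_resistances(0.5, 1.0, 1.0), 1.0)       # too little: dilate
  expect_warning(m <- update_resistances(100, 1, 5), "clamped")
  expect_equal(m, 10)
})

test_that("the controller converges to R* = P/Q_target on an Ohmic fixture", {
  # toy branch: fixed perfusion pressure P across a controllable resistance
  p_drive <- 90; r0 <- 60; q_target <- 1.2
  mult <- 1
  errs <- numeric(0)
  for (i in 1:40) {
    q <- p_drive / (r0 * mult)
    errs <- c(errs, abs(q / q_target - 1))
    if (errs[length(errs)] < 1e-4) break
    mult <- update_resistances(q, q_target, mult, gain = 0.5)
  }
  expect_equal(r0 * mult, p_drive / q_target, tolerance = 1e-3)
  # relative flow error contracts monotonically after the first iteration
  expect_true(all(diff(errs[-1]) < 1e-12))
})

test_that("autoregulation tracks the P-Q curve target past a stenosis by dilating", {
  for (ds in c(0.7, 0.8)) {
    cfg <- cv_config(coronary = list(branches = list(lad = list(
      stenosis = list(ds = ds, ref_diameter_mm = 3, length_mm = 10)))))
    base <- run_cycles(cfg, n_cycles = 10, record = "last")
    ar <- suppressWarnings(autoregulate(cfg, init = base$state,
                                        valve = base$valve))
    expect_true(ar$converged)
    expect_lt(ar$multipliers[["lad"]], 1)   # dilation
    sm <- ar$run$summaries[nrow(ar$run$summaries), ]
    # the target is the curve value at the achieved post-stenotic perfusion
    # pressure: a severe stenosis pushes perfusion below the plateau and the
    # controller settles on the reduced target (residual ischemia), a milder
    # one is fully compensated
    perf <- sm$p_epi_lad - sm$p_ra
    tgt <- cfg$coronary$branches$lad$reference_flow *
      target_flow(perf, pq_curve())
    expect_lt(abs(sm$q_lad / tgt - 1), cfg$autoreg$tolerance + 0.005)
    if (ds == 0.7) expect_gt(sm$q_lad, 0.8)
  }
})

test_that("resting coronary flow rises with valve disease under autoregulation", {
  study <- reference_study()
  q <- study$comparison$q_lad_mean
  expect_gt(q[2], q[1])   # AS above control
  expect_gt(q[3], q[1])   # AR above control
  # multipliers stay inside physiological dilation/constriction bounds
  for (nm in c("control", "AS", "AR")) {
    m <- vapply(study[[nm]]$config$coronary$branches, `[[`, numeric(1), "r_mult")
    expect_true(all(m >= 0.1 & m <= 10))
  }
})
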