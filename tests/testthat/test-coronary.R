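test_that("intramyocardial pressure is a floored linear map of chamber pressure", {
  expect_equal(intramyocardial_pressure(c(1/6, 1/2, 5/6), 0), c(0, 0, 0))
  expect_equal(intramyocardial_pressure(c(1/6, 1/2, 5/6), 120), c(20, 60, 100))
  # negative chamber pressure never sucks the wall open
  expect_equal(intramyocardial_pressure(0.5, -30), 0)
  # mid-wall is always the mean of the two neighbours for a linear gradient
  g <- cv_config()$coronary$gamma
  p <- intramyocardial_pressure(g, 87.3)
  expect_equal(p[2], (p[1] + p[3]) / 2, tolerance = 1e-12)
})

test_that("stenosis element geometry and losses behave as configured", {
  blood <- list(rho = 1050, mu = 0.0035)
  expect_error(stenosis_element(1.0), "DS")
  none <- stenosis_coefficients(stenosis_element(0), blood)
  expect_identical(none$b, 0)
  expect_identical(none$r_extra, 0)
  # DS = 0.5 leaves 25% of the reference lumen area
  el <- stenosis_element(0.5, ref_diameter_mm = 3)
  a_ref <- pi * (1.5e-3)^2
  a_st <- pi * (0.75e-3)^2
  expect_equal(a_st / a_ref, 0.25)
  # hand-evaluated separation loss for DS = 0.8, d_ref = 3 mm, Q = 1.25 mL/s
  el8 <- stenosis_element(0.8, ref_diameter_mm = 3, length_mm = 10)
  a_s8 <- a_ref * 0.04
  b_si <- 0.5 * 1050 * (1 / a_s8 - 1 / a_ref)^2
  q <- 1.25
  dp_hand_b <- b_si * (q * 1e-6)^2 / 133.322
  co <- stenosis_coefficients(el8, blood)
  expect_equal(co$b * q^2, dp_hand_b, tolerance = 1e-12)
  dp <- stenosis_pressure_drop(q, el8, blood)
  expect_gt(dp, dp_hand_b)  # viscous throat term adds on top
  expect_equal(stenosis_pressure_drop(0, el8, blood), 0)
  expect_true(all(diff(stenosis_pressure_drop(seq(0, 5, 0.5), el8, blood)) > 0))
})

test_that("with no tissue pressure the layers split like parallel resistors", {
  cfg <- cv_config()
  br <- cfg$coronary$branches$lad
  # steady Ohmic limit: q_in = q_out per layer; eliminate the layer pressure
  p_epi <- 90; p_ven <- 8
  q_expected <- (p_epi - p_ven) / (br$r_in * br$r_mult + br$r_out)
  # find the layer volumes that make each layer stationary, then check flows
  p_layer <- p_epi - q_expected * br$r_in * br$r_mult
  v_layer <- p_layer * br$c_layer
  fl <- coronary_layer_flows(br, c(0, 0, 0), v_layer, p_epi, p_ven, 120)
  expect_equal(fl$q_in, q_expected, tolerance = 1e-12)
  expect_equal(fl$q_out, q_expected, tolerance = 1e-12)
  expect_equal(fl$dv, c(0, 0, 0), tolerance = 1e-12)
})

test_that("systole squeezes the subendocardium hardest", {
  run <- settled_control()
  tr <- corovalve:::last_cycle(run)
  ipk <- which.max(tr[, "p_lv"])
  expect_lt(tr[ipk, "q_lad_l3"], tr[ipk, "q_lad_l1"])
  # and the layer inflows agree with the reference R implementation
  cfg <- run$config
  br <- cfg$coronary$branches$lad
  v_layer <- tr[ipk, c("v_l1_lad", "v_l2_lad", "v_l3_lad")]
  fl <- coronary_layer_flows(br, cfg$coronary$gamma, unname(v_layer),
                             tr[ipk, "p_epi_lad"],
                             tr[ipk, "v_ven_lad"] / br$c_ven,
                             tr[ipk, "p_lv"])
  expect_equal(unname(tr[ipk, c("q_lad_l1", "q_lad_l2", "q_lad_l3")]),
               fl$q_in, tolerance = 1e-9)
})

test_that("per-branch mass is conserved at periodic steady state", {
  run <- settled_control()
  tr <- corovalve:::last_cycle(run)
  for (b in c("lad", "lcx", "rca")) {
    q_in <- mean(tr[, paste0("q_", b, "_in")])
    cfg <- run$config$coronary$branches[[b]]
    p_ven <- tr[, paste0("v_ven_", b)] / cfg$c_ven
    q_out <- mean((p_ven - tr[, "p_ra"]) / cfg$r_v_out)
    expect_lt(abs(q_in / q_out - 1), 0.001)
  }
})

test_that("the control LAD waveform is diastolic-dominant through the intramyocardial pump", {
  study <- reference_study()
  expect_lt(study$control$metrics$sd_ratio, 0.5)
  # removing the tissue-pressure gradient removes the systolic dip
  cfg <- cv_config(coronary = list(gamma = c(0, 1e-7, 2e-7)))
  run <- run_cycles(cfg, n_cycles = 12, record = "last")
  tr <- corovalve:::last_cycle(run)
  sys <- tr[, "valve_open"] > 0.5
  q <- tr[, "q_lad_in"]
  sd_flat <- sum(q[sys]) / sum(q[!sys])
  expect_gt(sd_flat, study$control$metrics$sd_ratio)
})
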