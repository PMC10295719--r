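blood <- list(rho = 1050, mu = 0.0035)

test_that("valve parameters from geometry have the expected structure", {
  geom <- valve_geometry(eoa_systole_cm2 = 4, ado_cm2 = 4)
  vp <- valve_params(geom, blood, 4)
  # orifice equal to the outflow tract: no separation loss, no excess inertia
  expect_equal(vp$B, 0)
  expect_equal(vp$L, 0)
  expect_gt(vp$R, 0)
  # viscous resistance scales with 1/EOA^2
  r1 <- valve_params(geom, blood, 2)$R
  r2 <- valve_params(geom, blood, 1)$R
  expect_equal(r2 / r1, 4, tolerance = 1e-12)
})

test_that("Bernoulli coefficient matches the hand-evaluated value", {
  # EOA 1 cm^2, Ado 4 cm^2, rho 1050: B = 0.5*1050*(1e4 - 2.5e3)^2 Pa s^2/m^6
  b_si <- 0.5 * 1050 * (1e4 - 2.5e3)^2
  expect_equal(b_si, 2.953125e10)
  vp <- valve_params(valve_geometry(), blood, 1)
  expect_equal(vp$B, b_si * 1e-12 / 133.322, tolerance = 1e-12)
  # compiled core agrees
  cpp <- valve_rbl_cpp(1, 4, 1, 1050, 0.0035, 0.01, 1, 1)
  expect_equal(unname(cpp["B"]), vp$B, tolerance = 1e-12)
  expect_equal(unname(cpp["R"]), vp$R, tolerance = 1e-12)
  expect_equal(unname(cpp["L"]), vp$L, tolerance = 1e-12)
})

test_that("closed valve refuses parameter evaluation", {
  expect_error(valve_params(valve_geometry(), blood, 0), "closed")
  expect_error(valve_params(valve_geometry(), blood, 5), "Ado")
})

test_that("pressure drop is odd in flow and Bernoulli-dominated at high flow", {
  vp <- valve_params(valve_geometry(), blood, 1)
  expect_equal(valve_pressure_drop(0, 0, vp), 0)
  q <- c(5, 80, 400)
  expect_equal(valve_pressure_drop(-q, 0, vp), -valve_pressure_drop(q, 0, vp))
  # Q = 400 mL/s through a 1 cm^2 orifice: separation loss ~ 4.72 kPa ~ 35.4 mmHg
  b_term_pa <- 2.953125e10 * (4e-4)^2
  expect_equal(b_term_pa, 4725, tolerance = 1e-10)
  drop <- valve_pressure_drop(400, 0, list(R = 0, B = vp$B, L = 0))
  expect_equal(drop, 4725 / 133.322, tolerance = 1e-9)
})

test_that("valve phase schedule opens on pressure and seals on flow reversal", {
  ctrl <- disease_preset("control")
  st <- list(open = FALSE, eoa = 0)
  # diastole, ventricular pressure below aortic: stays closed, zero flow
  st1 <- eoa_schedule(st, p_upstream = 10, p_downstream = 80, q = 0, ctrl)
  expect_false(st1$open)
  expect_identical(st1$eoa, 0)
  expect_true(st1$q_forced_zero)
  # pressure crossover starts the opening ramp
  st2 <- eoa_schedule(st, p_upstream = 85, p_downstream = 80, q = 0, ctrl)
  expect_true(st2$open)
  expect_gt(st2$eoa, 0)
  expect_lt(st2$eoa, ctrl$eoa_systole_cm2)
  # full ramp reaches the systolic orifice in ramp_s
  for (i in 1:5) st2 <- eoa_schedule(st2, 100, 90, 300, ctrl)
  expect_equal(st2$eoa, 4.0)
  # reversal during pressure decay seals a competent valve at once
  st3 <- eoa_schedule(st2, p_upstream = 80, p_downstream = 95, q = -1, ctrl)
  expect_false(st3$open)
  expect_identical(st3$eoa, 0)
  expect_true(st3$q_forced_zero)
})

test_that("regurgitant preset ramps to its diastolic orifice instead of sealing", {
  ar <- disease_preset("AR")
  expect_equal(ar$eoa_diastole_cm2, 0.3)
  st <- list(open = TRUE, eoa = 4)
  st <- eoa_schedule(st, p_upstream = 80, p_downstream = 95, q = -1, ar)
  expect_false(st$open)
  expect_gt(st$eoa, ar$eoa_diastole_cm2)  # mid-ramp
  for (i in 1:6) st <- eoa_schedule(st, 60, 90, -50, ar)
  expect_equal(st$eoa, 0.3)
  expect_false(st$q_forced_zero)
})

test_that("disease presets carry the configured severities", {
  expect_equal(disease_preset("control")[c("eoa_systole_cm2", "eoa_diastole_cm2")],
               list(eoa_systole_cm2 = 4.0, eoa_diastole_cm2 = 0.0))
  expect_equal(disease_preset("AS")$eoa_systole_cm2, 1.0)
  expect_equal(disease_preset("AR")$eoa_diastole_cm2, 0.3)
})

test_that("scenario runs respect the valve phase contract", {
  study <- reference_study()
  ctrl_tr <- corovalve:::last_cycle(study$control$coupled)
  # competent valve: exactly zero flow whenever closed
  closed <- ctrl_tr[, "valve_open"] < 0.5
  expect_true(all(ctrl_tr[closed, "q_av_obs"] == 0))
  # AS: systolic orifice is the stenotic one
  as_tr <- corovalve:::last_cycle(study$AS$coupled)
  expect_equal(max(as_tr[, "eoa"]), 1.0)
  # AS: mean systolic trans-valvular gradient in the tens of mmHg, far above
  # the near-zero drop of the healthy orifice (peak gradients also carry a
  # transient inertial component, so the mean isolates the stenotic loss)
  grad <- function(tr) {
    o <- tr[, "valve_open"] > 0.5
    mean(tr[o, "p_lv"] - tr[o, "p_ao_root"])
  }
  expect_lt(grad(ctrl_tr), 2)
  expect_gt(grad(as_tr), grad(ctrl_tr) + 10)
  # AR: diastolic orifice open with strictly negative (regurgitant) flow
  ar_tr <- corovalve:::last_cycle(study$AR$coupled)
  dia <- ar_tr[, "valve_open"] < 0.5
  expect_equal(min(ar_tr[, "eoa"]), 0.3)
  expect_lt(sum(ar_tr[dia, "q_av_obs"]) * 0.001, 0)
  expect_lt(max(ar_tr[dia, "q_av_obs"]), 0)
})
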