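test_that("velocity-time integrals split a constant waveform by window length", {
  t <- seq(0, 0.8 - 0.001, by = 0.001)
  w <- waveform_record(t, rep(10, length(t)), "velocity",
                       systole_window = c(0, 0.3))
  m <- vti_metrics(w)
  expect_equal(m$vtis, 3.0, tolerance = 1e-9)
  expect_equal(m$vtid, 5.0, tolerance = 1e-9)
  expect_equal(m$sd_ratio, 0.6, tolerance = 1e-9)
  # zero velocity everywhere: undefined ratio is an error
  w0 <- waveform_record(t, rep(0, length(t)), "velocity",
                        systole_window = c(0, 0.3))
  expect_error(vti_metrics(w0), "undefined")
})

test_that("waveform records enforce uniform sampling and window bounds", {
  expect_error(waveform_record(c(0, 0.1, 0.3, 0.35), 1:4), "uniform")
  t <- seq(0, 0.99, by = 0.01)
  expect_error(waveform_record(t, rep(1, 100), systole_window = c(0.5, 1.5)),
               "window")
})

test_that("a single harmonic is recovered exactly", {
  m <- 256
  t <- seq(0, 1 - 1 / m, by = 1 / m)
  w <- waveform_record(t, 5 + 2 * sin(2 * pi * t + 0.3), "flow")
  sp <- fourier_decompose(w, n_harmonics = 5)
  expect_equal(sp$q0, 5, tolerance = 1e-10)
  expect_equal(sp$modulus[1], 2, tolerance = 1e-10)
  expect_equal(sp$phase[1], 0.3, tolerance = 1e-10)
  expect_lt(max(sp$modulus[2:5]), 1e-10)
  # moduli are invariant to the phase origin
  w2 <- waveform_record(t, 5 + 2 * sin(2 * pi * (t + 0.17) + 0.3), "flow")
  sp2 <- fourier_decompose(w2, n_harmonics = 5)
  expect_equal(sp2$modulus, sp$modulus, tolerance = 1e-9)
  # reconstruction at the Nyquist limit reproduces the samples
  spN <- fourier_decompose(w, n_harmonics = m / 2)
  expect_equal(reconstruct_waveform(spN, t), w$values, tolerance = 1e-8)
  expect_error(fourier_decompose(w, n_harmonics = m), "Nyquist")
})

test_that("a square wave has 1/n odd harmonics and passes Parseval", {
  m <- 512
  t <- seq(0, 1 - 1 / m, by = 1 / m)
  sq <- ifelse(t < 0.5, 1, -1)
  sp <- fourier_decompose(waveform_record(t, sq, "flow"), n_harmonics = 9)
  # analytic series: 4/(n pi) for odd n (discrete sampling correction ~ 1/m^2)
  odd <- c(1, 3, 5, 7, 9)
  expect_equal(sp$modulus[odd], 4 / (odd * pi), tolerance = 1e-3)
  expect_lt(max(sp$modulus[c(2, 4, 6, 8)]), 1e-10)
  # Parseval at the Nyquist limit, including the even-m Nyquist bin
  spN <- fourier_decompose(waveform_record(t, sq, "flow"), n_harmonics = m / 2)
  expect_equal(spectrum_mean_square(spN), mean(sq^2), tolerance = 1e-9)
  # and for a generic waveform
  fx <- generate_fixtures("toy_waveform", seed = 5)
  for (nm in c("sinusoid", "square", "half_rectified")) {
    x <- fx[[nm]]
    sp <- fourier_decompose(x, n_harmonics = length(x) / 2, dt = 1 / length(x))
    expect_equal(spectrum_mean_square(sp), mean(x^2), tolerance = 1e-9)
  }
})

test_that("TAWSS and OSI reach their analytic limits", {
  t <- seq(0, 1 - 1 / 512, by = 1 / 512)
  # unidirectional shear: no oscillation
  u <- tawss_osi(waveform_record(t, rep(2, 512), "shear"))
  expect_equal(u$tawss, 2)
  expect_equal(u$osi, 0)
  # zero-mean sinusoid: full reversal
  s <- tawss_osi(waveform_record(t, sin(2 * pi * t), "shear"))
  expect_equal(s$tawss, 2 / pi, tolerance = 1e-4)
  expect_equal(s$osi, 0.5, tolerance = 1e-6)
  # piecewise: +1 Pa for 75% of the cycle, -1 Pa for 25% -> TAWSS 1, OSI 0.25
  pw <- tawss_osi(ifelse(t < 0.75, 1, -1))
  expect_equal(pw$tawss, 1)
  expect_equal(pw$osi, 0.25)
  # sign flip leaves TAWSS; positive scaling leaves OSI
  x <- sin(2 * pi * t) + 0.4
  expect_equal(tawss_osi(-x)$tawss, tawss_osi(x)$tawss)
  expect_equal(tawss_osi(3.7 * x)$osi, tawss_osi(x)$osi, tolerance = 1e-12)
  # degenerate zero waveform warns and returns 0
  expect_warning(z <- tawss_osi(rep(0, 10)), "zero")
  expect_equal(z$osi, 0)
})

test_that("OSI stays within [0, 0.5] and TAWSS dominates the mean on model shear", {
  study <- reference_study()
  for (nm in c("control", "AS", "AR")) {
    per <- study[[nm]]$metrics$per_compartment
    expect_true(all(per["osi", ] >= 0 & per["osi", ] <= 0.5))
    expect_true(all(per["tawss", ] >= 0))
  }
})
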