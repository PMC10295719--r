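# shared helpers: small configurations and cached slow runs

# settle the default control model once per test run and reuse
settled_control <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_cycles(cv_config(), n_cycles = 30,
                                             record = "last")
    cache
  }
})

# one coupled three-scenario study at the reference configuration, cached
reference_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressWarnings(run_study(cv_config(), coupled = TRUE))
    cache
  }
})

expect_close <- function(actual, expected, rel = 0.01) {
  expect_lt(abs(actual - expected), rel * abs(expected))
}
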