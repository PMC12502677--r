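## Calibration tests run the optimizer at deliberately small problem sizes
## (coarse step, loose spin-up, few starts); the methods vignette records
## the production settings used for the shipped parameter values.
tiny <- list(dt = 600, conv_tol = 5e-3, max_cycles = 6,
             control = list(maxit = 8, reltol = 1e-3))

test_that("a fixed seed makes the whole multistart bit-reproducible", {
  c1 <- calibrate_growth("dynamic", n_starts = 2, seed = 11,
                         dt = tiny$dt, conv_tol = tiny$conv_tol,
                         max_cycles = tiny$max_cycles,
                         control = tiny$control)
  c2 <- calibrate_growth("dynamic", n_starts = 2, seed = 11,
                         dt = tiny$dt, conv_tol = tiny$conv_tol,
                         max_cycles = tiny$max_cycles,
                         control = tiny$control)
  expect_identical(coef(c1), coef(c2))
  expect_identical(c1$value, c2$value)
  ## a different seed explores different starts
  c3 <- calibrate_growth("dynamic", n_starts = 2, seed = 12,
                         dt = tiny$dt, conv_tol = tiny$conv_tol,
                         max_cycles = tiny$max_cycles,
                         control = tiny$control)
  expect_false(identical(coef(c1), coef(c3)))
})

test_that("the optimum dominates random feasible parameter vectors", {
  cal <- calibrate_growth("dynamic", n_starts = 3, seed = 5,
                          fe_levels = 40,
                          dt = tiny$dt, conv_tol = tiny$conv_tol,
                          max_cycles = tiny$max_cycles,
                          control = list(maxit = 20, reltol = 1e-3))
  b <- cal$bounds
  set.seed(99)
  probes <- vapply(1:20, function(i) {
    rates <- stats::setNames(
      b[1, ] + stats::runif(4) * (b[2, ] - b[1, ]), colnames(b))
    r <- suppressWarnings(run_diel(tricho_env(Fe_diss = 40), "dynamic",
                                   rates = rates, dt = tiny$dt,
                                   conv_tol = tiny$conv_tol,
                                   max_cycles = tiny$max_cycles))
    r$growth
  }, numeric(1))
  expect_gte(cal$value, max(probes) - 1e-6)
})

test_that("re-optimizing from the optimum does not improve growth materially", {
  ## fixed-point property under matched settings: polish an optimum, then
  ## polish again from it — the second pass must be near-idle
  a <- calibrate_growth("dynamic", n_starts = 1, seed = 7, fe_levels = 40,
                        start = calibrated_defaults("dynamic"),
                        dt = tiny$dt, conv_tol = tiny$conv_tol,
                        max_cycles = tiny$max_cycles,
                        control = list(maxit = 60, reltol = 1e-4))
  b <- calibrate_growth("dynamic", n_starts = 1, seed = 7, fe_levels = 40,
                        start = coef(a),
                        dt = tiny$dt, conv_tol = tiny$conv_tol,
                        max_cycles = tiny$max_cycles,
                        control = list(maxit = 60, reltol = 1e-4))
  expect_lt((b$value - a$value) / a$value, 0.01)
})

test_that("noise-free synthetic observations identify the generating growth", {
  ## self-consistent recovery: the generating parameters are an optimum of
  ## the test-size surface; observations taken from its run at zero noise;
  ## re-calibration (different seed) recovers the generating growth within
  ## 1% (parameters may be sloppy; growth is the identified quantity)
  set <- list(dt = 300, conv_tol = 1e-4, max_cycles = 40)
  cal0 <- calibrate_growth("dynamic", n_starts = 1, seed = 5,
                           fe_levels = 40,
                           start = calibrated_defaults("dynamic"),
                           dt = set$dt, conv_tol = set$conv_tol,
                           max_cycles = set$max_cycles,
                           control = list(maxit = 60, reltol = 1e-4))
  truth <- suppressWarnings(run_diel(
    tricho_env(Fe_diss = 40), "dynamic", rates = coef(cal0),
    dt = set$dt, conv_tol = set$conv_tol, max_cycles = set$max_cycles))
  obs <- make_synthetic_observations(truth, noise_cv = 0, n_times = 5,
                                     seed = 1)
  expect_identical(obs$growth, truth$growth)
  cal <- calibrate_growth("dynamic", n_starts = 2, seed = 3,
                          fe_levels = 40, start = coef(cal0),
                          dt = set$dt, conv_tol = set$conv_tol,
                          max_cycles = set$max_cycles,
                          control = list(maxit = 40, reltol = 1e-4))
  expect_lt(abs(cal$value - obs$growth) / obs$growth, 0.01)
  ## and the calibrated model reproduces the noise-free series
  m <- fit_metrics(predict(cal, fe_diss = 40), obs)
  expect_true(all(m$reliability_index < 1.25))
})

test_that("calibration surfaces and methods behave as a model fit", {
  cal <- calibrate_growth("fixed", n_starts = 1, seed = 2, fe_levels = 40,
                          dt = tiny$dt, conv_tol = tiny$conv_tol,
                          max_cycles = tiny$max_cycles,
                          control = tiny$control)
  expect_s3_class(cal, "tricho_calibration")
  expect_named(coef(cal), c("v_RP_max", "T_PS_max_BF", "T_BF_max_PS",
                            "T_NF_max_BF"))
  expect_output(print(cal), "growth-maximized")
  run <- predict(cal, fe_diss = 40)
  expect_s3_class(run, "diel_run")
  sims <- simulate(cal, nsim = 2, seed = 4, noise_cv = 0.1)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]]$fe_ps, sims[[2]]$fe_ps))
  expect_error(calibrate_growth("dynamic", bounds = matrix(1, 2, 3)),
               "2 x 4")
})
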