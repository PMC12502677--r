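p <- tricho_params()

test_that("half-sine light forcing hits its landmarks", {
  expect_equal(light_sine(6 * 3600, 140, 12), 140)
  expect_equal(light_sine(0, 140, 12), 0)
  expect_equal(light_sine(12 * 3600, 140, 12), 0)
  expect_equal(light_sine(3 * 3600, 140, 12), 140 * sin(pi / 4))
  expect_identical(light_sine(15 * 3600, 140, 12), 0)
  expect_identical(light_sine(-10, 140, 12), 0)
})

test_that("pure diffusion relaxes O2 along the exponential closed form", {
  ## dark, empty stores: the only active term is membrane diffusion, which
  ## is linear in the gradient, so the explicit integrator must track
  ## O2(t) = O2_ext + (O2_0 - O2_ext) exp(-g t)
  env <- tricho_env(Fe_diss = 0, O2_ext = 0.213)
  s <- cell_state(CH2O = 0, CS = 0, N = 0, O2 = 0.05,
                  Fe_PS = 0, Fe_NF = 0, Fe_buffer = 0, Fe_storage = 0,
                  Fe_maint = 0)
  g <- trichodiel:::o2_conductance(p$eps_fixed, p$geometry, p$d_O2)
  dt <- 0.05
  t <- 13 * 3600   # dark period
  x <- s
  o2 <- numeric(400)
  for (i in 1:400) {
    st <- diel_step(x, t + (i - 1) * dt, env, p, dt, mode = "fixed",
                    o2_method = "explicit")
    x <- st$state
    o2[i] <- x[["O2"]]
  }
  want <- 0.213 + (0.05 - 0.213) * exp(-g * (1:400) * dt)
  expect_equal(o2, want, tolerance = 1e-6)
  ## relaxation never overshoots the ambient level
  expect_true(all(o2 < 0.213))
  ## strictly monotone until it saturates at machine precision
  expect_true(all(diff(o2[1:100]) > 0))
  expect_true(all(diff(o2) >= 0))
})

test_that("explicit stepping refuses an unconditionally unstable dt", {
  env <- tricho_env(Fe_diss = 40)
  expect_error(diel_step(cell_state(), 0, env, p, dt = 5,
                         mode = "dynamic", o2_method = "explicit"),
               "unstable")
})

test_that("dark sealed cell with empty stores only flags starvation", {
  penv <- tricho_params(eps_fixed = 1e-12)
  env <- tricho_env(Fe_diss = 0, O2_ext = 0.213)
  s <- cell_state(CH2O = 0, CS = 0, N = 0, O2 = 0.213, Fe_PS = 0,
                  Fe_NF = 0, Fe_buffer = 0, Fe_storage = 0, Fe_maint = 0)
  st <- diel_step(s, 15 * 3600, env, penv, dt = 60, mode = "fixed")
  expect_equal(as.numeric(st$state), as.numeric(s), tolerance = 1e-12)
  expect_identical(unname(st$flux[["starved"]]), 1)
})

test_that("the QSS O2 root leaves a negligible mass-balance residual", {
  env <- tricho_env(Fe_diss = 40)
  cm <- trichodiel:::compile_model(env, p, "dynamic",
                                   calibrated_defaults("dynamic"))
  s <- as.numeric(cell_state(CH2O = 0.5, CS = 0.2, N = 0.01, O2 = 0.213,
                             Fe_PS = 60, Fe_NF = 15, Fe_buffer = 8,
                             Fe_storage = 20, Fe_maint = 3))
  for (t in c(1, 3, 5, 7, 9, 11) * 3600) {
    o2 <- trichodiel:::qss_root(cm$o2bal, t, s, NULL, s[[4]], env$O2_ext)
    ev <- cm$full(t, s, o2, NULL)
    gross <- ev$ch$P_O2 + ev$ch$C_O2 + abs(ev$ch$T_O2)
    expect_lt(abs(ev$ch$dO2), 1e-10 * max(gross, 1e-6))
  }
})

test_that("per-step energy closure: electron, ATP and NADPH books balance", {
  env <- tricho_env(Fe_diss = 40)
  st <- cell_state(CH2O = 0.5, CS = 0.2, N = 0.01, O2 = 0.3, Fe_PS = 80,
                   Fe_NF = 20, Fe_buffer = 10, Fe_storage = 30,
                   Fe_maint = 4)
  for (t in c(2, 5, 8, 10) * 3600) {
    fx <- diel_step(st, t, env, p, dt = 20, mode = "dynamic")$flux
    ## electron conservation, exactly
    expect_equal(fx[["V_LPET"]] + fx[["V_AET"]], fx[["V_PET"]],
                 tolerance = 1e-15)
    ## ATP production equals consumption
    atp_cons <- min(p$m_ATP, fx[["V_ATP"]]) + p$q_ATP_PR * fx[["V_PR"]] +
      p$q_ATP_NF * fx[["V_NF"]] +
      (p$q_ATP_CF + p$q_ATP_CCM) * fx[["V_CF"]]
    expect_lt(abs(fx[["V_ATP"]] - atp_cons) / max(fx[["V_ATP"]], 1e-12),
              1e-12)
    ## NADPH production (LPET yield) equals consumption
    nadph_prod <- p$y_NADPH_LPET * fx[["V_LPET"]]
    nadph_cons <- p$q_NADPH_PR * fx[["V_PR"]] +
      p$q_NADPH_NF * fx[["V_NF"]] + p$q_NADPH_CF * fx[["V_CF"]]
    expect_lt(abs(nadph_prod - nadph_cons) / max(nadph_prod, 1e-12), 1e-12)
    ## O2 source accounting: gross production is the LPET term alone
    expect_equal(fx[["P_O2"]],
                 p$y_O2_LPET * fx[["V_LPET"]] * p$rho_C,
                 tolerance = 1e-15)
  }
})

test_that("QSS and explicit integrations agree on the slow states", {
  env <- tricho_env(Fe_diss = 40)
  s0 <- cell_state(CH2O = 0.5, CS = 0.2, N = 0.01, O2 = 0.25, Fe_PS = 60,
                   Fe_NF = 10, Fe_buffer = 8, Fe_storage = 20,
                   Fe_maint = 3)
  t0 <- 2 * 3600
  horizon <- 1200           # 20 simulated minutes
  ## explicit RK4 at a stability-safe dt
  x <- s0
  for (i in seq_len(horizon / 0.1)) {
    x <- diel_step(x, t0 + (i - 1) * 0.1, env, p, 0.1, mode = "dynamic",
                   o2_method = "explicit")$state
  }
  ## QSS at a two-hundred-fold larger step
  y <- s0
  for (i in seq_len(horizon / 20)) {
    y <- diel_step(y, t0 + (i - 1) * 20, env, p, 20, mode = "dynamic")$state
  }
  slow <- c("CH2O", "CS", "N", "Fe_PS", "Fe_NF", "Fe_buffer",
            "Fe_storage", "Fe_maint", "logB")
  expect_equal(as.numeric(x[slow]), as.numeric(y[slow]), tolerance = 2e-3)
  expect_equal(x[["O2"]], y[["O2"]], tolerance = 5e-3)
  ## cross-check against an established stiff integrator on the same RHS
  skip_if_not_installed("deSolve")
  rhs <- function(t, y, parms) {
    list(trichodiel:::flux_eval(t, y, env, p, "dynamic",
                                calibrated_defaults("dynamic"),
                                O2 = max(y[[4]], 0))$d)
  }
  sol <- deSolve::lsoda(as.numeric(s0), times = c(t0, t0 + horizon), rhs,
                        rtol = 1e-8, atol = 1e-10)
  z <- sol[nrow(sol), -1]
  expect_equal(as.numeric(y[slow]),
               z[match(slow, trichodiel:::.state_names)],
               tolerance = 2e-3, ignore_attr = TRUE)
})

test_that("daily integrals are step-size converged and the budget closes", {
  base <- cached_run("dynamic", 40)
  expect_lt(abs(base$budget_closure), 0.005)
  expect_true(all(base$budget_fractions >= 0))
  expect_equal(sum(base$budget_fractions), 1, tolerance = 0.005)
  expect_gte(base$carbon_use_efficiency, 0)
  expect_lte(base$carbon_use_efficiency, 1)
  ## halving the step from the production default (20 s) changes daily
  ## integrals by less than 0.1%
  r1 <- suppressWarnings(run_diel(base$env, base$mode, rates = base$rates,
                                  dt = 20, conv_tol = 1e9, max_cycles = 1,
                                  init_state = base$final_state))
  r2 <- suppressWarnings(run_diel(base$env, base$mode, rates = base$rates,
                                  dt = 10, conv_tol = 1e9, max_cycles = 1,
                                  init_state = base$final_state))
  keys <- c("gross_carbon_fixation", "photorespiration",
            "respiratory_protection", "biosynthesis", "n2_fixation")
  rel <- abs(r2$daily[keys] - r1$daily[keys]) /
    pmax(abs(r1$daily[keys]), 1e-6)
  expect_true(all(rel < 1e-3))
})

test_that("perpetual darkness yields no growth beyond the initial stores", {
  env <- tricho_env(Fe_diss = 40, I_max = 0)
  r <- suppressWarnings(run_diel(env, "dynamic", dt = 120,
                                 conv_tol = 1e-4, max_cycles = 10))
  expect_lte(r$growth, 0.02)
  expect_gte(r$growth, 0)
  expect_identical(unname(r$daily[["gross_carbon_fixation"]]), 0)
})

test_that("the slim O2 balance agrees with the full evaluation everywhere", {
  ## the root solver uses a reduced evaluation of the O2 balance; it must
  ## be identical to the O2 tendency of the full derivative evaluation
  env <- tricho_env(Fe_diss = 40)
  for (mode in c("dynamic", "fixed")) {
    cm <- trichodiel:::compile_model(env, p, mode,
                                     calibrated_defaults(mode))
    set.seed(17)
    for (i in 1:150) {
      s <- as.numeric(cell_state(
        CH2O = runif(1, 0, 2), CS = runif(1, 0, 1),
        N = runif(1, 0, 0.06), O2 = runif(1, 0, 0.6),
        Fe_PS = runif(1, 0, 300), Fe_NF = runif(1, 0, 100),
        Fe_buffer = runif(1, 0, 50), Fe_storage = runif(1, 0, 300),
        Fe_maint = runif(1, 0, 20)))
      t <- runif(1, 0, 86400)
      o2 <- runif(1, 0, 0.6)
      expect_equal(cm$o2bal(t, s, o2, NULL),
                   cm$full(t, s, o2, NULL)$ch$dO2,
                   tolerance = 1e-12)
    }
  }
})
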