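p <- tricho_params()

test_that("PET requires light and photosystem Fe, and RP suppresses it", {
  expect_identical(pet_rate(0, 100, 0, p), 0)
  expect_identical(pet_rate(200, 0, 0, p), 0)
  set.seed(9)
  for (i in 1:40) {
    I <- runif(1, 1, 500); fe <- runif(1, 1, 400); rp <- runif(1, 0, 5e-4)
    expect_lte(pet_rate(I, fe, rp, p), pet_rate(I, fe, 0, p))
  }
  ## monotone in light and Fe
  g <- seq(0, 600, length.out = 60)
  expect_true(all(diff(pet_rate(g, 100, 0, p)) >= 0))
  expect_true(all(diff(pet_rate(100, g, 0, p)) >= 0))
})

test_that("electron partition solves the two-pathway yield system", {
  ## only ATP needed -> all AET
  sp <- partition_electrons(1e-3, atp_demand = 1e-4, nadph_demand = 0, p)
  expect_identical(sp$V_LPET, 0)
  expect_equal(sp$V_AET, 1e-3)
  ## demand ratio equal to LPET's intrinsic ATP:NADPH -> pure LPET
  rho_L <- p$y_ATP_LPET / p$y_NADPH_LPET
  sp2 <- partition_electrons(1e-3, rho_L * 5e-5, 5e-5, p)
  expect_equal(sp2$V_AET, 0, tolerance = 1e-15)
  ## intermediate ratios: compare against an algebraic 2x2 solve
  set.seed(21)
  for (i in 1:50) {
    atp <- runif(1, 1e-5, 1e-3); nadph <- runif(1, 1e-5, 1e-3)
    V <- runif(1, 1e-5, 2e-3)
    sp3 <- partition_electrons(V, atp, nadph, p)
    expect_equal(sp3$V_LPET + sp3$V_AET, V, tolerance = 1e-15)
    ## oracle: solve for the fraction f that matches the demand ratio,
    ## A = (aL f + aA (1-f)) V, N = nL f V, A/N = atp/nadph
    f_star <- p$y_ATP_AET /
      (p$y_ATP_AET + (atp / nadph) * p$y_NADPH_LPET - p$y_ATP_LPET)
    f_star <- min(1, max(0, f_star))
    expect_equal(sp3$V_LPET / V, f_star, tolerance = 1e-12)
    if (f_star > 0 && f_star < 1) {
      expect_equal(sp3$V_ATP / sp3$V_NADPH, atp / nadph, tolerance = 1e-9)
    }
  }
})

test_that("O2 evolution is exclusive to linear electron transport", {
  expect_identical(o2_evolution(0, 5e-4, p), 0)
  ## same total split all-AET vs all-LPET: zero vs maximal O2
  expect_identical(o2_evolution(0, 1e-3, p), 0)
  expect_equal(o2_evolution(1e-3, 0, p), p$y_O2_LPET * 1e-3)
  expect_equal(o2_evolution(3e-4, 0, p), 3 * o2_evolution(1e-4, 0, p))
})

## independent waterfall oracle: serve the priority list with cumulative
## bookkeeping written as a loop over (cost, cap) rows
waterfall_oracle <- function(A, N, d, p) {
  rows <- list(
    maintenance = c(qa = 1, qn = 0, cap = d$maintenance),
    V_PR = c(qa = p$q_ATP_PR, qn = p$q_NADPH_PR, cap = d$photorespiration),
    V_NF = c(qa = p$q_ATP_NF, qn = p$q_NADPH_NF, cap = d$n2_fixation),
    V_CF = c(qa = p$q_ATP_CF + p$q_ATP_CCM, qn = p$q_NADPH_CF,
             cap = d$carbon_fixation))
  out <- list()
  for (nm in names(rows)) {
    r <- rows[[nm]]
    f <- min(r[["cap"]],
             if (r[["qa"]] > 0) A / r[["qa"]] else Inf,
             if (r[["qn"]] > 0) N / r[["qn"]] else Inf)
    A <- A - r[["qa"]] * f
    N <- N - r[["qn"]] * f
    out[[nm]] <- f
  }
  c(out, list(atp_left = A, nadph_left = N))
}

test_that("energy allocation serves the priority list and never oversupplies", {
  d0 <- list(maintenance = 2e-6, photorespiration = 1e-5,
             n2_fixation = 5e-6, carbon_fixation = 1e-3)
  ## zero supply: everything zero, starvation flagged
  a <- allocate_energy(0, 0, d0, p)
  expect_true(a$starved)
  expect_identical(c(a$V_PR, a$V_NF, a$V_CF), c(0, 0, 0))
  ## supply exactly equal to maintenance: no C or N fixation
  a2 <- allocate_energy(2e-6, 0, d0, p)
  expect_false(a2$starved)
  expect_identical(c(a2$V_PR, a2$V_NF, a2$V_CF), c(0, 0, 0))
  ## generic vectors against the independent oracle
  set.seed(33)
  for (i in 1:100) {
    A <- runif(1, 0, 2e-3); N <- runif(1, 0, 1e-3)
    d <- list(maintenance = runif(1, 0, 1e-5),
              photorespiration = runif(1, 0, 5e-5),
              n2_fixation = runif(1, 0, 2e-5),
              carbon_fixation = runif(1, 0, 5e-4))
    got <- allocate_energy(A, N, d, p)
    want <- waterfall_oracle(A, N, d, p)
    expect_equal(got$maintenance, want$maintenance, tolerance = 1e-14)
    expect_equal(got$V_PR, want$V_PR, tolerance = 1e-14)
    expect_equal(got$V_NF, want$V_NF, tolerance = 1e-14)
    expect_equal(got$V_CF, want$V_CF, tolerance = 1e-14)
    expect_equal(got$atp_left, want$atp_left, tolerance = 1e-14)
    ## no demand over-satisfied
    expect_lte(got$V_PR, d$photorespiration + 1e-18)
    expect_lte(got$V_NF, d$n2_fixation + 1e-18)
    expect_lte(got$V_CF, d$carbon_fixation + 1e-18)
    ## conservation identity: consumption + leftovers == supply
    cons_A <- got$maintenance + p$q_ATP_PR * got$V_PR +
      p$q_ATP_NF * got$V_NF + (p$q_ATP_CF + p$q_ATP_CCM) * got$V_CF
    cons_N <- p$q_NADPH_PR * got$V_PR + p$q_NADPH_NF * got$V_NF +
      p$q_NADPH_CF * got$V_CF
    expect_equal(cons_A + got$atp_left, A, tolerance = 1e-12)
    expect_equal(cons_N + got$nadph_left, N, tolerance = 1e-12)
    ## with an unsaturated residual sink, one currency is fully drained
    if (got$V_CF < d$carbon_fixation - 1e-12) {
      expect_lt(min(got$atp_left, got$nadph_left), 1e-15)
    }
  }
})

test_that("partition at the allocation's demand closes both energy currencies", {
  ## the closure used by the integrator: supplies from partition_electrons
  ## evaluated at the demands realized by allocate_energy leave no leftovers
  V_PET <- 1.2e-3
  A_supply <- p$y_ATP_AET * V_PET
  d <- list(maintenance = 2e-6, photorespiration = 1.5e-5,
            n2_fixation = 8e-6, carbon_fixation = 1)
  a <- allocate_energy(A_supply, Inf, d, p)
  N_dem <- p$q_NADPH_PR * a$V_PR + p$q_NADPH_NF * a$V_NF +
    p$q_NADPH_CF * a$V_CF
  A_dem <- A_supply - a$atp_left
  sp <- partition_electrons(V_PET, A_dem, N_dem, p)
  a2 <- allocate_energy(sp$V_ATP, sp$V_NADPH, d, p)
  expect_lt(abs(a2$atp_left) / A_supply, 1e-12)
  expect_lt(abs(a2$nadph_left) / A_supply, 1e-12)
})

test_that("carbon-skeleton production is stimulated by CH2O, inhibited by CS", {
  expect_identical(carbon_skeleton_production(0, 0.5, p), 0)
  g <- seq(0, 3, length.out = 60)
  expect_true(all(diff(carbon_skeleton_production(g, 0.2, p)) >= 0))
  expect_true(all(diff(carbon_skeleton_production(0.5, g, p)) <= 0))
  expect_true(all(carbon_skeleton_production(g, 0.01, p) <= p$v_CS_max))
})
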