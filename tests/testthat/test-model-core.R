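# Structural model: drug kinetics, turnover ODE, covariates, and the
# bicarbonate -> MV -> PaCO2 chain.

test_that("drug amount follows bolus superposition with a 6-h half-life", {
  d <- dose_events(0, 500)
  expect_equal(drug_amount(d, 0.25, 0.25), 250)           # one half-life
  expect_equal(drug_amount(dose_events(numeric(0)), 0.25, c(0, 1)), c(0, 0))
  d2 <- dose_events(c(0, 0.5), 500)
  expect_equal(drug_amount(d2, 0.25, 0.5), 500 * 2^-2 + 500)  # 625
  # right-continuous: the dose at t is included at its own time
  expect_equal(drug_amount(d, 0.25, 0), 500)
  # unsorted inputs are sorted internally
  d3 <- data.frame(time = c(1, 0), amount = c(100, 200))
  expect_equal(drug_amount(d3, 0.25, 1), 200 * 2^-4 + 100)
  expect_error(drug_amount(d, 0.25, -1), "times")
  expect_error(drug_amount(d, 0, 1), "half_life")
})

test_that("drug amount is additive over dose lists (superposition)", {
  set.seed(42)
  for (rep in 1:5) {
    tA <- sort(runif(4, 0, 3)); tB <- sort(runif(3, 0, 3))
    aA <- runif(4, 100, 600); aB <- runif(3, 100, 600)
    both <- dose_events(c(tA, tB), c(aA, aB))
    tt <- runif(6, 0, 4)
    expect_equal(drug_amount(both, 0.25, tt),
                 drug_amount(dose_events(tA, aA), 0.25, tt) +
                   drug_amount(dose_events(tB, aB), 0.25, tt))
  }
})

test_that("kin is derived from the equilibrium condition", {
  expect_equal(derive_kin(35.4, 0.314), 11.1156)
  expect_equal(derive_kin(35.4, 0), 0)
  expect_equal(derive_kin(1, 1), 1)
  expect_error(derive_kin(-1, 0.3), "non-negative")
})

test_that("covariates act multiplicatively on baseline bicarbonate", {
  fx <- fixed_effects()
  expect_equal(covariate_bicar0(covariate_set(50, 100, FALSE), fx), 35.4)
  expect_equal(covariate_bicar0(covariate_set(50, 100, TRUE), fx),
               35.4 * 1.10)  # 38.94
  expect_equal(covariate_bicar0(covariate_set(50, 110, FALSE), fx),
               35.4 * 1.1^-1.17)  # ~31.66
  expect_error(covariate_set(saps2 = -2), "saps2")
})

test_that("zero-dose trajectories stay at equilibrium", {
  ind <- pop_individual()
  fx <- fixed_effects()
  B <- bicar_trajectory(ind, fx, times = seq(0, 10, 0.25))
  expect_lt(max(abs(B / ind$bicar0_i - 1)), 1e-6)
  # the whole chain is constant too
  tr <- simulate_trajectory(ind, fx, covariate_set(), times = seq(0, 10, 1))
  expect_lt(max(abs(tr$mv / tr$mv[1] - 1)), 1e-6)
  expect_lt(max(abs(tr$paco2 / tr$paco2[1] - 1)), 1e-6)
})

test_that("clamped-amount trajectories converge to the closed-form steady state", {
  ind <- pop_individual()
  fx <- fixed_effects()
  horizon <- ceiling(10 / ind$kout_i) + 10  # >= 10/kout days
  tt <- seq(0, horizon, length.out = 30)
  # A clamped at a50: stimulation 1/2 -> B0 / 1.5
  B <- bicar_trajectory(ind, fx, times = tt, clamp = list(acz = fx$a50))
  expect_equal(bicar_steady_state(ind, fx, acz = fx$a50), 35.4 / 1.5)
  expect_lt(abs(B[length(tt)] / (35.4 / 1.5) - 1), 0.001)
  # A -> infinity: B0 / (1 + emax)
  B2 <- bicar_trajectory(ind, fx, times = tt, clamp = list(acz = 1e9))
  expect_lt(abs(B2[length(tt)] / (35.4 / 2) - 1), 0.001)
  # furosemide clamp at fur50 raises the plateau by 1.5
  B3 <- bicar_trajectory(ind, fx, times = tt, clamp = list(fur = fx$fur50))
  expect_lt(abs(B3[length(tt)] / (35.4 * 1.5) - 1), 0.001)
})

test_that("the analytic solver matches adaptive lsoda integration", {
  ind <- pop_individual()
  fx <- fixed_effects()
  ace <- bid_doses(500, 4)
  fur <- dose_events(c(0, 1, 2, 3), 40, "fur")
  tt <- sort(c(seq(0.1, 4, 0.35), 2.0))
  B1 <- bicar_trajectory(ind, fx, ace, fur, tt)
  B2 <- bicar_trajectory(ind, fx, ace, fur, tt, method = "lsoda")
  expect_lt(max(abs(B1 - B2)), 1e-4)
  # and with a fast individual turnover rate
  ind2 <- list(bicar0_i = 35.4, kout_i = 3.1)
  B3 <- bicar_trajectory(ind2, fx, ace, NULL, tt)
  B4 <- bicar_trajectory(ind2, fx, ace, NULL, tt, method = "lsoda")
  expect_lt(max(abs(B3 - B4)), 1e-4)
})

test_that("responses are monotone in total acetazolamide dose", {
  ind <- pop_individual()
  fx <- fixed_effects()
  cov <- covariate_set()
  tt <- c(1, 2, 4)
  prev_b <- rep(Inf, 3); prev_mv <- rep(0, 3); prev_pa <- rep(Inf, 3)
  for (amt in c(0, 250, 500, 1000)) {
    doses <- if (amt > 0) bid_doses(amt, 4) else NULL
    tr <- simulate_trajectory(ind, fx, cov, doses, NULL, tt)
    expect_true(all(tr$bicar <= prev_b + 1e-10))
    expect_true(all(tr$mv >= prev_mv - 1e-10))
    expect_true(all(tr$paco2 <= prev_pa + 1e-10))
    prev_b <- tr$bicar; prev_mv <- tr$mv; prev_pa <- tr$paco2
  }
})

test_that("the MV link reproduces the reference products", {
  fx <- fixed_effects()
  ind <- pop_individual()
  expect_equal(mv_from_bicar(ind, fx, covariate_set(), 37.5), 11.1)
  expect_equal(mv_from_bicar(ind, fx,
                             covariate_set(female = TRUE, volume_assist = TRUE),
                             37.5),
               11.1 * 0.92 * 0.82)  # ~8.37
  expect_equal(mv_from_bicar(ind, fx, covariate_set(), 18.75),
               11.1 * 2^0.67)  # ~17.66, maximal-effect ceiling
  # strictly decreasing in bicarbonate
  b <- seq(20, 45, 1)
  expect_true(all(diff(mv_from_bicar(ind, fx, covariate_set(), b)) < 0))
  expect_error(mv_from_bicar(ind, fx, covariate_set(), 0), "bicar")
})

test_that("the PaCO2 link is a power of the MV ratio", {
  ind <- pop_individual()
  expect_equal(paco2_from_mv(ind, 11.1, 11.1), 54.4)
  expect_equal(paco2_from_mv(ind, 2 * 11.1, 11.1), 54.4 * 2^-0.71)  # ~33.3
  ind0 <- ind; ind0$pow_mv_paco2_i <- 0
  expect_equal(paco2_from_mv(ind0, 25, 11.1), 54.4)
  mv <- seq(6, 20, 0.5)
  expect_true(all(diff(paco2_from_mv(ind, mv, 11.1)) < 0))
  expect_error(paco2_from_mv(ind, -1, 11.1), "mv")
})

test_that("the chain is exactly consistent at baseline", {
  fx <- fixed_effects()
  set.seed(7)
  for (rep in 1:5) {
    cov <- covariate_set(saps2 = runif(1, 30, 80),
                         chloride = runif(1, 90, 112),
                         corticosteroid = runif(1) < 0.5,
                         female = runif(1) < 0.5,
                         volume_assist = runif(1) < 0.5)
    ind <- sample_individual(fx, random_effects(), cov)
    tr <- simulate_trajectory(ind, fx, cov, bid_doses(500, 2), NULL,
                              times = c(0, 1))
    expect_identical(tr$bicar[1], ind$bicar0_i)
    expect_equal(tr$mv[1], mv_from_bicar(ind, fx, cov, ind$bicar0_i))
    expect_identical(tr$paco2[1], ind$paco2_0_i)
  }
})
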