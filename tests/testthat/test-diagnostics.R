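# NPDE computation and tests, shrinkage, observed-vs-predicted tables.

test_that("npde location/scale/normality tests behave on known samples", {
  set.seed(61)
  x <- rnorm(1000)
  p <- npde_tests(x)
  expect_gt(p$wilcoxon_p, 0.05)
  expect_gt(p$fisher_var_p, 0.05)
  expect_gt(p$normality_p, 0.05)
  expect_lt(npde_tests(x + 1)$wilcoxon_p, 1e-3)
  expect_lt(npde_tests(x * 3)$fisher_var_p, 1e-3)
  expect_error(npde_tests(rep(1, 20)), "constant")
  expect_error(npde_tests(rnorm(5)), "at least 10")
})

test_that("an observation at the simulation median has npde near zero", {
  # untreated subjects, no BSV: simulations are independent proportional
  # noise around a constant, so the covariance is diagonal and the
  # median equals the prediction
  fx <- fixed_effects()
  par <- model_parameters(fx, random_effects(0, 0, 0, 0, 0),
                          residual_error())
  subs <- lapply(1:4, function(i)
    subject_record(i, covariate_set(),
                   observations = data.frame(time = c(0.5, 1, 2),
                                             dvid = "BICAR",
                                             value = 35.4)))
  ds <- structure(list(subjects = subs), class = "acz_dataset")
  np <- compute_npde(ds, par, n_sim = 1000, seed = 9)
  expect_lt(max(abs(np$table$npde)), 0.3)
  expect_true(all(abs(np$table$pd - 0.5) < 0.1))
})

test_that("npde are calibrated on data simulated from the true model", {
  truth <- truth_params()
  ds <- generate_cohort(truth, design_config(n_subjects = 200), seed = 21)
  np <- compute_npde(ds, truth, n_sim = 500, seed = 4)
  expect_lt(abs(mean(np$table$npde)), 0.06)
  expect_gt(var(np$table$npde), 0.9)
  expect_lt(var(np$table$npde), 1.1)
  expect_gt(np$tests$all$wilcoxon_p, 0.01)
  expect_gt(np$tests$all$fisher_var_p, 0.01)
  # per-dvid tables are populated
  expect_setequal(names(np$tests), c("BICAR", "MV", "PACO2", "all"))
  expect_equal(nrow(np$table), sum(summarize_cohort(ds)$n))
})

test_that("npde values are stable in the number of simulations", {
  truth <- truth_params()
  ds <- generate_cohort(truth, design_config(n_subjects = 30), seed = 33)
  npA <- compute_npde(ds, truth, n_sim = 500, seed = 1)
  npB <- compute_npde(ds, truth, n_sim = 2000, seed = 2)
  # same observations ranked against two independent simulation sets
  expect_gt(cor(npA$table$npde, npB$table$npde), 0.95)
  expect_lt(mean(abs(npA$table$npde - npB$table$npde)), 0.15)
})

test_that("shrinkage follows its defining identity", {
  expect_equal(shrinkage(c(-0.1, 0.1), sd(c(-0.1, 0.1))), 0)
  expect_equal(shrinkage(rep(0, 10), 0.3), 1)
  set.seed(8)
  etas <- rnorm(50)
  etas <- (etas - mean(etas)) / sd(etas) * 0.05
  expect_equal(shrinkage(etas, 0.10), 0.5)
  expect_error(shrinkage(etas, 0), "omega")
  expect_error(shrinkage(0.2, 0.1), "2 subjects")
})

test_that("observed-vs-predicted tables align and regress near identity", {
  # noise-free data at the population parameters: a zero-iteration fit
  # at the truth predicts every observation exactly
  par0 <- model_parameters(fixed_effects(),
                           random_effects(0, 0, 0, 0, 0),
                           residual_error(1e-12, 1e-12, 1e-12))
  des <- design_config(n_subjects = 8)
  ds0 <- generate_cohort(par0, des, seed = 12)
  fit0 <- fit_saem(ds0, par0, saem_config(n_burn = 0, n_smooth = 0,
                                          compute_ll = FALSE))
  g0 <- gof_tables(ds0, fit0)
  expect_equal(g0$table$observed, g0$table$pred_ind, tolerance = 1e-6)
  expect_equal(g0$table$observed, g0$table$pred_pop, tolerance = 1e-6)
  expect_equal(nrow(g0$table), sum(summarize_cohort(ds0)$n))
  # a short fit on noisy data: slope of observed ~ individual
  # prediction close to the identity line
  ds <- generate_cohort(truth_params(), design_config(n_subjects = 25),
                        seed = 13)
  fit <- fit_saem(ds, truth_params(),
                  saem_config(n_burn = 60, n_smooth = 40, seed = 3,
                              compute_ll = FALSE))
  g <- gof_tables(ds, fit)
  expect_gt(g$slopes[["MV"]], 0.9)
  expect_lt(g$slopes[["MV"]], 1.1)
  expect_gt(g$slopes[["BICAR"]], 0.9)
  expect_lt(g$slopes[["BICAR"]], 1.1)
  # PaCO2 carries only ~3 observations per subject: empirical-Bayes
  # shrinkage compresses the individual predictions, which tilts the
  # observed-on-predicted regression above the identity line
  expect_gt(g$slopes[["PACO2"]], 0.85)
  expect_lt(g$slopes[["PACO2"]], 1.35)
})
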