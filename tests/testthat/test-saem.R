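# SAEM estimation, importance-sampling likelihood, model comparison and
# covariate selection.

test_that("a zero-iteration fit returns the initial values unchanged", {
  ds <- generate_cohort(truth_params(), design_config(n_subjects = 5), seed = 3)
  init <- truth_params()
  fit <- fit_saem(ds, init, saem_config(n_burn = 0, n_smooth = 0,
                                        compute_ll = FALSE))
  expect_equal(unlist(fit$fixed), unlist(init$fixed))
  expect_equal(unlist(fit$random), unlist(init$random))
  expect_equal(unlist(fit$residual), unlist(init$residual))
  expect_equal(fit$eta_hat, matrix(0, 5, 5,
                                   dimnames = list(NULL, colnames(fit$eta_hat))))
})

test_that("near-noiseless data are recovered to within a few percent", {
  truth <- model_parameters(fixed_effects(),
                            random_effects(0, 0, 0, 0, 0),
                            residual_error(0.01, 0.01, 0.01))
  des <- design_config(n_subjects = 30,
                       mv_count = list(min = 12, size = 1, prob = 0.5),
                       gas_count = list(min = 5, size = 1, prob = 0.5))
  ds <- generate_cohort(truth, des, seed = 77)
  init <- model_parameters(
    fixed_effects(bicar0_pop = 30, kout = 0.2, a50 = 250, mv0_pop = 9,
                  paco2_0_pop = 45, pow_bicar_mv = 0.5, pow_mv_paco2 = 0.5),
    random_effects(0.1, 0.1, 0.1, 0.1, 0.1),
    residual_error(0.05, 0.05, 0.05))
  fit <- fit_saem(ds, init, saem_config(n_burn = 400, n_smooth = 300,
                                        n_mcmc = 3, seed = 8,
                                        compute_ll = FALSE))
  tv <- unlist(truth$fixed); tr <- unlist(fit$fixed)
  for (p in c("bicar0_pop", "kout", "a50", "mv0_pop", "paco2_0_pop",
              "pow_bicar_mv", "pow_mv_paco2"))
    expect_lt(abs(tr[[p]] / tv[[p]] - 1), 0.02, label = p)
  # residual sigma collapses towards the generating 1%
  expect_lt(fit$residual$MV, 0.03)
  # the trace has stabilized: last-quarter CV below 5%
  tr_m <- fit$trace[, c("bicar0_pop", "kout", "a50", "mv0_pop",
                        "paco2_0_pop", "pow_bicar_mv", "pow_mv_paco2")]
  lastq <- tr_m[seq(floor(nrow(tr_m) * 0.75), nrow(tr_m)), ]
  cvs <- apply(lastq, 2, function(x) sd(x) / mean(x))
  expect_true(all(cvs < 0.05))
})

test_that("importance sampling agrees with quadrature and the plug-in limit", {
  fx <- fixed_effects(); cov <- covariate_set()
  sub <- subject_record(1, cov,
                        observations = data.frame(time = c(0.2, 0.6, 1.1),
                                                  dvid = "BICAR",
                                                  value = c(34.1, 36.0, 35.2)))
  ds1 <- structure(list(subjects = list(sub)), class = "acz_dataset")
  par1 <- model_parameters(fx, random_effects(0.10, 0, 0, 0, 0),
                           residual_error())
  ll_is <- loglik_importance(ds1, par1, n_is = 8000, seed = 2)
  # 1-D quadrature oracle over the only active random effect
  res <- residual_error()
  f <- function(eta) vapply(eta, function(e) {
    ind <- list(bicar0_i = covariate_bicar0(cov, fx) * exp(e),
                kout_i = fx$kout, mv0_i = fx$mv0_pop,
                paco2_0_i = fx$paco2_0_pop, pow_mv_paco2_i = fx$pow_mv_paco2)
    exp(individual_loglik(sub, ind, fx, res) + dnorm(e, 0, 0.10, log = TRUE))
  }, numeric(1))
  ll_quad <- log(integrate(f, -0.6, 0.6, rel.tol = 1e-10)$value)
  expect_lt(abs(ll_is$loglik - ll_quad), 0.01)
  # omega -> 0: importance sampling collapses to the plug-in likelihood
  par0 <- model_parameters(fx, random_effects(0, 0, 0, 0, 0), residual_error())
  ll0 <- loglik_importance(ds1, par0, n_is = 50, seed = 3)
  ind0 <- sample_individual(fx, random_effects(0, 0, 0, 0, 0), cov)
  expect_equal(ll0$loglik, individual_loglik(sub, ind0, fx, res))
  # Monte-Carlo error shrinks roughly as 1/sqrt(n_is)
  se_small <- mean(vapply(1:8, function(s)
    loglik_importance(ds1, par1, n_is = 250, seed = s)$se, numeric(1)))
  se_big <- mean(vapply(1:8, function(s)
    loglik_importance(ds1, par1, n_is = 1000, seed = 100 + s)$se, numeric(1)))
  expect_lt(abs(se_small / se_big - 2), 0.8)
})

test_that("AIC and LRT comparisons follow their definitions", {
  ds <- generate_cohort(truth_params(), design_config(n_subjects = 6), seed = 4)
  fit <- fit_saem(ds, truth_params(),
                  saem_config(n_burn = 0, n_smooth = 0, ll_nsim = 100))
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$n_free)
  cmp <- compare_models(fit, fit)
  expect_equal(cmp$delta_aic, 0)
  expect_equal(cmp$lrt, 0)
  expect_equal(cmp$p, 1)
  expect_equal(cmp$df, 0L)
  # a smaller covariate model is nested in the default; the reverse is not
  fit0 <- fit_saem(ds, truth_params(),
                   saem_config(n_burn = 0, n_smooth = 0, ll_nsim = 100),
                   model = model_spec(covariates = list(bicar0 = "chloride")))
  cmp2 <- compare_models(fit0, fit)
  expect_equal(cmp2$df, fit$n_free - fit0$n_free)
  expect_true(cmp2$p >= 0 && cmp2$p <= 1)
  expect_warning(compare_models(fit, fit0), "not nested")
})

test_that("forward selection keeps a real covariate and drops a noise one", {
  # truth carries a strong chloride effect on baseline bicarbonate and
  # no sex effect on kout
  ds <- generate_cohort(truth_params(),
                        design_config(n_subjects = 40), seed = 15)
  cfg <- saem_config(n_burn = 80, n_smooth = 60, seed = 5, ll_nsim = 500)
  base <- model_spec(covariates = list(bicar0 = c("saps", "cortico"),
                                       mv0 = c("va", "female")))
  sel <- select_covariates(ds, neutral_init(), cfg, base,
                           candidates = list(c("bicar0", "chloride"),
                                             c("kout", "female")))
  expect_true("chloride" %in% sel$model$covariates$bicar0)
  expect_false("female" %in% sel$model$covariates$kout)
  expect_true(any(sel$report$kept))
  # no candidates: the base model comes back untouched
  sel0 <- select_covariates(ds, neutral_init(),
                            saem_config(n_burn = 0, n_smooth = 0,
                                        ll_nsim = 100),
                            base, candidates = list())
  expect_identical(sel0$model, base)
  expect_equal(nrow(sel0$report), 0L)
})

test_that("standard errors from the score information are sane and calibrated", {
  truth <- model_parameters(
    fixed_effects(beta_saps = 0, beta_chloride = 0, cortico_mult = 1,
                  va_mult = 1, female_mult = 1),
    random_effects(0.1, 0.001, 0.001, 0.001, 0.001),
    residual_error(0.05, 0.05, 0.05))
  des <- design_config(n_subjects = 40, dose_options = 0, p_fur = 0,
                       p_cortico = 0, p_female = 0, p_va = 0,
                       mv_count = list(min = 2, size = 1, prob = 0.5),
                       gas_count = list(min = 4, size = 1, prob = 0.5))
  ds <- generate_cohort(truth, des, seed = 55)
  fit <- fit_saem(ds, truth, saem_config(n_burn = 80, n_smooth = 60, seed = 6,
                                         compute_ll = FALSE),
                  model = model_spec(covariates = NULL))
  fit <- estimate_rse(fit, ds, n_draws = 50)
  expect_true(all(is.finite(fit$rse)) && all(fit$rse > 0))
  # baseline bicarbonate: %rse should be near sqrt(omega^2/n)*100 ~ 1.7
  expect_gt(fit$rse[["bicar0.intercept"]], 0.4)
  expect_lt(fit$rse[["bicar0.intercept"]], 5)
  # residual sigma for the richly sampled bicarbonate: ~ 1/sqrt(2*m) ~ 5.6%
  expect_lt(fit$rse[["sigma_bicar"]], 15)
})
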