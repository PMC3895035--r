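# Synthetic-cohort generator: design emulation, determinism, summaries.

test_that("the default design reproduces the reference observation volume", {
  ds <- generate_cohort(truth_params(), design_config(), seed = 2024)
  expect_length(ds$subjects, 68)
  sm <- summarize_cohort(ds)
  n_mv <- sm$n[sm$dvid == "MV"]
  n_b <- sm$n[sm$dvid == "BICAR"]
  n_p <- sm$n[sm$dvid == "PACO2"]
  # design targets: ~619 minute-ventilation and ~207 blood-gas
  # observations, within 15%
  expect_lt(abs(n_mv / 619 - 1), 0.15)
  expect_lt(abs(n_b / 207 - 1), 0.15)
  expect_lt(abs(n_p / 207 - 1), 0.15)
  expect_equal(n_b, n_p)  # paired blood gases
  expect_equal(sm$median_per_subject[sm$dvid == "MV"], 9)
  expect_equal(sm$median_per_subject[sm$dvid == "BICAR"], 3)
  expect_true(sm$min_per_subject[sm$dvid == "MV"] >= 2)
  expect_true(sm$max_per_subject[sm$dvid == "MV"] <= 14)
  expect_true(sm$max_per_subject[sm$dvid == "BICAR"] <= 6)
})

test_that("a noise-free untreated cohort sits at the covariate-adjusted baselines", {
  par0 <- model_parameters(fixed_effects(),
                           random_effects(0, 0, 0, 0, 0),
                           residual_error(1e-12, 1e-12, 1e-12))
  des <- design_config(n_subjects = 6, dose_options = 0, p_fur = 0)
  ds <- generate_cohort(par0, des, seed = 5)
  fx <- fixed_effects()
  for (s in ds$subjects) {
    expect_equal(nrow(s$ace_doses), 0L)
    ind <- sample_individual(fx, random_effects(0, 0, 0, 0, 0), s$covariates)
    b0 <- covariate_bicar0(s$covariates, fx)
    mv0 <- mv_from_bicar(ind, fx, s$covariates, b0)
    obs <- s$observations
    expect_equal(obs$value[obs$dvid == "BICAR"],
                 rep(b0, sum(obs$dvid == "BICAR")), tolerance = 1e-9)
    expect_equal(obs$value[obs$dvid == "MV"],
                 rep(mv0, sum(obs$dvid == "MV")), tolerance = 1e-9)
    expect_equal(obs$value[obs$dvid == "PACO2"],
                 rep(fx$paco2_0_pop, sum(obs$dvid == "PACO2")),
                 tolerance = 1e-9)
  }
})

test_that("generation is reproducible and the written file byte-identical", {
  des <- design_config(n_subjects = 10)
  ds1 <- generate_cohort(truth_params(), des, seed = 31)
  ds2 <- generate_cohort(truth_params(), des, seed = 31)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_dataset(ds1, f1); write_dataset(ds2, f2)
  expect_identical(readLines(f1), readLines(f2))
  ds3 <- generate_cohort(truth_params(), des, seed = 32)
  expect_false(identical(as.data.frame(ds1), as.data.frame(ds3)))
})

test_that("cohort summaries aggregate like a plain concatenation", {
  dsA <- generate_cohort(truth_params(), design_config(n_subjects = 7), seed = 1)
  dsB <- generate_cohort(truth_params(), design_config(n_subjects = 5), seed = 2)
  for (i in seq_along(dsB$subjects))
    dsB$subjects[[i]]$id <- dsB$subjects[[i]]$id + 100
  merged <- structure(list(subjects = c(dsA$subjects, dsB$subjects)),
                      class = "acz_dataset")
  sm <- summarize_cohort(merged)
  # brute-force oracle on the concatenated observation table
  tab <- do.call(rbind, lapply(merged$subjects, function(s)
    cbind(id = s$id, s$observations)))
  for (d in c("BICAR", "MV", "PACO2")) {
    sel <- tab[tab$dvid == d, ]
    expect_equal(sm$n[sm$dvid == d], nrow(sel))
    expect_equal(sm$mean[sm$dvid == d], mean(sel$value))
    expect_equal(sm$median_per_subject[sm$dvid == d],
                 median(as.integer(table(sel$id))))
  }
  # single subject with 3 observations counts as n = 3
  one <- structure(list(subjects = list(toy_subject())), class = "acz_dataset")
  expect_equal(sum(summarize_cohort(one)$n), 3L)
})

test_that("generated values are consistent with the generating hierarchy", {
  # untreated, noise-free in MV terms: mean MV near the 11 L/min baseline
  par <- model_parameters()
  des <- design_config(n_subjects = 120, dose_options = 0, p_fur = 0)
  ds <- generate_cohort(par, des, seed = 77)
  sm <- summarize_cohort(ds)
  expect_gt(sm$mean[sm$dvid == "MV"], 9.5)
  expect_lt(sm$mean[sm$dvid == "MV"], 13)
  # empirical BSV of log baseline bicarbonate close to omega after
  # removing the covariate part (sigma_bicar = 0.044 adds little)
  fx <- fixed_effects()
  lb <- vapply(ds$subjects, function(s) {
    b <- s$observations$value[s$observations$dvid == "BICAR"]
    if (length(b) == 0L) return(NA_real_)
    log(mean(b) / covariate_bicar0(s$covariates, fx))
  }, numeric(1))
  expect_lt(abs(sd(lb, na.rm = TRUE) / 0.10 - 1), 0.30)
})
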