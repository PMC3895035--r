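# Shared fixtures: all synthetic, built in code.

# published reference parameters (package defaults)
truth_params <- function() model_parameters()

# deterministic individual at the population values (no BSV)
pop_individual <- function(cov = covariate_set()) {
  sample_individual(fixed_effects(), random_effects(0, 0, 0, 0, 0), cov)
}

# a twice-daily acetazolamide schedule over `duration` days
bid_doses <- function(amount = 500, duration = 4) {
  dose_events(seq(0, duration - 0.5, by = 0.5), amount, "acz")
}

# neutral starting values for estimation tests: plausible clinical
# guesses, deliberately away from the generating truth
neutral_init <- function() {
  model_parameters(
    fixed_effects(bicar0_pop = 30, kout = 0.15, a50 = 300, mv0_pop = 9,
                  paco2_0_pop = 45, pow_bicar_mv = 0.5, pow_mv_paco2 = 0.5,
                  beta_saps = 0, beta_chloride = 0, cortico_mult = 1,
                  va_mult = 1, female_mult = 1),
    random_effects(0.3, 0.3, 0.3, 0.3, 0.3),
    residual_error(0.15, 0.15, 0.15))
}

# small single-subject record with mixed observation types
toy_subject <- function(values = c(34, 12, 50), times = c(0.25, 0.5, 1)) {
  subject_record(1, covariate_set(),
                 ace_doses = bid_doses(250, 2),
                 observations = data.frame(
                   time = times, dvid = c("BICAR", "MV", "PACO2"),
                   value = values))
}
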