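#' Fixed (population) effects of the acetazolamide turnover model
#'
#' Constructs the set of population-level structural and covariate
#' parameters of the model. Defaults are the final population estimates
#' reported for the reference cohort of 68 invasively ventilated COPD
#' patients, so `fixed_effects()` with no arguments gives the published
#' model.
#'
#' The structural chain is: an IV-bolus one-compartment drug amount
#' \eqn{A(t)} (half-life fixed at 0.25 day, i.e. 6 h) stimulates the
#' elimination side of a bicarbonate turnover equation
#' \deqn{dB/dt = k_{in}(1 + F/(F+F_{50})) - k_{out}(1 + E_{max} A/(A+A_{50})) B}
#' with \eqn{k_{in} = k_{out} \times Bicar_0} (equilibrium at t = 0).
#' Minute ventilation is \eqn{MV = MV_0 (37.5/B)^{0.67}} (times mode and
#' sex multipliers), and \eqn{PaCO_2 = PaCO2_0 (MV_0/MV)^{0.71}}.
#'
#' @param bicar0_pop baseline serum bicarbonate, mmol/L.
#' @param kout first-order bicarbonate turnover rate constant, /day.
#' @param a50 acetazolamide body amount giving half-maximal effect, mg.
#' @param emax maximal fractional stimulation of elimination
#'   (dimensionless, in (0, 1]; fixed at 1 in the final model because
#'   `emax` and `a50` are not jointly identifiable).
#' @param fur50 furosemide body amount giving half-maximal stimulation of
#'   bicarbonate formation, mg.
#' @param mv0_pop baseline minute ventilation, L/min.
#' @param paco2_0_pop baseline PaCO2, mmHg.
#' @param half_life acetazolamide elimination half-life, day (fixed 0.25).
#' @param fur_half_life furosemide elimination half-life, day. Not
#'   reported for the reference model; the bolus model mirrors the only
#'   kinetic constant available (0.25 day) and can be overridden.
#' @param beta_saps exponent on SAPS II/50 applied to `bicar0_pop`.
#' @param beta_chloride exponent on chloride/100 applied to `bicar0_pop`.
#' @param cortico_mult multiplier on `bicar0_pop` when corticosteroids
#'   are co-administered.
#' @param va_mult multiplier on `mv0_pop` under volume-assist ventilation.
#' @param female_mult multiplier on `mv0_pop` for female subjects.
#' @param pow_bicar_mv power of the bicarbonate effect (37.5/Bicar)^pow
#'   on minute ventilation.
#' @param bicar_ref reference bicarbonate of the MV link, mmol/L
#'   (structural constant, 37.5).
#' @param pow_mv_paco2 power of the minute-ventilation effect
#'   (MV0/MV)^pow on PaCO2.
#'
#' @return An object of class `acz_fixed` (named list).
#' @examples
#' fx <- fixed_effects()
#' fx$kout
#' @export
fixed_effects <- function(bicar0_pop = 35.4,
                          kout = 0.314,
                          a50 = 163,
                          emax = 1,
                          fur50 = 204,
                          mv0_pop = 11.1,
                          paco2_0_pop = 54.4,
                          half_life = 0.25,
                          fur_half_life = 0.25,
                          beta_saps = -0.11,
                          beta_chloride = -1.17,
                          cortico_mult = 1.10,
                          va_mult = 0.92,
                          female_mult = 0.82,
                          pow_bicar_mv = 0.67,
                          bicar_ref = 37.5,
                          pow_mv_paco2 = 0.71) {
  fx <- list(bicar0_pop = bicar0_pop, kout = kout, a50 = a50, emax = emax,
             fur50 = fur50, mv0_pop = mv0_pop, paco2_0_pop = paco2_0_pop,
             half_life = half_life, fur_half_life = fur_half_life,
             beta_saps = beta_saps, beta_chloride = beta_chloride,
             cortico_mult = cortico_mult, va_mult = va_mult,
             female_mult = female_mult, pow_bicar_mv = pow_bicar_mv,
             bicar_ref = bicar_ref, pow_mv_paco2 = pow_mv_paco2)
  for (nm in c("bicar0_pop", "kout", "a50", "fur50", "mv0_pop",
               "paco2_0_pop", "half_life", "fur_half_life", "cortico_mult",
               "va_mult", "female_mult", "bicar_ref")) {
    v <- fx[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop("fixed_effects: '", nm, "' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(emax) || length(emax) != 1L || emax <= 0 || emax > 1)
    stop("fixed_effects: 'emax' must lie in (0, 1]", call. = FALSE)
  for (nm in c("beta_saps", "beta_chloride", "pow_bicar_mv", "pow_mv_paco2"))
    if (!is.numeric(fx[[nm]]) || length(fx[[nm]]) != 1L || !is.finite(fx[[nm]]))
      stop("fixed_effects: '", nm, "' must be a single finite number", call. = FALSE)
  structure(fx, class = "acz_fixed")
}

#' Between-subject variability (BSV) specification
#'
#' Standard deviations of the exponential (log-normal) random effects:
#' individual parameters are \eqn{\theta_i = \theta \exp(\eta_i)} with
#' \eqn{\eta_i \sim N(0, \omega^2)}, independent across parameters.
#' Defaults are the reference-model estimates. Random effects are carried
#' by the baselines (bicarbonate, MV, PaCO2), the turnover rate, and the
#' MV-to-PaCO2 power; `a50`, `fur50`, `emax` and the half-life have none.
#'
#' @param omega_bicar0,omega_kout,omega_mv0,omega_paco2_0,omega_pow_mv_paco2
#'   non-negative standard deviations of the log-scale random effects.
#' @return An object of class `acz_ranef`.
#' @export
random_effects <- function(omega_bicar0 = 0.10,
                           omega_kout = 0.995,
                           omega_mv0 = 0.225,
                           omega_paco2_0 = 0.102,
                           omega_pow_mv_paco2 = 0.56) {
  re <- c(bicar0 = omega_bicar0, kout = omega_kout, mv0 = omega_mv0,
          paco2_0 = omega_paco2_0, pow_mv_paco2 = omega_pow_mv_paco2)
  if (any(!is.finite(re)) || any(re < 0))
    stop("random_effects: all omegas must be finite and >= 0", call. = FALSE)
  structure(as.list(re), class = "acz_ranef")
}

#' Proportional residual-error specification
#'
#' Observations follow \eqn{y = f (1 + \epsilon)},
#' \eqn{\epsilon \sim N(0, \sigma^2)}, one \eqn{\sigma} per observation
#' type (constant coefficient of variation). Defaults are the
#' reference-model estimates.
#'
#' @param sigma_bicar,sigma_mv,sigma_paco2 positive proportional SDs for
#'   serum bicarbonate, minute ventilation and PaCO2 observations.
#' @return An object of class `acz_resid`.
#' @export
residual_error <- function(sigma_bicar = 0.044,
                           sigma_mv = 0.16,
                           sigma_paco2 = 0.12) {
  rs <- c(BICAR = sigma_bicar, MV = sigma_mv, PACO2 = sigma_paco2)
  if (any(!is.finite(rs)) || any(rs <= 0))
    stop("residual_error: all sigmas must be finite and > 0", call. = FALSE)
  structure(as.list(rs), class = "acz_resid")
}

#' Bundle of population model parameters
#'
#' Convenience container holding fixed effects, BSV and residual error
#' together; this is what the cohort generator, the regimen simulator and
#' the diagnostics consume. With no arguments it is the published
#' reference model.
#'
#' @param fixed an [fixed_effects()] object.
#' @param random a [random_effects()] object.
#' @param residual a [residual_error()] object.
#' @return An object of class `acz_params`.
#' @export
model_parameters <- function(fixed = fixed_effects(),
                             random = random_effects(),
                             residual = residual_error()) {
  stopifnot(inherits(fixed, "acz_fixed"), inherits(random, "acz_ranef"),
            inherits(residual, "acz_resid"))
  structure(list(fixed = fixed, random = random, residual = residual),
            class = "acz_params")
}

#' Subject covariates
#'
#' The covariates retained in the final model. SAPS II, serum chloride
#' and corticosteroid use act on baseline bicarbonate; sex and ventilator
#' mode act on baseline minute ventilation.
#'
#' @param saps2 SAPS II severity score (> 0, dimensionless).
#' @param chloride serum chloride, mmol/L (> 0).
#' @param corticosteroid logical, corticosteroid co-administration.
#' @param female logical, female sex.
#' @param volume_assist logical, `TRUE` = volume-assist ventilation,
#'   `FALSE` = pressure-support ventilation.
#' @return An object of class `acz_covariates`.
#' @export
covariate_set <- function(saps2 = 50, chloride = 100,
                          corticosteroid = FALSE, female = FALSE,
                          volume_assist = FALSE) {
  if (!is.numeric(saps2) || length(saps2) != 1L || !is.finite(saps2) || saps2 <= 0)
    stop("covariate_set: 'saps2' must be a single positive number", call. = FALSE)
  if (!is.numeric(chloride) || length(chloride) != 1L || !is.finite(chloride) || chloride <= 0)
    stop("covariate_set: 'chloride' must be a single positive number", call. = FALSE)
  structure(list(saps2 = saps2, chloride = chloride,
                 corticosteroid = isTRUE(corticosteroid),
                 female = isTRUE(female),
                 volume_assist = isTRUE(volume_assist)),
            class = "acz_covariates")
}

#' Dose events
#'
#' Builds a validated table of instantaneous IV bolus dose events for one
#' drug. Doses delivered "over a couple of minutes" are modelled as
#' boluses; unsorted times are sorted internally (documented convention).
#'
#' @param time dose times, day (>= 0).
#' @param amount dose amounts, mg (>= 0).
#' @param drug `"acetazolamide"` (`"acz"`) or `"furosemide"` (`"fur"`).
#' @return A `data.frame` with columns `time`, `amount`, `drug` sorted by
#'   time, class `acz_doses`.
#' @export
dose_events <- function(time, amount, drug = "acetazolamide") {
  if (length(time) == 0L) {
    out <- data.frame(time = numeric(0), amount = numeric(0),
                      drug = character(0), stringsAsFactors = FALSE)
    class(out) <- c("acz_doses", "data.frame")
    return(out)
  }
  drug <- match.arg(tolower(drug),
                    c("acetazolamide", "furosemide", "acz", "fur"))
  drug <- switch(drug, acetazolamide = , acz = "acz", furosemide = , fur = "fur")
  if (any(!is.finite(time)) || any(time < 0))
    stop("dose_events: times must be finite and >= 0", call. = FALSE)
  amount <- rep_len(amount, length(time))
  if (any(!is.finite(amount)) || any(amount < 0))
    stop("dose_events: amounts must be finite and >= 0", call. = FALSE)
  o <- order(time)
  out <- data.frame(time = time[o], amount = amount[o], drug = drug,
                    stringsAsFactors = FALSE)
  class(out) <- c("acz_doses", "data.frame")
  out
}

#' Single-subject record
#'
#' @param id subject identifier (scalar).
#' @param covariates a [covariate_set()].
#' @param ace_doses,fur_doses [dose_events()] tables (possibly empty).
#' @param observations `data.frame` with columns `time` (day, >= 0),
#'   `dvid` (one of `"BICAR"`, `"MV"`, `"PACO2"`) and `value` (> 0).
#' @return An object of class `acz_subject`.
#' @export
subject_record <- function(id, covariates,
                           ace_doses = dose_events(numeric(0)),
                           fur_doses = dose_events(numeric(0), drug = "fur"),
                           observations = data.frame(time = numeric(0),
                                                     dvid = character(0),
                                                     value = numeric(0))) {
  stopifnot(length(id) == 1L, inherits(covariates, "acz_covariates"))
  obs <- as.data.frame(observations)
  if (nrow(obs)) {
    if (!all(c("time", "dvid", "value") %in% names(obs)))
      stop("subject_record: observations need columns time, dvid, value", call. = FALSE)
    if (any(!obs$dvid %in% c("BICAR", "MV", "PACO2")))
      stop("subject_record: dvid must be BICAR, MV or PACO2", call. = FALSE)
    if (any(!is.finite(obs$time)) || any(obs$time < 0))
      stop("subject_record: observation times must be >= 0", call. = FALSE)
    if (any(!is.finite(obs$value)) || any(obs$value <= 0))
      stop("subject_record: observation values must be > 0", call. = FALSE)
    obs <- obs[order(obs$time, obs$dvid), , drop = FALSE]
    rownames(obs) <- NULL
  }
  structure(list(id = id, covariates = covariates,
                 ace_doses = ace_doses, fur_doses = fur_doses,
                 observations = obs),
            class = "acz_subject")
}

#' @export
print.acz_fixed <- function(x, ...) {
  cat("Fixed effects (turnover model):\n")
  print(unlist(x))
  invisible(x)
}

#' @export
print.acz_params <- function(x, ...) {
  cat("Population model parameters\n")
  cat("  fixed:   ", paste0(names(x$fixed), "=", signif(unlist(x$fixed), 4),
                            collapse = ", "), "\n")
  cat("  omega:   ", paste0(names(x$random), "=", signif(unlist(x$random), 4),
                            collapse = ", "), "\n")
  cat("  sigma:   ", paste0(names(x$residual), "=", signif(unlist(x$residual), 4),
                            collapse = ", "), "\n")
  invisible(x)
}
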