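# Monte-Carlo dose-regimen simulation: distribution of the change in
# minute ventilation and PaCO2 under candidate acetazolamide regimens in
# a virtual population, and responder proportions at the clinically
# relevant thresholds (MV increase > 0.75 L/min, PaCO2 drop > 5 mmHg).

#' Dose-regimen specification
#'
#' @param daily_dose total acetazolamide per day, mg (>= 0).
#' @param doses_per_day number of equal administrations per day.
#' @param duration treatment duration, day.
#' @param horizon evaluation time of the change from baseline, day
#'   (<= duration). The default of 1 day mirrors the 24-h pre/post
#'   contrasts of the observed data; the original report does not state
#'   the evaluation time of its simulations.
#' @return An object of class `acz_regimen`.
#' @export
regimen_spec <- function(daily_dose, doses_per_day = 1, duration = 4,
                         horizon = 1) {
  if (!is.numeric(daily_dose) || length(daily_dose) != 1L || daily_dose < 0)
    stop("regimen_spec: 'daily_dose' must be a single number >= 0", call. = FALSE)
  if (doses_per_day < 1 || duration <= 0)
    stop("regimen_spec: invalid dosing schedule", call. = FALSE)
  if (horizon > duration || horizon <= 0)
    stop("regimen_spec: 'horizon' must lie in (0, duration]", call. = FALSE)
  tau <- 1 / doses_per_day
  times <- seq(0, duration - tau, by = tau)
  structure(list(daily_dose = daily_dose, doses_per_day = doses_per_day,
                 duration = duration, horizon = horizon,
                 dose_times = times, dose_amount = daily_dose / doses_per_day),
            class = "acz_regimen")
}

#' Simulate a dose regimen in a virtual population
#'
#' For each virtual subject: draws covariates from the design
#' distributions (ventilator mode forced when a stratum is requested),
#' draws random effects, integrates the turnover model under the
#' regimen, and evaluates the change from the subject's own pre-dose
#' model value at the horizon:
#' \eqn{\Delta MV = MV(h) - MV(0)}, \eqn{\Delta PaCO_2 = PaCO_2(h) - PaCO_2(0)}.
#' Residual (assay) error is excluded from the deltas by default.
#'
#' @param params [model_parameters()] used as simulation truth.
#' @param regimen a [regimen_spec()].
#' @param n_subjects virtual subjects per call.
#' @param mode `"psv"` or `"va"` to force the ventilator mode (the
#'   published responder proportions are stratified), or `"cohort"` to
#'   draw it from the design.
#' @param design [design_config()] supplying the covariate
#'   distributions.
#' @param seed RNG seed.
#' @param include_residual also perturb the baseline and horizon values
#'   with proportional residual error before differencing.
#' @return `data.frame` (class `acz_sim`) with one row per subject:
#'   `mode`, `dmv` (L/min), `dpaco2` (mmHg; negative = decrease), and
#'   the baseline values `mv0`, `paco2_0`.
#' @export
simulate_regimen <- function(params, regimen, n_subjects = 10000,
                             mode = c("psv", "va", "cohort"),
                             design = design_config(), seed = 1,
                             include_residual = FALSE) {
  stopifnot(inherits(params, "acz_params"), inherits(regimen, "acz_regimen"))
  mode <- match.arg(mode)
  fx <- params$fixed; om <- unlist(params$random); sig <- unlist(params$residual)
  set.seed(seed)
  n <- as.integer(n_subjects)
  saps <- stats::rlnorm(n, design$saps_meanlog, design$saps_sdlog)
  chl <- stats::rnorm(n, design$chloride_mean, design$chloride_sd)
  while (any(chl <= 0))
    chl[chl <= 0] <- stats::rnorm(sum(chl <= 0), design$chloride_mean,
                                  design$chloride_sd)
  cort <- stats::runif(n) < design$p_cortico
  fem <- stats::runif(n) < design$p_female
  va <- switch(mode, psv = rep(FALSE, n), va = rep(TRUE, n),
               cohort = stats::runif(n) < design$p_va)
  eta <- matrix(stats::rnorm(5L * n, 0, om), n, 5L, byrow = TRUE)
  b0 <- fx$bicar0_pop * (saps / 50)^fx$beta_saps * (chl / 100)^fx$beta_chloride *
    ifelse(cort, fx$cortico_mult, 1) * exp(eta[, 1L])
  kout <- fx$kout * exp(eta[, 2L])
  mv0_i <- fx$mv0_pop * exp(eta[, 3L]) * ifelse(va, fx$va_mult, 1) *
    ifelse(fem, fx$female_mult, 1)
  pa0_i <- fx$paco2_0_pop * exp(eta[, 4L])
  pw_i <- fx$pow_mv_paco2 * exp(eta[, 5L])

  tt <- sort(unique(c(0, regimen$horizon)))
  if (regimen$daily_dose > 0) {
    pre <- .traj_precompute(regimen$dose_times,
                            rep(regimen$dose_amount, length(regimen$dose_times)),
                            numeric(0), numeric(0), tt,
                            fx$half_life, fx$fur_half_life)
    Bh <- vapply(seq_len(n), function(i) {
      .traj_solve(pre, b0[i], kout[i], fx$a50, fx$fur50, fx$emax)[length(tt)]
    }, numeric(1))
  } else {
    Bh <- b0
  }
  mv_base <- mv0_i * (fx$bicar_ref / b0)^fx$pow_bicar_mv
  mv_h <- mv0_i * (fx$bicar_ref / Bh)^fx$pow_bicar_mv
  pa_base <- pa0_i
  pa_h <- pa0_i * (mv_base / mv_h)^pw_i
  if (include_residual) {
    mv_base <- mv_base * (1 + stats::rnorm(n, 0, sig["MV"]))
    mv_h <- mv_h * (1 + stats::rnorm(n, 0, sig["MV"]))
    pa_base <- pa_base * (1 + stats::rnorm(n, 0, sig["PACO2"]))
    pa_h <- pa_h * (1 + stats::rnorm(n, 0, sig["PACO2"]))
  }
  out <- data.frame(id = seq_len(n), mode = ifelse(va, "va", "psv"),
                    dmv = mv_h - mv_base, dpaco2 = pa_h - pa_base,
                    mv0 = mv_base, paco2_0 = pa_base,
                    stringsAsFactors = FALSE)
  attr(out, "regimen") <- regimen
  class(out) <- c("acz_sim", "data.frame")
  out
}

#' Responder proportions at clinical thresholds
#'
#' Fraction of simulated subjects whose minute ventilation increases by
#' more than the MV threshold and whose PaCO2 decreases by more than
#' the PaCO2 threshold (strict inequalities), stratified by ventilator
#' mode.
#'
#' @param sim an `acz_sim` from [simulate_regimen()] (or any data frame
#'   with `mode`, `dmv`, `dpaco2`).
#' @param thresholds named vector `c(mv = , paco2 = )`: MV increase in
#'   L/min and PaCO2 decrease in mmHg.
#' @return `data.frame` with one row per stratum (plus `"all"`):
#'   `p_mv_responder`, `p_paco2_responder`, `n`.
#' @export
responder_proportions <- function(sim, thresholds = c(mv = 0.75, paco2 = 5)) {
  if (nrow(sim) == 0L)
    stop("responder_proportions: empty simulation", call. = FALSE)
  strata <- c(sort(unique(sim$mode)), "all")
  out <- do.call(rbind, lapply(strata, function(st) {
    d <- if (st == "all") sim else sim[sim$mode == st, , drop = FALSE]
    data.frame(mode = st,
               p_mv_responder = mean(d$dmv > thresholds[["mv"]]),
               p_paco2_responder = mean(-d$dpaco2 > thresholds[["paco2"]]),
               n = nrow(d))
  }))
  rownames(out) <- NULL
  out
}

#' Regimen-by-mode simulation summary
#'
#' Runs [simulate_regimen()] over a grid of daily doses and ventilator
#' modes and summarizes the distribution of the changes and the
#' responder proportions.
#'
#' @param params [model_parameters()].
#' @param daily_doses vector of total daily doses, mg.
#' @param modes ventilator-mode strata to force.
#' @param doses_per_day,duration,horizon passed to [regimen_spec()].
#' @param n_subjects virtual subjects per cell.
#' @param design [design_config()].
#' @param seed base seed; each cell uses a deterministic offset.
#' @param thresholds passed to [responder_proportions()].
#' @return `data.frame` with one row per dose-mode cell: median and
#'   quartiles of `dmv` and `dpaco2` plus responder proportions.
#' @export
simulate_regimen_grid <- function(params, daily_doses = c(250, 500, 1000, 2000),
                                  modes = c("psv", "va"), doses_per_day = 1,
                                  duration = 4, horizon = 1,
                                  n_subjects = 10000,
                                  design = design_config(), seed = 1,
                                  thresholds = c(mv = 0.75, paco2 = 5)) {
  cells <- expand.grid(dose = daily_doses, mode = modes,
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(j) {
    rg <- regimen_spec(cells$dose[j], doses_per_day, duration, horizon)
    sim <- simulate_regimen(params, rg, n_subjects, mode = cells$mode[j],
                            design = design, seed = seed + 1000L * j)
    q_mv <- stats::quantile(sim$dmv, c(0.25, 0.5, 0.75), names = FALSE)
    q_pa <- stats::quantile(sim$dpaco2, c(0.25, 0.5, 0.75), names = FALSE)
    rp <- responder_proportions(sim, thresholds)
    rp <- rp[rp$mode == cells$mode[j], ]
    data.frame(daily_dose = cells$dose[j], mode = cells$mode[j],
               dmv_q1 = q_mv[1], dmv_median = q_mv[2], dmv_q3 = q_mv[3],
               dpaco2_q1 = q_pa[1], dpaco2_median = q_pa[2],
               dpaco2_q3 = q_pa[3],
               p_mv_responder = rp$p_mv_responder,
               p_paco2_responder = rp$p_paco2_responder,
               n = n_subjects)
  }))
  rownames(out) <- NULL
  out
}
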