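# Covariate relationships, individual-parameter realization, the
# Bicar -> MV -> PaCO2 algebraic chain, and the observation model.

#' Covariate-adjusted baseline bicarbonate
#'
#' Applies the retained covariate relationships multiplicatively to the
#' population baseline:
#' \deqn{Bicar_0 \times (SAPS II/50)^{\beta_{SAPS}} \times
#'       (Cl/100)^{\beta_{Cl}} \times cortico_{mult}^{[cortico]}}
#'
#' @param cov a [covariate_set()].
#' @param fx [fixed_effects()].
#' @param bicar0_pop population baseline; defaults to `fx$bicar0_pop`.
#' @return Covariate-adjusted baseline bicarbonate, mmol/L.
#' @examples
#' covariate_bicar0(covariate_set(saps2 = 50, chloride = 100), fixed_effects())
#' @export
covariate_bicar0 <- function(cov, fx, bicar0_pop = fx$bicar0_pop) {
  if (cov$saps2 <= 0 || cov$chloride <= 0)
    stop("covariate_bicar0: saps2 and chloride must be > 0", call. = FALSE)
  bicar0_pop * (cov$saps2 / 50)^fx$beta_saps *
    (cov$chloride / 100)^fx$beta_chloride *
    (if (cov$corticosteroid) fx$cortico_mult else 1)
}

#' Draw one individual's parameters
#'
#' Realizes a subject's parameters from the population model: covariate
#' adjustment of baseline bicarbonate, then independent log-normal
#' between-subject variability \eqn{\theta_i = \theta \exp(\eta_i)},
#' \eqn{\eta_i \sim N(0, \omega^2)}, on baseline bicarbonate, turnover
#' rate, baseline MV, baseline PaCO2 and the MV-to-PaCO2 power. The sex
#' and ventilator-mode multipliers on MV are not folded into `mv0_i`;
#' they are applied at prediction time by [mv_from_bicar()] (mirroring
#' how the covariates enter the MV link).
#'
#' @param fx [fixed_effects()].
#' @param re [random_effects()].
#' @param cov [covariate_set()].
#' @param seed optional integer; when given the draw is reproducible.
#' @return An object of class `acz_individual` with elements `bicar0_i`,
#'   `kout_i`, `mv0_i`, `paco2_0_i`, `pow_mv_paco2_i`, the drawn `eta`
#'   vector, and the shared structural constants.
#' @export
sample_individual <- function(fx, re, cov, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  om <- unlist(re)
  eta <- stats::rnorm(5L, 0, om)
  names(eta) <- names(om)
  ind <- list(
    bicar0_i = covariate_bicar0(cov, fx) * exp(eta[["bicar0"]]),
    kout_i = fx$kout * exp(eta[["kout"]]),
    mv0_i = fx$mv0_pop * exp(eta[["mv0"]]),
    paco2_0_i = fx$paco2_0_pop * exp(eta[["paco2_0"]]),
    pow_mv_paco2_i = fx$pow_mv_paco2 * exp(eta[["pow_mv_paco2"]]),
    eta = eta)
  structure(ind, class = "acz_individual")
}

#' Minute ventilation from bicarbonate
#'
#' \deqn{MV = MV_{0,i} \times va_{mult}^{[VA]} \times fem_{mult}^{[female]}
#'       \times (37.5/Bicar)^{0.67}}
#' Strictly decreasing in bicarbonate: washing out the metabolic
#' alkalosis restores ventilatory drive.
#'
#' @param ind individual parameters ([sample_individual()]).
#' @param fx [fixed_effects()].
#' @param cov [covariate_set()] supplying sex and ventilator mode.
#' @param bicar bicarbonate value(s), mmol/L (> 0); vectorized.
#' @return Minute ventilation, L/min.
#' @export
mv_from_bicar <- function(ind, fx, cov, bicar) {
  if (any(!is.finite(bicar)) || any(bicar <= 0))
    stop("mv_from_bicar: 'bicar' must be > 0", call. = FALSE)
  ind$mv0_i *
    (if (cov$volume_assist) fx$va_mult else 1) *
    (if (cov$female) fx$female_mult else 1) *
    (fx$bicar_ref / bicar)^fx$pow_bicar_mv
}

#' PaCO2 from minute ventilation
#'
#' \deqn{PaCO_2 = PaCO2_{0,i} \times (MV_{0,i}/MV)^{0.71_i}}
#' where the baseline `mv_baseline` is the subject's own model MV at
#' t = 0 (including the sex/mode multipliers and the baseline
#' bicarbonate factor), so that \eqn{PaCO_2(0) = PaCO2_{0,i}} identically.
#' Strictly decreasing in MV.
#'
#' @param ind individual parameters.
#' @param mv minute ventilation, L/min (> 0); vectorized.
#' @param mv_baseline the subject's baseline model MV, L/min (> 0).
#' @return PaCO2, mmHg.
#' @export
paco2_from_mv <- function(ind, mv, mv_baseline) {
  if (any(!is.finite(mv)) || any(mv <= 0) || any(mv_baseline <= 0))
    stop("paco2_from_mv: 'mv' and 'mv_baseline' must be > 0", call. = FALSE)
  ind$paco2_0_i * (mv_baseline / mv)^ind$pow_mv_paco2_i
}

#' Deterministic trajectory of the full chain
#'
#' Evaluates drug amount, bicarbonate, minute ventilation and PaCO2 for
#' one individual on a time grid.
#'
#' @inheritParams bicar_trajectory
#' @param cov [covariate_set()].
#' @return `data.frame` with columns `time`, `drug_amount` (mg of
#'   acetazolamide in the body), `bicar`, `mv`, `paco2`.
#' @export
simulate_trajectory <- function(ind, fx, cov,
                                ace_doses = NULL, fur_doses = NULL, times,
                                method = c("analytic", "lsoda")) {
  B <- bicar_trajectory(ind, fx, ace_doses, fur_doses, times, method = method)
  A <- if (is.null(ace_doses)) rep(0, length(times)) else
    drug_amount(ace_doses, fx$half_life, times)
  mv <- mv_from_bicar(ind, fx, cov, B)
  mv0 <- mv_from_bicar(ind, fx, cov, ind$bicar0_i)
  pa <- paco2_from_mv(ind, mv, mv0)
  data.frame(time = times, drug_amount = A, bicar = B, mv = mv, paco2 = pa)
}

#' Model predictions at a subject's observation times
#'
#' Solves the bicarbonate trajectory at the subject's observation times
#' and maps each observation row to its model prediction according to
#' its type (`BICAR`, `MV`, `PACO2`).
#'
#' @param subject a [subject_record()].
#' @param ind individual parameters.
#' @param fx [fixed_effects()].
#' @return The subject's observation `data.frame` with an added `pred`
#'   column.
#' @export
predict_subject <- function(subject, ind, fx) {
  obs <- subject$observations
  if (nrow(obs) == 0L) {
    obs$pred <- numeric(0)
    return(obs)
  }
  ut <- sort(unique(obs$time))
  B <- bicar_trajectory(ind, fx, subject$ace_doses, subject$fur_doses, ut)
  Bobs <- B[match(obs$time, ut)]
  cov <- subject$covariates
  mv0 <- mv_from_bicar(ind, fx, cov, ind$bicar0_i)
  pred <- numeric(nrow(obs))
  is_b <- obs$dvid == "BICAR"; is_m <- obs$dvid == "MV"; is_p <- obs$dvid == "PACO2"
  pred[is_b] <- Bobs[is_b]
  if (any(is_m)) pred[is_m] <- mv_from_bicar(ind, fx, cov, Bobs[is_m])
  if (any(is_p)) pred[is_p] <- paco2_from_mv(
    ind, mv_from_bicar(ind, fx, cov, Bobs[is_p]), mv0)
  obs$pred <- pred
  obs
}

#' Proportional-error observation
#'
#' Applies the residual model \eqn{y = f (1 + \epsilon)},
#' \eqn{\epsilon \sim N(0, \sigma^2)}. Draws that would produce a
#' non-positive observation are resampled (observations are
#' physiological positives; at the reference sigmas the truncation
#' probability is negligible).
#'
#' @param pred positive model prediction(s); vectorized.
#' @param sigma proportional SD (>= 0).
#' @param seed optional integer seed for reproducibility.
#' @return Simulated observation(s), same length as `pred`.
#' @export
observe <- function(pred, sigma, seed = NULL) {
  if (any(!is.finite(pred)) || any(pred <= 0))
    stop("observe: 'pred' must be > 0", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("observe: 'sigma' must be a single number >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  y <- pred * (1 + stats::rnorm(length(pred), 0, sigma))
  bad <- which(y <= 0)
  guard <- 0L
  while (length(bad)) {
    y[bad] <- pred[bad] * (1 + stats::rnorm(length(bad), 0, sigma))
    bad <- bad[y[bad] <= 0]
    guard <- guard + 1L
    if (guard > 1000L) stop("observe: resampling failed to produce positive values")
  }
  y
}

#' Individual log-likelihood under the proportional error model
#'
#' Sum over the subject's observations of the Normal log-density of the
#' observed value given its model prediction, with SD
#' \eqn{\sigma_{dvid} \times f}.
#'
#' @param subject a [subject_record()].
#' @param ind individual parameters.
#' @param fx [fixed_effects()].
#' @param res [residual_error()].
#' @return Scalar log-likelihood (finite).
#' @export
individual_loglik <- function(subject, ind, fx, res) {
  pr <- predict_subject(subject, ind, fx)
  if (nrow(pr) == 0L) return(0)
  if (any(!is.finite(pr$pred)) || any(pr$pred <= 0))
    stop("individual_loglik: non-positive model prediction", call. = FALSE)
  sig <- unlist(res)[pr$dvid]
  ll <- sum(stats::dnorm(pr$value, mean = pr$pred, sd = sig * pr$pred, log = TRUE))
  if (!is.finite(ll))
    stop("individual_loglik: non-finite log-likelihood", call. = FALSE)
  ll
}
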