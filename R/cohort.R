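# Synthetic-cohort generator emulating the reference study design:
# 68 ventilated COPD subjects on IV acetazolamide 250-500 mg twice daily
# over a multi-day weaning window, with ~9 minute-ventilation and ~3
# paired blood-gas (bicarbonate + PaCO2) observations per subject.

#' Study-design configuration for the cohort generator
#'
#' Defaults emulate the reference cohort: 68 subjects, acetazolamide 250
#' or 500 mg (per-subject choice) every 0.5 day for 4 days; per-subject
#' observation counts drawn as `min + Binomial(size, prob)`, giving
#' minute-ventilation counts with median 9 (range 2-14, ~619 total) and
#' paired blood-gas counts with median 3 (range 1-6, ~207 of each).
#' Covariate distributions are not reported for the original cohort and
#' are explicit assumptions chosen to centre the published normalizers:
#' SAPS II log-normal (median 50, CV 30%), chloride Normal(100, 5)
#' truncated positive, corticosteroids Bernoulli(0.3), female
#' Bernoulli(0.3), volume-assist Bernoulli(0.5), furosemide
#' co-medication Bernoulli(0.3) at 40 mg once daily.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param dose_options acetazolamide per-dose amounts, mg; one option is
#'   drawn per subject. Use `0` for an untreated design.
#' @param dose_interval dosing interval, day (0.5 = twice daily).
#' @param duration treatment duration, day.
#' @param mv_count,gas_count lists `list(min, size, prob)` defining the
#'   per-subject observation-count distributions (`min + rbinom(size, prob)`).
#' @param saps_meanlog,saps_sdlog log-normal parameters of SAPS II.
#' @param chloride_mean,chloride_sd Normal parameters of serum chloride.
#' @param p_cortico,p_female,p_va,p_fur Bernoulli probabilities.
#' @param fur_dose,fur_interval furosemide dose (mg) and interval (day).
#' @return An object of class `acz_design`.
#' @export
design_config <- function(n_subjects = 68,
                          dose_options = c(250, 500),
                          dose_interval = 0.5,
                          duration = 4,
                          mv_count = list(min = 2, size = 12, prob = 0.59),
                          gas_count = list(min = 1, size = 5, prob = 0.41),
                          saps_meanlog = log(50),
                          saps_sdlog = sqrt(log(1 + 0.3^2)),
                          chloride_mean = 100, chloride_sd = 5,
                          p_cortico = 0.3, p_female = 0.3, p_va = 0.5,
                          p_fur = 0.3, fur_dose = 40, fur_interval = 1) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("design_config: 'n_subjects' must be >= 1", call. = FALSE)
  if (duration <= 0 || dose_interval <= 0)
    stop("design_config: 'duration' and 'dose_interval' must be > 0", call. = FALSE)
  for (cc in list(mv_count, gas_count))
    if (!all(c("min", "size", "prob") %in% names(cc)) || cc$min < 1)
      stop("design_config: count specs need min >= 1, size, prob", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 dose_options = dose_options, dose_interval = dose_interval,
                 duration = duration, mv_count = mv_count,
                 gas_count = gas_count, saps_meanlog = saps_meanlog,
                 saps_sdlog = saps_sdlog, chloride_mean = chloride_mean,
                 chloride_sd = chloride_sd, p_cortico = p_cortico,
                 p_female = p_female, p_va = p_va, p_fur = p_fur,
                 fur_dose = fur_dose, fur_interval = fur_interval),
            class = "acz_design")
}

#' Generate a synthetic cohort
#'
#' For each subject: draws covariates from the design distributions,
#' realizes individual parameters ([sample_individual()]), builds the
#' dose schedule, integrates the model trajectory, and emits
#' proportional-error observations at the sampled times. Fully
#' reproducible from the master seed; per-subject sub-seeds are derived
#' deterministically from it so a subject's data do not depend on how
#' many subjects precede it.
#'
#' @param params [model_parameters()] used as generating truth.
#' @param design a [design_config()].
#' @param seed master integer seed.
#' @return An object of class `acz_dataset`: a list with `subjects` (list
#'   of [subject_record()]), and the generating `design` echoed back.
#' @export
generate_cohort <- function(params, design = design_config(), seed = 1) {
  stopifnot(inherits(params, "acz_params"), inherits(design, "acz_design"))
  fx <- params$fixed; re <- params$random; res <- params$residual
  set.seed(seed)
  sub_seeds <- sample.int(2147483646L, design$n_subjects)
  subjects <- vector("list", design$n_subjects)
  for (i in seq_len(design$n_subjects)) {
    set.seed(sub_seeds[i])
    # covariates
    saps <- stats::rlnorm(1, design$saps_meanlog, design$saps_sdlog)
    repeat {
      chl <- stats::rnorm(1, design$chloride_mean, design$chloride_sd)
      if (chl > 0) break
    }
    cov <- covariate_set(saps2 = saps, chloride = chl,
                         corticosteroid = stats::runif(1) < design$p_cortico,
                         female = stats::runif(1) < design$p_female,
                         volume_assist = stats::runif(1) < design$p_va)
    # dose schedules
    amt <- if (length(design$dose_options) > 1L)
      sample(design$dose_options, 1L) else design$dose_options
    dose_times <- seq(0, design$duration - design$dose_interval,
                      by = design$dose_interval)
    ace <- if (amt > 0) dose_events(dose_times, amt, "acz") else
      dose_events(numeric(0))
    on_fur <- stats::runif(1) < design$p_fur
    fur <- if (on_fur && design$fur_dose > 0)
      dose_events(seq(0, design$duration - design$fur_interval,
                      by = design$fur_interval), design$fur_dose, "fur")
    else dose_events(numeric(0), drug = "fur")
    # observation schedule: MV uniform over the window, blood gases
    # (paired bicarbonate + PaCO2) ~1/day
    n_mv <- design$mv_count$min +
      stats::rbinom(1, design$mv_count$size, design$mv_count$prob)
    n_gas <- design$gas_count$min +
      stats::rbinom(1, design$gas_count$size, design$gas_count$prob)
    t_mv <- round(sort(stats::runif(n_mv, 0, design$duration)), 4)
    t_gas <- round(sort(stats::runif(n_gas, 0, design$duration)), 4)
    obs <- data.frame(
      time = c(t_mv, t_gas, t_gas),
      dvid = c(rep("MV", n_mv), rep("BICAR", n_gas), rep("PACO2", n_gas)),
      stringsAsFactors = FALSE)
    # individual parameters and noise-free predictions
    ind <- sample_individual(fx, re, cov)
    sub <- subject_record(i, cov, ace, fur,
                          cbind(obs, value = 1))  # placeholder values
    pr <- predict_subject(sub, ind, fx)
    sig <- unlist(res)[pr$dvid]
    vals <- if (all(sig == 0)) pr$pred else {
      y <- pr$pred
      nz <- sig > 0
      if (any(nz)) {
        y[nz] <- pr$pred[nz] * (1 + stats::rnorm(sum(nz), 0, sig[nz]))
        bad <- which(y <= 0)
        while (length(bad)) {
          y[bad] <- pr$pred[bad] * (1 + stats::rnorm(length(bad), 0, sig[bad]))
          bad <- bad[y[bad] <= 0]
        }
      }
      y
    }
    sub$observations$value <- vals
    subjects[[i]] <- sub
  }
  structure(list(subjects = subjects, design = design, seed = seed),
            class = "acz_dataset")
}

#' Summarize a dataset by observation type
#'
#' @param dataset an `acz_dataset`.
#' @return `data.frame` with one row per observation type: total count,
#'   mean and SD of values, and median/min/max of per-subject counts.
#' @export
summarize_cohort <- function(dataset) {
  stopifnot(inherits(dataset, "acz_dataset"))
  if (length(dataset$subjects) == 0L)
    stop("summarize_cohort: empty dataset", call. = FALSE)
  tab <- do.call(rbind, lapply(dataset$subjects, function(s) {
    if (nrow(s$observations) == 0L) return(NULL)
    cbind(id = s$id, s$observations)
  }))
  if (is.null(tab)) stop("summarize_cohort: dataset has no observations", call. = FALSE)
  out <- do.call(rbind, lapply(c("BICAR", "MV", "PACO2"), function(d) {
    sel <- tab[tab$dvid == d, , drop = FALSE]
    if (nrow(sel) == 0L)
      return(data.frame(dvid = d, n = 0L, mean = NA_real_, sd = NA_real_,
                        median_per_subject = NA_real_,
                        min_per_subject = NA_real_, max_per_subject = NA_real_))
    cnt <- table(factor(sel$id, levels = unique(tab$id)))
    cnt <- as.integer(cnt[cnt > 0])
    data.frame(dvid = d, n = nrow(sel), mean = mean(sel$value),
               sd = stats::sd(sel$value),
               median_per_subject = stats::median(cnt),
               min_per_subject = min(cnt), max_per_subject = max(cnt))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.acz_dataset <- function(x, ...) {
  nobs <- sum(vapply(x$subjects, function(s) nrow(s$observations), integer(1)))
  cat("Synthetic PD dataset:", length(x$subjects), "subjects,",
      nobs, "observations\n")
  invisible(x)
}
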