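# Model diagnostics: normalized prediction distribution errors (NPDE)
# with per-subject decorrelation, location/scale/normality tests,
# eta-shrinkage, and observed-vs-predicted tables.

#' Normalized prediction distribution errors
#'
#' Simulates `n_sim` full-model replicates of every subject's
#' observation vector (new random effects and residual errors on the
#' subject's own design), decorrelates the observed and simulated
#' vectors with the inverse Cholesky factor of the empirical simulated
#' covariance, computes each observation's prediction discrepancy
#' \eqn{pd = (rank + U(0,1))/(n_{sim}+1)} (jittered ranks break ties;
#' pd is clipped away from 0 and 1 so the probit stays finite), and
#' returns \eqn{npde = \Phi^{-1}(pd)}. Under a correct model the npde
#' are standard normal.
#'
#' @param dataset an `acz_dataset`.
#' @param fit an `acz_fit` or [model_parameters()] defining the
#'   simulation model.
#' @param n_sim Monte-Carlo replicates (>= 50; the reference analysis
#'   used 500).
#' @param seed RNG seed.
#' @return An object of class `acz_npde`: list with `table`
#'   (per-observation `id`, `time`, `dvid`, `observed`, `pd`, `npde`),
#'   `tests` (per-dvid and overall [npde_tests()] p-values), `n_sim`,
#'   `seed`.
#' @export
compute_npde <- function(dataset, fit, n_sim = 500, seed = 1) {
  stopifnot(inherits(dataset, "acz_dataset"))
  if (n_sim < 50) stop("compute_npde: 'n_sim' must be >= 50", call. = FALSE)
  params <- as_model_parameters(fit)
  fx <- params$fixed; re <- params$random; res <- params$residual
  sig <- unlist(res)  # BICAR, MV, PACO2
  om <- unlist(re)
  set.seed(seed)
  ridge_warned <- FALSE
  rows <- vector("list", length(dataset$subjects))
  for (si in seq_along(dataset$subjects)) {
    s <- dataset$subjects[[si]]
    obs <- s$observations
    if (nrow(obs) == 0L) next
    ut <- sort(unique(obs$time))
    pre <- .traj_precompute(s$ace_doses$time, s$ace_doses$amount,
                            s$fur_doses$time, s$fur_doses$amount,
                            ut, fx$half_life, fx$fur_half_life)
    idx <- match(obs$time, ut)
    dvid <- obs$dvid
    cov <- s$covariates
    mu_b0 <- covariate_bicar0(cov, fx)
    mv_mult <- (if (cov$volume_assist) fx$va_mult else 1) *
      (if (cov$female) fx$female_mult else 1)
    nobs <- nrow(obs)
    S <- matrix(NA_real_, n_sim, nobs)
    sig_obs <- sig[dvid]
    for (j in seq_len(n_sim)) {
      eta <- stats::rnorm(5L, 0, om)
      B0 <- mu_b0 * exp(eta[1L])
      B <- .traj_solve(pre, B0, fx$kout * exp(eta[2L]), fx$a50, fx$fur50,
                       fx$emax)
      f <- numeric(nobs)
      ib <- dvid == "BICAR"; im <- dvid == "MV"; ip <- dvid == "PACO2"
      f[ib] <- B[idx[ib]]
      if (any(im)) f[im] <- fx$mv0_pop * exp(eta[3L]) * mv_mult *
        (fx$bicar_ref / B[idx[im]])^fx$pow_bicar_mv
      if (any(ip)) f[ip] <- fx$paco2_0_pop * exp(eta[4L]) *
        (B[idx[ip]] / B0)^(fx$pow_bicar_mv * fx$pow_mv_paco2 * exp(eta[5L]))
      y <- f * (1 + stats::rnorm(nobs, 0, sig_obs))
      bad <- which(y <= 0)
      while (length(bad)) {
        y[bad] <- f[bad] * (1 + stats::rnorm(length(bad), 0, sig_obs[bad]))
        bad <- bad[y[bad] <= 0]
      }
      S[j, ] <- y
    }
    # the observed vector joins the empirical mean/covariance (weight
    # 1/(n_sim+1)): the decorrelating transformation is then symmetric
    # in all n_sim+1 vectors, so under a correct model the observation
    # is exactly exchangeable with the simulations and the ranks are
    # exactly uniform -- whitening by the simulations alone leaves the
    # observation out-of-sample and inflates the npde variance by
    # O(n_obs/n_sim)
    SY <- rbind(S, obs$value)
    Ebar <- colMeans(SY)
    V <- stats::cov(SY)
    L <- NULL
    ridge <- 0
    for (attempt in 1:6) {
      L <- tryCatch(chol(V + diag(ridge, nobs)), error = function(e) NULL)
      if (!is.null(L)) break
      ridge <- if (ridge == 0) 1e-8 * mean(diag(V)) else ridge * 100
    }
    if (is.null(L))
      stop("compute_npde: simulated covariance is singular for subject ",
           s$id, call. = FALSE)
    if (ridge > 0 && !ridge_warned) {
      warning("compute_npde: ridge-regularized a singular simulated covariance")
      ridge_warned <- TRUE
    }
    # decorrelate: forward-solve with the lower factor
    yd <- forwardsolve(t(L), obs$value - Ebar)
    Sd <- forwardsolve(t(L), t(S) - Ebar)   # nobs x n_sim
    rk <- rowSums(Sd < yd)                   # rank of obs among sims
    pd <- (rk + stats::runif(nobs)) / (n_sim + 1)
    lo <- 1 / (2 * (n_sim + 1))
    pd <- pmin(pmax(pd, lo), 1 - lo)
    rows[[si]] <- data.frame(id = s$id, time = obs$time, dvid = dvid,
                             observed = obs$value, pd = pd,
                             npde = stats::qnorm(pd))
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) < 10L)
    stop("compute_npde: need at least 10 observations", call. = FALSE)
  tests <- lapply(split(tab$npde, tab$dvid), function(x)
    if (length(x) >= 10L) npde_tests(x) else NULL)
  tests$all <- npde_tests(tab$npde)
  structure(list(table = tab, tests = tests, n_sim = n_sim, seed = seed),
            class = "acz_npde")
}

#' Location, scale and normality tests on npde values
#'
#' Under a correct model npde values are iid standard normal: the
#' Wilcoxon signed-rank test checks mean 0, a chi-square variance test
#' checks variance 1 (the scale counterpart of the classical F
#' variance-ratio test, two-sided), and Shapiro-Wilk (Kolmogorov-
#' Smirnov above n = 5000) checks normality.
#'
#' @param x numeric vector of npde values (>= 10, non-constant).
#' @return Named list `wilcoxon_p`, `fisher_var_p`, `normality_p`.
#' @export
npde_tests <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 10L) stop("npde_tests: need at least 10 values", call. = FALSE)
  if (stats::sd(x) == 0) stop("npde_tests: constant input", call. = FALSE)
  w <- suppressWarnings(stats::wilcox.test(x, mu = 0))$p.value
  stat <- (n - 1) * stats::var(x)
  pv <- stats::pchisq(stat, df = n - 1)
  fisher_var_p <- min(1, 2 * min(pv, 1 - pv))
  norm_p <- if (n <= 5000L) stats::shapiro.test(x)$p.value else
    suppressWarnings(stats::ks.test(x, "pnorm"))$p.value
  list(wilcoxon_p = w, fisher_var_p = fisher_var_p, normality_p = norm_p)
}

#' Eta-shrinkage
#'
#' \eqn{1 - sd(\eta)/\omega}: near 0 when the data inform the individual
#' estimates, near 1 when they shrink to the population value.
#'
#' @param etas numeric vector of individual (posterior-mean) etas for
#'   one parameter, length >= 2.
#' @param omega the population BSV estimate (> 0).
#' @return Shrinkage fraction.
#' @export
shrinkage <- function(etas, omega) {
  if (!is.numeric(omega) || length(omega) != 1L || !is.finite(omega) ||
      omega <= 0)
    stop("shrinkage: 'omega' must be a single number > 0", call. = FALSE)
  if (length(etas) < 2L)
    stop("shrinkage: need at least 2 subjects", call. = FALSE)
  1 - stats::sd(etas) / omega
}

#' Shrinkage for every random effect of a fit
#'
#' @param fit an `acz_fit`.
#' @return Named numeric vector of shrinkage fractions.
#' @export
shrinkage_table <- function(fit) {
  stopifnot(inherits(fit, "acz_fit"))
  om <- unlist(fit$random)
  vapply(seq_along(.acz_bsv_params), function(p)
    shrinkage(fit$eta_hat[, p], max(om[p], 1e-12)), numeric(1)) |>
    stats::setNames(.acz_bsv_params)
}

#' Observed versus predicted values
#'
#' Population predictions use the covariate-adjusted population
#' parameters (eta = 0); individual predictions use the posterior-mean
#' etas. The identity-line regression slope of observed on individual
#' predictions is reported per observation type.
#'
#' @param dataset an `acz_dataset`.
#' @param fit an `acz_fit` of that dataset.
#' @return List with `table` (`id`, `time`, `dvid`, `observed`,
#'   `pred_pop`, `pred_ind`) and `slopes` (per-dvid regression slope of
#'   observed on individual prediction).
#' @export
gof_tables <- function(dataset, fit) {
  stopifnot(inherits(dataset, "acz_dataset"), inherits(fit, "acz_fit"))
  subs <- .saem_compile(dataset, fit$fixed, fit$model)
  C <- fit$coefficients; struct <- fit$struct; consts <- fit$consts
  rows <- vector("list", length(subs))
  for (i in seq_along(subs)) {
    su <- subs[[i]]
    s <- dataset$subjects[[i]]
    obs <- s$observations
    mu_i <- vapply(.acz_bsv_params, function(p)
      sum(su$X[[p]] * C[[p]]), numeric(1))
    eta_i <- if (!is.null(fit$eta_hat)) fit$eta_hat[i, ] else rep(0, 5)
    pp <- .saem_pred(su, mu_i, struct, consts)
    pi_ <- .saem_pred(su, mu_i + eta_i, struct, consts)
    stack <- function(pred) {
      out <- numeric(nrow(obs))
      out[obs$dvid == "BICAR"] <- pred$fB
      out[obs$dvid == "MV"] <- pred$fM
      out[obs$dvid == "PACO2"] <- pred$fP
      out
    }
    rows[[i]] <- data.frame(id = s$id, time = obs$time, dvid = obs$dvid,
                            observed = obs$value, pred_pop = stack(pp),
                            pred_ind = stack(pi_))
  }
  tab <- do.call(rbind, rows)
  slopes <- vapply(split(tab, tab$dvid), function(d) {
    if (nrow(d) < 2L || stats::sd(d$pred_ind) == 0) return(NA_real_)
    unname(stats::coef(stats::lm(observed ~ pred_ind, data = d))[2L])
  }, numeric(1))
  list(table = tab, slopes = slopes)
}
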