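# Core numerics for the drug-amount / bicarbonate-turnover model.
#
# The turnover ODE
#   dB/dt = kin * sF(t) - kout * sA(t) * B,
#   sA(t) = 1 + emax * A(t)/(A(t) + a50),  sF(t) = 1 + F(t)/(F(t) + f50)
# is linear in B with piecewise-smooth forcing (A, F are exact bolus
# superpositions), so between dose times the integrating-factor solution
#   B(t) = e^{-H(t)} [ B(t0) + int_{t0}^t kin sF(u) e^{H(u)} du ]
# is exact, with H available in closed form:
#   H(t) = kout [ (t - t0) + (emax/ke) log((A0 + a50)/(A(t) + a50)) ].
# Only the forcing integral needs quadrature; 7-point Gauss-Legendre on
# substeps no longer than 0.125 day (0.25 day off drug) keeps the
# relative error near machine precision for physiological rate
# constants. Dose times are hard breakpoints. An adaptive-step
# deSolve::lsoda path is kept as an independent cross-check.

# 7-point Gauss-Legendre nodes/weights on [-1, 1]
.gl7 <- list(
  x = c(-0.9491079123427585, -0.7415311855993945, -0.4058451513773972, 0,
        0.4058451513773972, 0.7415311855993945, 0.9491079123427585),
  w = c(0.1294849661688697, 0.2797053914892767, 0.3818300505051189,
        0.4179591836734694, 0.3818300505051189, 0.2797053914892767,
        0.1294849661688697))

#' Drug amount in the body under IV bolus superposition
#'
#' One-compartment open model with linear elimination: the body amount at
#' time `t` is the superposition of the remaining fractions of all doses
#' given at or before `t`,
#' \eqn{A(t) = \sum_{t_i \le t} D_i 2^{-(t - t_i)/t_{1/2}}}.
#' The amount is right-continuous at dose times: a dose is included at
#' its own time (an observation at a dose time is post-dose).
#'
#' @param doses a [dose_events()] table (or any `data.frame` with `time`
#'   and `amount`); unsorted times are sorted internally.
#' @param half_life elimination half-life, day (> 0; `Inf` means no
#'   elimination, used for clamped-amount experiments).
#' @param t time(s) at which to evaluate, day (>= 0); vectorized.
#' @return Numeric vector of body amounts, mg.
#' @examples
#' d <- dose_events(time = 0, amount = 500)
#' drug_amount(d, half_life = 0.25, t = 0.25)  # one half-life: 250 mg
#' @export
drug_amount <- function(doses, half_life, t) {
  if (!is.numeric(half_life) || length(half_life) != 1L || is.na(half_life) ||
      half_life <= 0)
    stop("drug_amount: 'half_life' must be a single positive number", call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0))
    stop("drug_amount: times must be finite and >= 0", call. = FALSE)
  if (is.null(doses) || nrow(doses) == 0L) return(rep(0, length(t)))
  o <- order(doses$time)
  dt <- doses$time[o]; da <- doses$amount[o]
  ke <- log(2) / half_life
  vapply(t, function(tt) {
    keep <- dt <= tt
    if (!any(keep)) return(0)
    sum(da[keep] * exp(-ke * (tt - dt[keep])))
  }, numeric(1))
}

#' Bicarbonate formation rate from the equilibrium condition
#'
#' At baseline the turnover equation is at equilibrium, so the zero-order
#' formation rate is \eqn{k_{in} = k_{out} \times Bicar_0}.
#'
#' @param bicar0_i baseline bicarbonate, mmol/L (> 0 or 0 allowed only
#'   through `kout_i = 0`).
#' @param kout_i first-order elimination rate, /day (>= 0).
#' @return `kin` in mmol/L/day.
#' @export
derive_kin <- function(bicar0_i, kout_i) {
  if (!is.numeric(bicar0_i) || !is.numeric(kout_i) ||
      any(bicar0_i < 0) || any(kout_i < 0))
    stop("derive_kin: arguments must be non-negative numbers", call. = FALSE)
  kout_i * bicar0_i
}

# Precompute the substep structure for one dose schedule + output grid.
# All quantities that do not depend on (B0, kout, a50, f50) are frozen
# here so that repeated solves (MCMC, Monte Carlo) are pure arithmetic.
# times must be sorted, unique, >= 0.
.traj_precompute <- function(ace_times, ace_amts, fur_times, fur_amts,
                             times, half_life, fur_half_life,
                             max_step_drug = 0.125, max_step = 0.25) {
  stopifnot(!is.unsorted(times), all(times >= 0))
  tmax <- max(times, 0)
  keep_a <- ace_times <= tmax & ace_amts > 0
  keep_f <- fur_times <= tmax & fur_amts > 0
  ace_times <- ace_times[keep_a]; ace_amts <- ace_amts[keep_a]
  fur_times <- fur_times[keep_f]; fur_amts <- fur_amts[keep_f]
  ke_a <- if (is.finite(half_life)) log(2) / half_life else 0
  ke_f <- if (is.finite(fur_half_life)) log(2) / fur_half_life else 0

  knots <- sort(unique(c(0, ace_times, fur_times, times)))
  nk <- length(knots)
  # running post-dose amounts at each knot
  A_knot <- numeric(nk); F_knot <- numeric(nk)
  A <- 0; Fam <- 0; tprev <- 0
  for (j in seq_len(nk)) {
    tk <- knots[j]
    A <- A * exp(-ke_a * (tk - tprev))
    Fam <- Fam * exp(-ke_f * (tk - tprev))
    A <- A + sum(ace_amts[ace_times == tk])
    Fam <- Fam + sum(fur_amts[fur_times == tk])
    A_knot[j] <- A; F_knot[j] <- Fam
    tprev <- tk
  }

  # substeps within each inter-knot interval
  t0 <- numeric(0); h <- numeric(0); A0 <- numeric(0); F0 <- numeric(0)
  end_knot <- integer(0)  # index of knot an accumulated substep ends on (0 = interior)
  for (j in seq_len(nk - 1L)) {
    a <- knots[j]; b <- knots[j + 1L]
    drug_here <- A_knot[j] > 1e-3 || F_knot[j] > 1e-3
    step <- if (drug_here) max_step_drug else max_step
    ns <- max(1L, ceiling((b - a) / step))
    hh <- (b - a) / ns
    ss <- a + (seq_len(ns) - 1L) * hh
    t0 <- c(t0, ss); h <- c(h, rep(hh, ns))
    A0 <- c(A0, A_knot[j] * exp(-ke_a * (ss - a)))
    F0 <- c(F0, F_knot[j] * exp(-ke_f * (ss - a)))
    end_knot <- c(end_knot, c(rep(0L, ns - 1L), j + 1L))
  }
  m <- length(t0)
  if (m) {
    U <- outer(h, (.gl7$x + 1) / 2)             # m x 7 node offsets
    An <- A0 * exp(-ke_a * U)                    # amounts at nodes
    Fn <- F0 * exp(-ke_f * U)
    Aend <- A0 * exp(-ke_a * h)
  } else {
    U <- An <- Fn <- matrix(0, 0, 7); Aend <- numeric(0)
  }
  # map output times -> substep index whose end equals that time
  end_time <- ifelse(end_knot > 0L, knots[pmax(end_knot, 1L)], t0 + h)
  out_sub <- vapply(times, function(tt) {
    if (tt == 0) return(0L)
    i <- which(end_knot > 0L & abs(end_time - tt) < 1e-12)
    if (length(i) != 1L) stop("internal: output time not on a substep boundary")
    i
  }, integer(1))

  list(times = times, m = m, h = h, U = U, A0 = A0, F0 = F0, An = An,
       Fn = Fn, Aend = Aend, ke_a = ke_a, ke_f = ke_f,
       has_fur = any(F0 > 0), has_acz = any(A0 > 0), out_sub = out_sub)
}

# Solve B(t) at pre$times given individual (B0, kout) and structural
# (a50, f50, emax). Pure arithmetic on the precomputed structure.
.traj_solve <- function(pre, B0, kout, a50, f50, emax) {
  if (pre$m == 0L) return(rep(B0, length(pre$times)))
  kin <- kout * B0
  # H at nodes and at substep ends
  if (pre$has_acz) {
    if (pre$ke_a > 0) {
      la0 <- log(pre$A0 + a50)
      Hu <- kout * (pre$U + (emax / pre$ke_a) * (la0 - log(pre$An + a50)))
      Hend <- kout * (pre$h + (emax / pre$ke_a) * (la0 - log(pre$Aend + a50)))
    } else {  # clamped amount (infinite half-life): constant stimulation
      s <- 1 + emax * pre$A0 / (pre$A0 + a50)
      Hu <- (kout * s) * pre$U
      Hend <- kout * s * pre$h
    }
  } else {
    Hu <- kout * pre$U
    Hend <- kout * pre$h
  }
  sF <- if (pre$has_fur) 1 + pre$Fn / (pre$Fn + f50) else 1
  q <- kin * (pre$h / 2) * as.vector((sF * exp(Hu)) %*% .gl7$w)
  a <- exp(-Hend)
  cumH <- cumsum(Hend)
  if (max(cumH) < 500) {
    P <- exp(-cumH)
    Bend <- P * (B0 + cumsum(q / c(1, P[-pre$m])))
  } else {  # very fast turnover: sequential recursion avoids overflow
    Bend <- numeric(pre$m)
    Bc <- B0
    for (j in seq_len(pre$m)) {
      Bc <- a[j] * (Bc + q[j])
      Bend[j] <- Bc
    }
  }
  ifelse(pre$out_sub == 0L, B0, Bend[pmax(pre$out_sub, 1L)])
}

#' Bicarbonate trajectory under acetazolamide and furosemide dosing
#'
#' Integrates the turnover equation
#' \eqn{dB/dt = k_{in}(1 + F/(F+F_{50})) - k_{out}(1 + E_{max}A/(A+A_{50}))B}
#' from the equilibrium start \eqn{B(0) = Bicar_{0,i}}, with \eqn{A(t)}
#' and \eqn{F(t)} the exact bolus-superposition body amounts. The default
#' `"analytic"` method uses the exact integrating-factor solution with
#' Gauss-Legendre quadrature of the forcing integral and dose times as
#' breakpoints; `"lsoda"` uses adaptive integration via
#' \pkg{deSolve} (rtol 1e-8, atol 1e-10) and exists as an independent
#' numerical cross-check.
#'
#' @param ind an individual parameter set from [sample_individual()], or
#'   any list with `bicar0_i` and `kout_i`.
#' @param fx [fixed_effects()] supplying `a50`, `fur50`, `emax` and the
#'   half-lives.
#' @param ace_doses,fur_doses [dose_events()] tables (may be `NULL`).
#' @param times output times, day, increasing from 0.
#' @param method `"analytic"` (default) or `"lsoda"`.
#' @param clamp optional named list `list(acz = , fur = )` of constant
#'   clamped body amounts (mg); when given, dosing tables are ignored and
#'   the amounts are held fixed over the whole horizon (used for
#'   steady-state experiments).
#' @return Numeric vector of bicarbonate, mmol/L, one value per `times`.
#' @export
bicar_trajectory <- function(ind, fx, ace_doses = NULL, fur_doses = NULL,
                             times, method = c("analytic", "lsoda"),
                             clamp = NULL) {
  method <- match.arg(method)
  if (any(!is.finite(times)) || any(times < 0) || is.unsorted(times))
    stop("bicar_trajectory: 'times' must be increasing and >= 0", call. = FALSE)
  B0 <- ind$bicar0_i; kout <- ind$kout_i
  if (!is.finite(B0) || B0 <= 0 || !is.finite(kout) || kout < 0)
    stop("bicar_trajectory: individual bicar0/kout must be positive", call. = FALSE)
  if (!is.null(clamp)) {
    acz_amt <- if (!is.null(clamp$acz)) clamp$acz else 0
    fur_amt <- if (!is.null(clamp$fur)) clamp$fur else 0
    ace <- list(time = 0, amount = acz_amt)
    fur <- list(time = 0, amount = fur_amt)
    hl_a <- Inf; hl_f <- Inf
  } else {
    ace <- if (is.null(ace_doses)) list(time = numeric(0), amount = numeric(0)) else ace_doses
    fur <- if (is.null(fur_doses)) list(time = numeric(0), amount = numeric(0)) else fur_doses
    hl_a <- fx$half_life; hl_f <- fx$fur_half_life
  }
  tt <- sort(unique(times))
  if (method == "analytic") {
    # off-drug substep short enough for the quadrature at this kout
    ms <- max(min(0.25, 1 / max(kout * (1 + fx$emax), 1e-9)), 0.01)
    pre <- .traj_precompute(ace$time, ace$amount, fur$time, fur$amount,
                            tt, hl_a, hl_f, max_step = ms)
    Bv <- .traj_solve(pre, B0, kout, fx$a50, fx$fur50, fx$emax)
  } else {
    Bv <- .traj_lsoda(B0, kout, fx, ace, fur, hl_a, hl_f, tt)
  }
  if (any(!is.finite(Bv)) || any(Bv <= 0))
    stop("bicar_trajectory: solver produced non-positive or non-finite values",
         call. = FALSE)
  Bv[match(times, tt)]
}

# deSolve cross-check path: piecewise adaptive integration between dose
# breakpoints with the analytic A(t), F(t) evaluated inside the RHS.
.traj_lsoda <- function(B0, kout, fx, ace, fur, hl_a, hl_f, times) {
  kin <- kout * B0
  ke_a <- if (is.finite(hl_a)) log(2) / hl_a else 0
  ke_f <- if (is.finite(hl_f)) log(2) / hl_f else 0
  amt_at <- function(t, dt, da, ke) {
    keep <- dt <= t + 1e-15
    if (!any(keep)) return(0)
    sum(da[keep] * exp(-ke * (t - dt[keep])))
  }
  rhs <- function(t, y, p) {
    A <- amt_at(t, ace$time, ace$amount, ke_a)
    Fam <- amt_at(t, fur$time, fur$amount, ke_f)
    list(kin * (1 + Fam / (Fam + fx$fur50)) -
           kout * (1 + fx$emax * A / (A + fx$a50)) * y)
  }
  knots <- sort(unique(c(0, ace$time, fur$time, times)))
  knots <- knots[knots <= max(times)]
  out <- numeric(length(times))
  if (any(times == 0)) out[times == 0] <- B0
  Bc <- B0
  for (j in seq_len(length(knots) - 1L)) {
    seg <- c(knots[j], knots[j + 1L])
    sol <- deSolve::ode(c(B = unname(Bc)), times = seg, func = rhs,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-8, atol = 1e-10)
    Bc <- unname(sol[nrow(sol), "B"])
    hit <- which(times == knots[j + 1L])
    if (length(hit)) out[hit] <- Bc
  }
  out
}

#' Closed-form bicarbonate steady state under clamped drug amounts
#'
#' With constant clamped amounts the turnover equation relaxes to
#' \eqn{B_{ss} = k_{in}(1 + s_F)/(k_{out}(1 + s_A))} where
#' \eqn{s_A = E_{max} A/(A + A_{50})} and \eqn{s_F = F/(F + F_{50})}.
#' Serves as the analytic oracle for the ODE solver.
#'
#' @inheritParams bicar_trajectory
#' @param acz,fur clamped constant body amounts, mg (>= 0).
#' @return Steady-state bicarbonate, mmol/L.
#' @export
bicar_steady_state <- function(ind, fx, acz = 0, fur = 0) {
  stimA <- fx$emax * acz / (acz + fx$a50)
  stimF <- fur / (fur + fx$fur50)
  kin <- derive_kin(ind$bicar0_i, ind$kout_i)
  kin * (1 + stimF) / (ind$kout_i * (1 + stimA))
}
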