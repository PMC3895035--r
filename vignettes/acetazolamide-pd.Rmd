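---
title: "Modelling the respiratory effect of acetazolamide in ventilated COPD patients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the respiratory effect of acetazolamide in ventilated COPD patients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aczpd)
```

## The clinical problem

COPD patients weaned from invasive mechanical ventilation frequently
carry a metabolic alkalosis: serum bicarbonate is elevated, blood pH is
pushed up, and the central respiratory drive is blunted. Acetazolamide,
a carbonic-anhydrase inhibitor that blocks renal bicarbonate
reabsorption, is the usual treatment, but at the conventional 250–500 mg
IV twice daily its respiratory effect is modest. The question this
package addresses quantitatively is: *how much* acetazolamide would be
needed to produce a clinically relevant increase in minute ventilation
(MV) and decrease in PaCO2, and in what fraction of patients?

## The model

The model is a chain of three linked components, evaluated per subject.

**Drug amount.** Acetazolamide is given as IV boluses ("over a couple
of minutes", so no infusion duration) and eliminated linearly with a
half-life fixed at 6 h (0.25 day). The body amount is the bolus
superposition
$$A(t) = \sum_{t_i \le t} D_i\, 2^{-(t - t_i)/t_{1/2}},$$
right-continuous at dose times (an observation at a dose time is
post-dose). The model is amount-driven: no plasma concentrations are
modelled, so the half-maximal amount $A_{50}$ is in mg of drug in the
body, commensurate with the 250–500 mg doses.

**Bicarbonate turnover.** Serum bicarbonate $B(t)$ (mmol/L) follows an
indirect-response (turnover) equation in which acetazolamide stimulates
elimination — it blocks reabsorption, so bicarbonate is lost faster —
and co-administered furosemide stimulates formation (loop diuretics
raise bicarbonate):
$$\frac{dB}{dt} = k_{in}\Big(1 + \frac{F(t)}{F(t) + F_{50}}\Big)
  - k_{out}\Big(1 + E_{max}\frac{A(t)}{A(t) + A_{50}}\Big) B,$$
with $k_{in} = k_{out} B_0$ from the equilibrium condition at $t = 0$.
$E_{max}$ and $A_{50}$ are not jointly identifiable from amount-driven
data, so $E_{max}$ is fixed at 1 (the elimination rate can at most
double). The furosemide amount uses the same one-compartment bolus
model; its half-life is not separately known and defaults to the same
0.25 day, overridable in `fixed_effects()`.

**The chain to ventilation and gas exchange.** Minute ventilation and
PaCO2 are tied to bicarbonate by power laws:
$$MV(t) = MV_0 \cdot m_{VA}^{[VA]} \cdot m_{F}^{[female]} \cdot
  \Big(\frac{37.5}{B(t)}\Big)^{0.67}, \qquad
  PaCO_2(t) = PaCO2_0 \Big(\frac{MV(0)}{MV(t)}\Big)^{0.71}.$$
The reference bicarbonate 37.5 mmol/L is a fixed structural constant.
$MV(0)$ in the PaCO2 link is the subject's own covariate-adjusted model
MV at baseline (including the sex/mode multipliers and the baseline
bicarbonate factor), which makes $PaCO_2(0) = PaCO2_0$ an exact
identity; the multipliers then cancel in the ratio, so PaCO2 responds
only to the *relative* change in MV. Note the ventilator-mode
multiplier (0.92 for volume assist) is placed on $MV_0$, following the
reported estimates table rather than the looser statement in the
methods text that the mode acts on the PaCO2 equilibrium.

**Hierarchy and error.** Between-subject variability is exponential
(log-normal), $\theta_i = \theta\,e^{\eta_i}$,
$\eta_i \sim N(0, \omega^2)$, independent across the five parameters
that carry it ($B_0$, $k_{out}$, $MV_0$, $PaCO2_0$, and the MV→PaCO2
power; the same log-normal convention is applied to the power, whose
reporting does not state the convention — an explicit choice here).
The variance–covariance structure is diagonal by default; the original
analysis mentions testing richer structures but reports none.
Covariates enter multiplicatively: $(SAPS II/50)^{-0.11}$,
$(Cl/100)^{-1.17}$ and ×1.10 for corticosteroids on $B_0$; ×0.92 for
volume-assist and ×0.82 for female sex on $MV_0$. Residual error is
proportional, $y = f(1 + \varepsilon)$, with one $\sigma$ per
observation type (4.4% bicarbonate, 16% MV, 12% PaCO2); simulated
observations that would be non-positive are redrawn (the probability is
negligible at these $\sigma$'s). Defaults throughout
(`fixed_effects()`, `random_effects()`, `residual_error()`) are the
published final-model estimates for the reference cohort of 68
ventilated COPD patients.

## Numerical solution of the turnover equation

The turnover ODE is *linear* in $B$ with piecewise-smooth forcing, so
between dose times the integrating-factor solution is exact:
$$B(t) = e^{-H(t)}\Big[B(t_0) + \int_{t_0}^{t} k_{in}\,s_F(u)\,e^{H(u)}du\Big],
\qquad
H(t) = k_{out}\Big[(t - t_0) + \frac{E_{max}}{k_e}
 \log\frac{A_0 + A_{50}}{A(t) + A_{50}}\Big],$$
where $H$ has the closed form above because
$d\log(A + A_{50})/dt = -k_e A/(A + A_{50})$. Only the forcing integral
needs quadrature; 7-point Gauss–Legendre on substeps of at most 0.125
day on drug (0.25 day off drug, shortened further for fast individual
$k_{out}$) keeps the error near machine precision. Dose times are hard
breakpoints and a clamped-amount mode (infinite half-life) supports
steady-state experiments against the closed form
$B_{ss} = k_{in}(1 + s_F) / (k_{out}(1 + s_A))$.

This solver agrees with adaptive `deSolve::lsoda` integration
(rtol 1e-8/atol 1e-10), which is retained as `method = "lsoda"` and as
the independent numerical oracle in the test suite, to ~1e-6 mmol/L on
dosed trajectories — and it is two orders of magnitude faster, which is
what makes the SAEM MCMC, the 500-replicate NPDE simulations and the
10,000-subject regimen Monte Carlo practical in plain R.

## Synthetic cohorts

There is no public dataset (the original data are retrospective,
single-centre chart data), so `generate_cohort()` emulates the study
design and makes every downstream stage testable: 68 subjects,
acetazolamide 250 or 500 mg (one per-subject amount) every 12 h over a
4-day window, furosemide 40 mg/day in 30% of subjects; per-subject
observation counts `2 + Binomial(12, 0.59)` for MV and
`1 + Binomial(5, 0.41)` for paired blood gases, matching the reported
per-patient medians (9 and 3) and totals (~619 MV and ~207 blood-gas
observations); MV observation times uniform over the window, blood
gases roughly daily. Covariate distributions are *not* reported for the
original cohort; the generator's choices — SAPS II log-normal with
median 50 and 30% CV, chloride Normal(100, 5) truncated positive,
corticosteroids/female/volume-assist/furosemide Bernoulli with
probabilities 0.3/0.3/0.5/0.3 — centre the published covariate
normalizers and are explicit assumptions, all overridable in
`design_config()`. Generation is reproducible from one master seed via
deterministic per-subject sub-seeds.

What passing tests on these cohorts do **not** show: robustness to the
features of real chart data the generator leaves out — dose
interruptions and titration, informative observation times (gases drawn
when the patient deteriorates), within-subject drift of ventilator
settings, model misspecification of the covariate distributions, and
dropout. Parameter-recovery results here are statements about the
estimator under a correctly specified model at the study's design and
sample size.

## SAEM estimation

`fit_saem()` is a stochastic-approximation EM with per-subject MCMC —
maximum likelihood without any linearization. Individual log-parameters
$\varphi_{ip} = x_{ip}'c_p + \eta_{ip}$ are linear in log space, so the
covariate model (power covariates become linear terms, multipliers
become indicator coefficients) has a closed-form weighted-regression
M-step, and $\omega^2$, $\sigma^2$ update in closed form from
stochastic-approximation sufficient statistics (step size 1 during
burn-in, then $k^{-0.7}$; defaults 300 + 200 iterations, 2 transitions
per subject per iteration).

Design choices that proved load-bearing, found on synthetic recovery
experiments:

* **MCMC kernels.** The per-subject sampler combines component-wise
  *independence* proposals from the prior $N(\mu_p, \omega_p)$ (the
  prior and proposal cancel in the Metropolis ratio) with two blocked
  random walks — (log $B_0$, log $k_{out}$), which requires re-solving
  the trajectory, and (log $MV_0$, log $PaCO2_0$, log power), which
  reuses the cached bicarbonate solution. Random-walk scales adapt to a
  35% acceptance target during burn-in only. The independence kernel is
  essential: with random walks alone, weakly informed components (a
  subject with 3 bicarbonate points carries little information on
  $k_{out}$, whose $\omega$ is ~1) stop exploring as $\omega$ shrinks
  and the fit spirals into variance collapse.
* **Annealing.** During burn-in, $\omega$ and $\sigma$ may shrink by at
  most 5% per iteration, for the same reason.
* **No-variability structural parameters** ($A_{50}$, optionally
  $F_{50}$, and the bicarbonate→MV power) are estimated with an
  artificial log-scale variability annealed from 0.30 to 0.05 across
  burn-in and on to a 0.005 floor during smoothing; their M-step update
  is the mean of the sampled per-subject values. The textbook
  alternative — maximizing the residual likelihood against the current
  conditional sample — systematically froze at self-consistent fixed
  points away from the maximum in our experiments.
* $E_{max}$, the half-lives, the 37.5 mmol/L reference and $F_{50}$
  (carried over from the prior bicarbonate analysis without a reported
  uncertainty) are fixed by default.

The marginal log-likelihood is estimated by per-subject importance
sampling with a 5-df t proposal centred at the conditional posterior
mean with 1.3× posterior-sd scale (validated against 1-D quadrature in
the tests); AIC is $-2\ell + 2k$ over the free parameters, and
`compare_models()` / `select_covariates()` implement the LRT and
forward AIC selection. Percent relative standard errors come from
`estimate_rse()`: by Fisher's identity the marginal score of a subject
is the conditional expectation of its complete-data score, averaged
over the stored conditional draws; the information is the cross-subject
outer product of these scores (the score/BHHH estimator at the
maximum), with analytic derivatives except a central finite difference
for the structural block. These SEs are approximate — MCMC noise in the
conditional means inflates them somewhat for variance components.

## Diagnostics

`compute_npde()` implements normalized prediction distribution errors
with the standard decorrelation step: 500 full-model Monte-Carlo
replicates of each subject's observation vector (new random effects and
residual noise on the subject's own design), decorrelation of observed
and simulated vectors by the inverse Cholesky factor of the empirical
covariance (ridge-regularized with a warning if singular). One
refinement over the textbook recipe: the observed vector is included in
the empirical mean and covariance (weight $1/(n_{sim}+1)$), which makes
the decorrelating transformation symmetric in all $n_{sim}+1$ vectors —
under a correct model the observation is then exactly exchangeable with
the simulations and the ranks exactly uniform, where whitening by the
simulations alone leaves the observation out-of-sample and inflates the
npde variance by $O(n_{obs}/n_{sim})$ (about 3% at these designs,
enough to bias the variance test). Then
jittered ranks $pd = (\mathrm{rank} + U(0,1))/(n_{sim}+1)$ clipped away
from 0 and 1, and $npde = \Phi^{-1}(pd)$ follow. Under a correct model these
are standard normal; `npde_tests()` checks location (Wilcoxon
signed-rank), scale (a two-sided chi-square variance test against 1 —
the scale counterpart of the classical variance-ratio test) and
normality (Shapiro–Wilk, Kolmogorov–Smirnov above n = 5000; the
original analysis does not name its normality test). Shrinkage is
$1 - sd(\eta)/\omega$ and `gof_tables()` produces observed versus
population/individual predictions with identity-line slopes.

## Dose-regimen simulation

`simulate_regimen()` draws a virtual population (covariates from the
cohort design, ventilator mode forced per stratum, full BSV),
integrates each subject under the candidate regimen, and evaluates
$\Delta MV$ and $\Delta PaCO_2$ against the subject's own pre-dose
model value. Responder thresholds are strict: MV increase > 0.75 L/min,
PaCO2 decrease > 5 mmHg.

The evaluation time of the original simulations is not stated. We
evaluated the candidates: at a 24-h horizon the simulated responder
proportions under 1000 mg once daily (~68% MV/PSV, ~64% MV/VA, ~36%
PaCO2) bracket the reported 65%/60%/45%, whereas at quasi-steady state
(4 days, $k_{out} = 0.314$/day) essentially all subjects respond
(>95%), far from the reported figures. Since the study's own observed
contrasts are 24-h pre/post differences, the default horizon is 1 day
after the first dose. Residual (assay) error is excluded from the
deltas by default (`include_residual = TRUE` adds it to both endpoints;
this raises the PaCO2 proportion to ~48% and lowers the MV proportions
to ~58/56%, also within the reported range). The PaCO2 responder
proportion is the quantity most sensitive to this protocol ambiguity.

## Problem sizes and tolerances used in the tests

Steady-state and equilibrium oracles run in fractions of a second at
relative tolerances of 0.1% and 1e-6. The recovery experiment fits one
reference-design cohort (n = 68, published truth, fixed seeds) with
300 + 200 SAEM iterations and checks $B_0$, $MV_0$, $PaCO2_0$ within
±10%, $k_{out}$ within ±50% and $A_{50}$ within ±60% — roughly twice
the published relative standard errors plus design noise, reflecting
how weakly the turnover pair is identified at three blood gases per
subject. The near-noiseless oracle (no BSV, 1% residual, 30 richly
sampled subjects) recovers all structural parameters within 2%. NPDE
calibration uses 20 replicate cohorts at 500 simulations each and
requires at least 90% of the location and scale tests to be
non-significant at the 5% level (the expected rate for a calibrated
implementation is 95%; counting whole replicates as passing only when
both tests do would put the expected pass rate exactly at the
threshold and turn the check into a coin flip).
Regimen checks use 10,000 virtual subjects per stratum.

## Known limitations

* Respiratory rate and tidal volume are not decomposed; the model
  operates on minute ventilation only, and weaning outcomes, work of
  breathing and safety are out of scope.
* Drug elimination is linear by assumption; no plasma-concentration
  data inform the kinetics, and the furosemide half-life is a stated
  default, not an estimate.
* Only the proportional residual model is implemented (the original
  analysis tested and rejected a combined model; the comparison
  machinery in `compare_models()` can reproduce such a test but the
  combined error model itself is not offered).
* The equation placement of the two drug effects (acetazolamide on
  elimination, furosemide on formation) is reconstructed from the
  pharmacology and the equilibrium constraints; the original equations
  figure is not reproducible from the text.
* Inter-occasion variability, correlated random effects (the
  variance–covariance matrix is diagonal; no reported off-diagonal
  structure exists to reproduce) and mixture models are not
  implemented.
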