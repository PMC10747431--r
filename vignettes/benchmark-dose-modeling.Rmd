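---
title: "Benchmark dose modeling: models, profile limits and decision rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmark dose modeling: models, profile limits and decision rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benchdose)
```

benchdose estimates the benchmark dose (BMD) — the dose producing a
predefined change in an adverse effect relative to background — from
summarized toxicology bioassay data, computes its one-sided lower
confidence limit (BMDL) by profile likelihood, applies the standard
viability and recommendation rules to a suite of candidate models, and
carries a point of departure through the deterministic arithmetic of a
health-based guidance value (ADI, MRL, MOE). This vignette documents the
statistical machinery and the design choices behind it.

## Data model

Quantal (dichotomous) endpoints are dose groups with the number of animals
examined and the number affected; continuous endpoints are dose groups with
size, mean and standard deviation. Both require a control group (dose 0)
and at least three groups, and are kept on the dose scale as printed
(mg/kg bw/day) — BMD and BMDL are reported on that original scale, so no
dose normalization survives into the results (doses are rescaled to [0, 1]
*inside* the optimizer purely for conditioning, and parameters are
converted back).

Dropping dose groups is an explicit, user-driven operation
(`drop_dose_groups()`), mirroring how an assessor omits the highest dose
group when no model fits the full design, or excludes low doses without a
dose-response relationship. The control is never droppable.

## Quantal models

All nine standard dichotomous families are implemented with the
parameterizations used by the EPA's BMDS software, e.g.

* multistage, degree $k$: $p(d) = g + (1-g)\,\bigl(1 - e^{-\sum_{i=1}^k b_i d^i}\bigr)$
* quantal linear: $p(d) = g + (1-g)\,(1 - e^{-b d})$
* gamma: $p(d) = g + (1-g)\,F_{\Gamma}(b d;\, a)$
* Weibull: $p(d) = g + (1-g)\,(1 - e^{-b d^a})$
* log-logistic / log-probit: $p(d) = g + (1-g)\,F(a + b \ln d)$
* logistic / probit: $p(d) = F(a + b d)$
* dichotomous Hill: $p(d) = g + v\,(1-g)\,\mathrm{logistic}(a + b \ln d)$

The log-dose families return $g$ at dose zero (their limit). *Restricted*
fits bound the shape/slope parameters at 1 (gamma, Weibull, log-logistic,
log-probit, dichotomous Hill) or force the multistage coefficients to be
non-negative, excluding biologically implausible curves. Unrestricted
multistage fits relax the coefficient signs but penalize any predicted
probability outside [0, 1] at the observed doses — this is what allows a
locally decreasing curve on plateauing tumor data while keeping the model a
probability model. Unrestricted gamma and Weibull keep the software's
conventional lower bound of 0.2 on the power parameter.

The binomial log-likelihood omits the combinatorial constant, so
$\mathrm{AIC} = -2\hat\ell + 2k$ is directly comparable with BMDS output.

### Benchmark dose

For quantal data the benchmark response is *extra risk*
$\mathrm{ER}(d) = \frac{p(d) - p(0)}{1 - p(0)}$, with a benchmark response
factor (BMRF) of 0.1 by default. Every family admits a closed-form
inversion of $\mathrm{ER}(d) = \mathrm{BMRF}$; the multistage family uses
the smallest positive real root of its polynomial, which handles
non-monotone unrestricted fits correctly. A BMD beyond 10x the highest
observed dose is reported as undefined rather than extrapolated. An
independent oracle (`true_bmd()`) recomputes the BMD by a dense grid scan
plus refinement and is held against the analytic inversion in the tests.

### Profile-likelihood BMDL

The BMDL is the one-sided lower confidence limit at level 0.95: the
largest dose $b < \mathrm{BMD}$ at which the log-likelihood, re-maximized
subject to the constraint $\mathrm{BMD}(\theta) = b$, has dropped by
$\chi^2_1(0.90)/2 \approx 1.3528$ from the unconstrained maximum. The
constraint is imposed by eliminating one parameter per family (e.g.
$b_1 = \bigl(-\ln(1-\mathrm{BMRF}) - \sum_{i \ge 2} b_i b^i\bigr)/b$ for
the multistage model; for the logistic and probit families the intercept is
recovered by a one-dimensional root solve). The outer search walks down
from the BMD in 8% steps so that warm starts track the profile path, then
bisects inside the bracketing step to a relative tolerance of about
$10^{-6}$. Inner constrained optimizations are multi-start bounded
quasi-Newton; for the multistage and polynomial families extra starts
redistribute the benchmark-response mass across coefficients, which the
profile needs on very sparse incidence patterns (e.g. 0/0/0/2 affected).

### Goodness of fit

Pearson $\chi^2 = \sum_i (y_i - n_i p_i)^2 / \bigl(n_i p_i (1-p_i)\bigr)$
with per-group scaled residuals, df = groups minus estimated parameters,
upper-tail p-value; df $\le 0$ leaves the p-value undefined.

### Parameter counting

Parameters whose estimate lands on a *structural* bound — a restriction
bound such as a multistage coefficient at 0, a shape parameter at 1, or a
background at 0 — are not counted as estimated for either the AIC or the
goodness-of-fit df. This is the convention of the reference software and
is what makes, say, a restricted degree-3 multistage that collapses to a
single linear term report the same AIC and df as the quantal-linear model
it has become. Purely numerical guard bounds (optimizer boxes) do not
reduce the count; hitting one raises a `boundary_hit` flag instead.

## Continuous models

Continuous endpoints are fitted under a normal likelihood with a single
shared (constant) variance, computed from the sufficient statistics:
$-2\ell = N \log(2\pi\hat\sigma^2) + N$ with
$\hat\sigma^2 = \tfrac{1}{N}\sum_i \bigl[(n_i-1)s_i^2 + n_i(\bar y_i - m(d_i))^2\bigr]$.
This equals the individual-data likelihood for any data with matching group
summaries (a tested invariant). The variance is profiled out analytically,
so the optimizer only sees the mean-model parameters. Families: linear,
polynomial (degree capped like the multistage degree), power
$m(d) = g + v d^n$, Hill, and exponential-3/5; the exponential families are
offered in restricted form only, matching the software suite the results
are compared against. The adverse direction is taken from the
configuration (down for body weight), never auto-detected.

The benchmark response is the *relative deviation*: the smallest dose at
which $|m(d) - m(0)| = \mathrm{BMRF} \cdot |m(0)|$ in the adverse
direction, again with closed-form inversions per family. Goodness of fit
is a likelihood-ratio test against the saturated model (one free mean per
group, shared variance), which cancels all distributional constants, so
the GOF p-value is convention-independent even where absolute AIC values
depend on constant-term conventions. BMD/BMDL parity with reference
results is the binding requirement; AIC parity is best-effort, and
within-suite AIC *ranking* (what the recommendation uses) is unaffected by
the additive constant because every model sees the same $N$.

## Classification and recommendation

Each fit is classified following the frequentist recommendation logic of
BMDS 3.3:

* **unusable** — no convergence, or BMD/BMDL not computable;
* **questionable** — GOF p-value < 0.10; p-value undefined because the
  model saturates the groups (df = 0); BMD or BMDL more than 10-fold below
  the lowest positive dose; or a scaled residual exceeding 2 in magnitude;
* **viable** — everything else. A BMD or BMDL above the highest dose is a
  *warning*, not a disqualifier.

The low-BMD rule matters in practice: unrestricted shape families on
plateauing tumor data happily fit a supra-linear curve whose BMD collapses
to a fraction of the lowest dose; the p-value alone would call them viable
while the reference assessments do not.

Among viable models, if the BMDLs span at most a 3-fold range (a
configurable `narrow_ratio`), the lowest AIC is recommended; otherwise the
lowest BMDL. The 3-fold convention is the software guidance's default and
is the value that reproduces both observed branches in the validation
data: a wide BMDL range (unrounded 18-58 on the carcinoma endpoint) picks
the lowest BMDL, a narrow one (353-432 on body weight) picks the lowest
AIC. Ties on the deciding criterion break by lower BMDL, then by a fixed
alphabetical family order, which makes the recommendation invariant to the
input ordering of fits (a tested property). When a tie spans models that
have collapsed to the same curve, one representative is recommended; the
tied models carry identical BMD/BMDL anyway.

## Risk arithmetic

The downstream arithmetic is deliberately plain: ADI = POD / product of
uncertainty factors (the `uf_ledger()` keeps each factor labelled);
MRL = allocation x ADI x body weight / daily commodity intake;
per-capita amounts convert to per-kg doses by dividing by body weight
(default 60 kg, the JECFA convention; EFSA's 70 kg is a parameter, not a
different code path); MOE = POD / exposure. All operations are exact
double arithmetic on the inputs; integer-looking published values (16,
960, 1280, 6000) emerge exactly, and any rounding (two decimals for
exposures) is presentation-only.

## Synthetic data

`simulate_quantal()` draws affected counts binomially from a chosen
family's true probabilities; `simulate_continuous()` draws individual
normal responses and summarizes them to (n, mean, sd), exactly the
information the fitting consumes. Both take an explicit integer seed for
the global RNG and record it in the returned scenario attribute; model
fitting itself contains no randomness, so fits of simulated data are
reproducible end to end.

The default test scenarios mirror the bioassay designs the package is
validated on: 4 doses x 50 animals (2-year design), 6 doses x 10 animals
(3-month design), 4 groups x 10 for continuous summaries. The BMDL
coverage check uses a quantal-linear truth with background 0.15 and a true
BMD of 50 mg/kg bw/day placed between control and the middle of the tested
range at the 4 x 50 design, 500 replicates; one-sided coverage of the
nominal 95% limit is required to be at least 0.93, the margin reflecting
Monte Carlo error plus the mild small-sample undercoverage profile limits
show near parameter bounds. What these simulations emulate is sampling
noise around a correctly specified model; they do not emulate model
misspecification, litter effects, historical-control drift or
dose-placement pathologies, so passing them says the estimator and its
confidence limit are correctly computed, not that any single real dataset
is well described by the chosen family.

## Numerical choices

* Optimizer: L-BFGS-B with a deterministic multi-start grid seeded from
  transform-regression estimates (e.g. regressing
  $\log(-\log(1-\mathrm{ER}))$ on log dose for the Weibull), Nelder-Mead
  fallback on failure; convergence factor `factr = 1e4`.
* Dose in [0, 1] and response in units of the control mean inside the
  optimizer; parameters and the log-likelihood are converted back exactly.
* Probabilities are clamped to $[10^{-12}, 1-10^{-12}]$ inside the
  likelihood; constraint violations (unrestricted multistage probabilities,
  restricted signs under profile elimination) are quadratic penalties with
  weight $10^6$.
* Degenerate inputs: datasets without a control group, with duplicate
  doses or with `affected > n` are rejected at construction with the
  offending row named; a fitted probability of exactly 0 or 1 at a group
  with observations flags the fit rather than producing NaN residuals.
* Degree rule: multistage/polynomial degree defaults to one less than the
  number of dose groups, capped at 3.

## Limitations

Only summarized data are supported (no individual animals, no
litter/nested structure); continuous responses are normal with constant
variance (no modeled variance, no lognormal, no hybrid tail-probability
BMR); there is no Bayesian fitting or model averaging; and time-to-tumor
or survival-adjusted incidence is out of scope. AIC values for continuous
models can differ from other software by an additive constant convention,
and exact parameter counts can differ when an estimate sits infinitesimally
off a bound — BMD/BMDL values are the stable, binding quantities.
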