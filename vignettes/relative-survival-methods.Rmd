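---
title: "Relative survival as a generalisability measure: models, conventions, and the synthetic scenario"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative survival as a generalisability measure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relsurvgen)
```

## The problem

Longitudinal cohorts of older people lose participants to death, and cohort
members are rarely a random draw from the population they are meant to
represent: people who volunteer for health studies tend to be healthier than
their peers (the healthy-volunteer effect). Baseline comparisons with census
or survey data capture who enrolled; they say nothing about whether the
cohort's subsequent *mortality experience* matches the population's, which is
exactly what matters when survivors are re-surveyed for years.

Relative survival expresses this in a single measure: the ratio of the
survival observed in the cohort to the survival the same people would have
had under the age-, calendar-year- and region-specific mortality of the
general population, taken from published life tables. A cumulative relative
survival of 1.10 at twelve years means the cohort retained 10% more of its
members than population mortality predicts — a direct, interpretable
quantification of how selective enrolment and attrition-by-death bias the
surviving panel.

## The cohort life table

Follow-up time since entry is cut into annual intervals
$[i, i+1)$. With $L_i$ members at risk at the start of interval $i$, $D_i$
deaths and $W_i$ withdrawals (losses and administrative censorings) during
it, the actuarial convention treats withdrawals as exposed for half the
interval:

$$L_i' = L_i - W_i/2, \qquad P_i = 1 - D_i/L_i', \qquad
  CP_{i+1} = CP_i \, P_i, \quad CP_0 = 1 .$$

Expected survival uses the Ederer II estimator: expected deaths in interval
$i$ are accumulated only over the members actually still at risk at its
start,

$$D_i^* = \sum_{j \,\in\, \text{at risk}} w_j \, q^*_{ij},$$

where $q^*_{ij}$ is member $j$'s annual death probability from the
population life table at their attained age (entry age $+ i$), attained
calendar year (entry year $+ i$) and stratum, and $w_j$ is the sampling
weight. Members censored *within* the interval contribute $w_j q^*_{ij}/2$,
mirroring the $L - W/2$ exposure convention on the observed side. Then
$P^*_i = 1 - D^*_i/L_i'$, $CP^*$ follows the same product recursion, and the
interval-specific and cumulative relative survival ratios are

$$R_i = P_i / P^*_i, \qquad CR_i = CP_i / CP^*_i .$$

Design oversampling (e.g. of rural and remote residents) is handled by
accumulating every count — $L$, $D$, $W$, $D^*$ — as a sum of weights; all
formulas then apply unchanged, and the ratios are invariant to rescaling all
weights by a constant.

`rs_lifetable()` runs this pipeline from individual records and a population
life table. It also accepts pre-tabulated counts plus an injected
expected-survival series, which is how a published table can be rebuilt from
its printed columns: when a printed cumulative expected column is supplied
it is used as given, because a cumulative product of per-interval values
rounded to three decimals carries less information than the printed
cumulative column itself.

### Confidence intervals

The source analyses for tables of this kind typically leave the variance
estimator unstated. We use the Greenwood estimator of the variance of
$\log CP$,

$$\widehat{\mathrm{var}}(\log CP_i) =
  \sum_{k \le i} \frac{D_k}{L_k' (L_k' - D_k)},$$

treat $CP^*$ as fixed (national life tables are estimated from complete
death registrations; their sampling error is negligible against the
cohort's), and set $CI = \exp\{\log CR_i \pm z_{1-\alpha/2}
\sqrt{\widehat{\mathrm{var}}}\}$. The test suite validates this choice
against a percentile bootstrap (resampling records) on a synthetic cohort of
2000: the two intervals agree to well within 15% of the interval width.
With weights the same formula is applied to the weighted counts; this
ignores the design effect of unequal weights, which is the standard
first-order practice for weighted actuarial tables and is conservative only
by accident — a survey-design variance is out of scope.

### Conventions and degenerate inputs

* Intervals are half-open $[i, i+1)$; an endpoint exactly on a boundary
  belongs to the interval that starts there (floor-based binning, no ties).
* Display truncates the effective at-risk count to an integer, as published
  tables do (9106.5 prints as 9106); all computation keeps full precision.
* An interval with $L' \le 0$ is dropped with a warning; $D > L'$ is an
  error, as is a zero expected survival or an interval where everyone at
  risk dies (Greenwood variance undefined).
* Ages beyond the life table clamp to its terminal age (published tables end
  in an open-ended age group); calendar years outside the table fall back to
  the nearest tabulated year, deterministically.
* Whether the life-table lookup should track each member's attained calendar
  year or stay fixed at the entry year is not decidable from a published
  analysis; both are exposed (`year_mode = "attained"` is the default, since
  annual national tables exist for each follow-up year).

### The half-interval approximation

The actuarial convention is first-order exact: with censoring times spread
uniformly over an interval, a censored member's true expected death
probability before censoring is $\mathrm{E}[1 - e^{-\mu u}] \approx \mu/2 -
\mu^2/6$, while the convention charges $q/2 \approx \mu/2 - \mu^2/4$ on the
expected side. The interval ratio $R$ therefore carries an upward bias of
order $\mu^2/3$ in intervals with heavy within-interval censoring — about
0.001–0.002 at hazards typical of ages 81–86. This is a property of the
estimator, not of the implementation; the test suite both verifies clean
calibration ($\mathrm{E}[R] = 1$ within Monte-Carlo error) on null cohorts
observed through every interval, and bounds this approximation error below
0.5% under an enrolment-spread scenario.

## The multiplicative relative-mortality model

To ask *which baseline characteristics* carry the cohort's survival
advantage, the death intensity of member $i$ at attained age $a$, stratum
$s$ is modelled as a log-linear scaling of the known population hazard:

$$\lambda_i(a, s, z_i) = \lambda^*_i(a, s) \, e^{\beta' z_i},$$

a multiplicative (SMR-type) model: a hazard ratio below 1 means mortality
below that of population peers, i.e. better relative survival. The
multiplicative form is preferred to the additive excess-hazard model here
because an ageing general-population cohort need not sit uniformly above or
below population mortality for every covariate pattern.

Follow-up is split into annual person-time cells aligned to time since
entry; each cell carries its exposure, the population hazard
$\mu^* = -\log(1 - q^*)$ at the cell's attained age/year/stratum, and the
member's baseline covariates (covariates are time-fixed; the only
time-dependence is through $\mu^*$). Because $\lambda^*$ is fully specified
there is no nuisance baseline, and the log likelihood on the cells,

$$\ell(\beta) = \sum_{\text{cells}} w \left[ d (\log \mu^* + \beta'z)
  - \mu^* \, t \, e^{\beta' z} \right],$$

is exact and globally concave — formally a Poisson likelihood with offset
$\log(\mu^* t)$. It is maximised by Newton–Raphson with the analytic
gradient and Hessian, step-halving on any likelihood decrease,
initialisation at $\beta = 0$, and convergence declared when the relative
likelihood change falls below $10^{-8}$ (at most 50 iterations; a
non-converged fit is returned flagged, not thrown). The likelihood depends
on the data only through per-covariate-pattern sums of weighted events and
weighted expected events, so cells are aggregated before iteration — fits
on a million cells take milliseconds — and aggregation provably leaves
$\hat\beta$ unchanged.

Two parameterisation decisions:

* **Intercept.** The default formula includes an intercept, so
  $e^{\beta_0}$ is the overall SMR of the reference category and the
  remaining hazard ratios are relative to their reference levels, printed as
  1.00 — the layout of published multivariate tables. With a fully known
  $\lambda^*$ the no-intercept model is also estimable (`~ x - 1`), pinning
  the reference category to population mortality; that is a stronger
  assumption than a cohort-level analysis usually wants.
* **Weights and variance.** Sampling weights enter as pseudo-likelihood
  multipliers; the reported covariance is the inverse observed information.
  A cluster (by participant) sandwich estimator is available via
  `robust = TRUE` but is off by default, matching the common practice of
  adjusting for the design by covariate inclusion rather than by
  design-based variance. Records with missing covariates are excluded with
  a logged count (complete-case analysis).

In the one-binary-covariate case the maximum-likelihood hazard ratio equals
the ratio of the two groups' standardised mortality ratios exactly; the test
suite asserts this closed form and cross-checks general fits against an
independent Poisson-with-offset fit from `stats::glm`.

## Survey comparison and counterfactual reweighting

Baseline category distributions are compared with a reference health survey
by Pearson's $\chi^2$ on the $k \times 2$ count table ($df = k - 1$, no
continuity correction by default — multi-category tables at large $N$).
Published comparison tables give percentages and totals; `reconstruct_counts()`
rebuilds counts as $\mathrm{round}(pct/100 \times N)$, repairing a
discrepancy of at most $k/2$ by the largest-remainder rule (a pure rounding
artifact) and otherwise preserving and reporting it, since a larger gap
reflects rounding already present in the published percentages and forcing
the total would distort individual categories.

The contribution of one characteristic to the survival advantage is
quantified by direct standardisation: per-category cumulative mortality
$M_k = 1 - CP_k(h)$ at horizon $h$ is estimated by running the life-table
stage within category $k$, and the cohort's mortality is recomputed under a
target (e.g. the reference survey's) category distribution:

$$\frac{\sum_k \pi^{\text{target}}_k M_k}{\sum_k \hat\pi_k M_k},$$

with $\hat\pi_k$ the weighted observed proportions. The choice of the
life-table $CP$ as the per-category mortality estimator keeps the
counterfactual consistent with the headline analysis. The ratio is
scale-free in cohort size and invariant to category ordering.

## The synthetic scenario

Since the motivating microdata are not public, the generator produces
cohorts with the full statistical structure the analysis assumes, with known
ground truth.

**Life table.** Adult mortality follows a Gompertz law: $q(s, y, a) = 1 -
\exp\{-m_s b e^{ca}\}$. The default slope $c = \log 2 / 8$ doubles the
hazard every 8 years of age, the standard tempo for ages 70+. The base
hazard $b$ is solved in closed form so that expected 12-year survival from
entry at age 70 is 0.665, anchoring the synthetic table to the cumulative
expected survival scale of real analyses of women this age. Stratum
multipliers (urban 0.99, rural 1.02, remote 1.08) impose a mild remoteness
gradient; a secular-improvement hook exists (`trend`) but defaults to zero.

**Cohort.** The default scenario enrols $n = 12\,424$ women in 1996 at ages
70–75 (19% at each of 70–74, 5% at 75), over-samples rural (×2) and remote
(×4) strata with weights $1/\text{fraction}$, draws baseline smoking
(62.1 / 30.4 / 7.6% never/ex/current) and self-rated health
(6.4 / 26.2 / 39.4 / 23.6 / 4.3% excellent–poor) independently, and censors
administratively at $12 - U(0, 1)$ years: enrolment over the whole entry
calendar year with a single censoring date puts all administrative
withdrawals uniformly inside the final interval — simultaneously the
realistic pattern (withdrawals appear only in the last annual row) and the
evenly-distributed-withdrawals assumption under which the actuarial
estimator is calibrated.

**Hazards.** Member $i$'s hazard in follow-up year $k$ is
$h \cdot \mu^*(a_i + k,\, 1996 + k,\, s_i) \cdot e^{\beta' z_i}$, and death
times are drawn by inverse transform over this piecewise-constant hazard.
Two deliberate choices:

* `healthy_volunteer_factor` $h = 0.92$ implements the central phenomenon —
  a cohort uniformly healthier than its source population — as a single
  scalar.
* Covariate effect sizes mirror published multivariate hazard ratios
  (smoking 1.27 / 1.84; self-rated health 1.10 / 1.42 / 2.42 / 4.86 against
  their reference levels) but are **centred** within each covariate,
  $\beta_k \leftarrow \beta_k - \log \sum_k \pi_k e^{\beta_k}$, so the
  cohort-average covariate multiplier is exactly 1. Without centring,
  reference levels anchored at the population hazard would give the average
  member nearly twice population mortality and the scenario would contradict
  the survival advantage it exists to emulate; with it, $h$ alone sets the
  cohort-level advantage and the published *relative* effects are preserved
  (differences of centred coefficients are untouched, and the regression
  stage re-estimates them as such with its intercept absorbing $h$ and the
  centring).

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: death-ascertainment error (probabilistic
registry linkage with a 3–11% false-negative range is a separately argued
limitation of such studies), correlation between covariates (a hook exists,
defaults to independence; published sources give no joint distribution),
time-varying covariates, within-stratum frailty beyond the modelled
covariates, and secular mortality improvement (off by default). The preset's
$h = 0.92$ is a scenario choice, not an estimate: cohort-level advantage and
covariate effects are not jointly identifiable from published aggregates.

## Problem sizes

The shipped checks use simulation scales chosen to make Monte-Carlo error
small against the effects being verified while keeping a full run of the
suite inside a coffee break: parameter recovery uses 100 cohorts of
$n = 10\,000$ (Monte-Carlo SE on the smoking log-HR about 0.01); null
calibration uses 200 replicates of $n = 5\,000$ (per-interval SE on $R$
between 0.0002 and 0.0005); the bootstrap cross-check of the Greenwood CI
uses 1000 resamples of a 2000-member cohort; qualitative trajectory checks
use single cohorts of 20 000–50 000.

## Known limitations

* Ederer II only; Ederer I, Hakulinen, period analysis, age-standardised
  (ICSS-weighted) relative survival and cure models are out of scope.
* Greenwood-with-fixed-$CP^*$ intervals ignore the weight design effect.
* Abridged (5-year) life tables are not interpolated; the table must carry
  single-year ages, contiguous and uniform across stratum-years.
* The regression supports time-fixed baseline covariates only.
* Counterfactual reweighting standardises over one characteristic at a
  time; joint reweighting would need a joint target distribution, which
  published survey tables do not provide.
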