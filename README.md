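# relsurvgen

Relative survival as a generalisability measure for ageing cohorts.

Longitudinal studies of older people are threatened by a bias that baseline
comparisons cannot see: participants tend to be healthier than the
population they were sampled from, and death removes members non-randomly
for the rest of the study. `relsurvgen` quantifies this by **relative
survival** — the ratio of the cohort's observed survival to the survival
expected if its members had experienced the mortality of their population
peers (same age, calendar year and region, from published life tables).

For annual follow-up intervals with $L$ at risk, $D$ deaths and $W$
withdrawals, the actuarial cohort life table uses

$$L' = L - W/2, \quad P = 1 - D/L', \quad CP_{i+1} = CP_i P_i,$$

with expected deaths $D^*$ from the Ederer II estimator (population death
probabilities $q^*$ summed over the members still at risk, half-weight for
those censored within the interval), expected survival $P^\*$, $CP^\*$ by
the same recursion, and relative survival

$$R = P/P^*, \qquad CR = CP/CP^* .$$

Sampling weights (design oversampling) enter every count. Greenwood-type
confidence intervals are computed on the log cumulative scale with expected
survival treated as fixed. A companion regression stage fits the
multiplicative relative-mortality (SMR-type) proportional hazards model

$$\lambda_i(a, s, z_i) = \lambda^*_i(a, s)\, e^{\beta' z_i}$$

on annually split person-time by exact maximum likelihood (a hazard ratio
below 1 means mortality below population peers). Further stages compare
cohort covariate distributions with a reference survey (Pearson $\chi^2$),
recompute cumulative mortality under a counterfactual covariate distribution
(direct standardisation), and simulate entire synthetic cohorts plus
Gompertz population life tables with known ground truth.

## Worked example

Simulate a cohort of 4000 women entering in 1996 at ages 70–75 from the
documented default scenario (rural/remote oversampling, a cohort-wide
healthy-volunteer hazard factor of 0.92, baseline smoking and self-rated
health with realistic marginals), then estimate its relative survival
against the same life table:

```r
library(relsurvgen)

preset <- alswh_like_preset(n = 4000, seed = 20)
cohort <- simulate_cohort(preset$config, preset$table)
fit <- rs_lifetable(cohort, preset$table, max_intervals = 12)
summary(fit)
#> Cumulative relative survival at 12 years: 1.061 (95% CI 1.031-1.093)
#> Observed 0.647 vs expected 0.609 cumulative survival; deaths: 960
#> Relative survival advantage: +6.1%
```

The weighted cohort kept 6.1% more of its members over twelve years than
population mortality predicts, and the interval-by-interval table
(`print(fit)`) shows the cumulative ratio `CR` climbing steadily from 1.007
to 1.061 — the survival advantage does not wash out with follow-up. Which
baseline factors carry excess mortality *within* the cohort:

```r
cohort$smoking <- factor(cohort$smoking, levels = c("never", "ex", "current"))
m <- relmort(~ smoking, cohort, preset$table)
hazard_ratio_table(m)
#>    covariate       level hazard_ratio    ci_low  ci_high       beta         se
#> 1 (baseline)         SMR     0.790568 0.7273209 0.859315 -0.2350036 0.04254356
#> 2    smoking never (ref)     1.000000        NA       NA  0.0000000         NA
#> 3    smoking          ex     1.178340 1.0244387 1.355361  0.1641065 0.07141028
#> 4    smoking     current     1.868277 1.5141858 2.305172  0.6250166 0.10721560
```

Never-smokers in this cohort die at 0.79× the rate of their population
peers; current smokers at 1.87× the never-smoker rate — close to the true
simulated effect (1.84). Published tables can also be rebuilt directly from
their printed counts via the `counts`/`expected` arguments of
`rs_lifetable()`, and `rs_lifetable_by()` re-runs the analysis per subgroup.
An end-to-end driver (`run_pipeline()`, with a thin command-line wrapper in
`inst/scripts/relsurv_pipeline.R`) orchestrates simulate / lifetable /
regress / compare runs from a single config.

See the vignette (`vignettes/relative-survival-methods.Rmd`) for the models,
estimation conventions, and what the synthetic scenario does and does not
emulate.

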