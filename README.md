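# cohortcomp

Did a population-level disruption change *who* was born, not just *how many*?
`cohortcomp` estimates shifts in the socioeconomic composition of a birth
cohort conceived during the COVID-19 pandemic, relative to the counterfactual
cohort that would have been born had pre-pandemic trends simply continued.
It is written for demographers and epidemiologists working with weekly or
monthly live-birth counts stratified by parental socioeconomic position
(income or deprivation quintiles, or maternal education), and ships a
synthetic birth-register generator with exact ground truth so the entire
workflow can be developed and validated without access to restricted
national registers.

## Model

For each socioeconomic group *g*, live-birth counts per period *t* follow an
interrupted-time-series Poisson regression with log link and no offset:

```
y_gt ~ Poisson(mu_gt)
log mu_gt = a_g + b1_g * t_lin + b2_g * t_lin^2        (secular trend)
          + s_g[week/month of year]                     (seasonality, ref = first period of year)
          + sum_k c_gk * 1[t in shock window k]         (e.g. Zika, Aug-Dec 2016)
          + d_g * 1[t in exposed window]                (average pandemic effect)
```

where `t_lin = (t - mean(t)) / T` is the centred/scaled period index. The
exposed window — the birth cohort plausibly conceived after the mid-March
2020 lockdowns — is December 2020 through December 2021: 13 months for
monthly series, or 54 weeks starting in ISO week 51 of 2020 for weekly
series.

The counterfactual number of births for group *g* is the model prediction
summed over the exposed window with `d_g` set to zero (seasonality
retained), with a delta-method standard error from the coefficient
covariance. Compositions are the group shares of these totals; the headline
quantity is the percentage-point difference `100 * (p_g - q_g)` between the
observed share `p_g` and counterfactual share `q_g`. Its 95% confidence
interval comes from a three-step Monte-Carlo procedure: draw each group's
counterfactual total independently from `Normal(total_g, se_g)`, renormalise
the draws into a composition, difference against the observed composition;
repeat 10,000 times and take the 2.5th/97.5th percentiles.

## Worked example

The built-in monthly demonstration scenario emulates a small European
country (~7,100 births/month) with education-style groups and known truth:
exposure multipliers 1.05 (advantaged), 1.01 (middle), 0.97 (disadvantaged),
1.00 (missing information).

```r
library(cohortcomp)

series <- generate_group_series(demo_scenario("monthly"))
fit <- cohort_composition(series, n_draws = 10000, seed = 1)
fit
#> Counterfactual birth-cohort composition analysis
#>   4 groups, exposure 2020-12 .. 2021-12, 10000 Monte-Carlo draws
#>
#>          group observed counterfactual             delta_pp
#>     advantaged   30,580         29,137 +1.12 [+0.60; +1.66]
#>         middle   42,397         42,335 -0.51 [-1.09; +0.05]
#>  disadvantaged   17,307         17,654 -0.61 [-1.05; -0.18]
#>        missing    4,763          4,707 -0.00 [-0.25; +0.24]
#>              rel_diff
#>  +5.0% [+2.8%; +7.2%]
#>  +0.1% [-1.5%; +1.9%]
#>  -2.0% [-4.4%; +0.6%]
#>  +1.2% [-3.7%; +6.5%]
```

Reading the first row: over the exposed window the advantaged group had
30,580 observed births against a counterfactual expectation of 29,137 —
about 5% more births than expected (`rel_diff`), lifting its share of the
cohort by 1.12 percentage points (`delta_pp`), 95% CI [+0.60; +1.66]. The
generative truth for this scenario is a +1.09 pp shift, inside the interval.
`plot(fit)` draws the dot-and-CI composition chart; `plot(fit$fits$advantaged)`
shows observed counts with the fitted, deseasonalised and dashed
counterfactual trajectories and the exposure-start rule.

Real data enter either as pre-aggregated counts
(`read_count_series()`, CSV `period,group,count` with `2020-W51` /
`2020-12` period labels) or as individual records
(`aggregate_records()`, with `assign_quintiles()` for quintile grouping from
pre-pandemic scores and `filter_records()` for inclusion rules). The whole
workflow is also scriptable from one YAML file via `run_pipeline()` — see
`inst/extdata/demo_analysis_config.yaml` and the thin CLI at
`inst/scripts/cohortcomp.R` (subcommands `simulate`, `build`, `fit`,
`compose`, `run`).

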