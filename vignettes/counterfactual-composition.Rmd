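---
title: "Counterfactual birth-cohort composition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual birth-cohort composition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortcomp)
```

## The question and the estimand

Fertility responds quickly to large shocks, and it need not respond equally
across social strata. If socioeconomically advantaged couples postponed
fewer or recuperated more conceptions during the COVID-19 pandemic than
disadvantaged couples, the cohort conceived during the pandemic differs in
its parental socioeconomic make-up from the cohort that would have been born
otherwise — with consequences that compound over that cohort's life course.

`cohortcomp` estimates exactly that compositional shift. The estimand, for
each socioeconomic group $g$, is

$$\Delta_g = 100\,(p_g - q_g),$$

the percentage-point difference between the group's observed share $p_g$ of
births in the exposed window and its counterfactual share $q_g$ under a
continuation of pre-pandemic trends. Working with *shares* rather than
counts makes countries and data sources comparable and separates "fewer
births overall" from "a different mix of births".

## The exposed cohort

Births from December 2020 through December 2021 are taken as the cohort
potentially conceived after the mid-March 2020 lockdowns: given typical
gestational ages, roughly half of late-December 2020 births were conceived
after pandemic onset. Weekly series use ISO-8601 weeks (Monday start, the
European register standard) and are exposed from the start of ISO week 51 of
2020 for 54 weeks; monthly series from December 2020 for 13 months. Because
2020 contains an ISO week 53, "54 weeks from 2020-W51" ends with 2021-W51;
the package treats the window as fixed-length rather than ending at the last
ISO week of 2021, keeping the weekly and monthly windows the same calendar
length. The deliberately short window is also what justifies the
counterfactual: extrapolating level, trend and seasonality 13 months beyond
the pre-pandemic data is defensible where a multi-year extrapolation would
not be.

## The per-group model

Counts per period are modelled by an interrupted time series Poisson
regression with log link and no population offset (registers rarely provide
a usable weekly population-at-risk, and shares are insensitive to a common
scale):

$$\log \mu_{gt} = a_g + b_{1g}\,\tilde t + b_{2g}\,\tilde t^2 +
  s_{g}[\mathrm{woy}(t)] + \textstyle\sum_k c_{gk}\,Z_k(t) + d_g\,E(t),$$

* $\tilde t = (t - \bar t)/T$: the 0-based period index centred and divided
  by the series length. This keeps the quadratic term well conditioned
  (raw $t^2$ up to $365^2$ would produce a nearly singular information
  matrix) and makes generator truth and fitted coefficients directly
  comparable, since the synthetic module uses the identical scaling.
* $s_g[\cdot]$: week- or month-of-year fixed effects, first week/month of
  the year as reference. ISO week 53 occurs in only one or two years of a
  typical span, so its indicator is merged with week 52 rather than
  estimated from a couple of observations.
* $Z_k(t)$: optional level-shift shock indicators over fixed calendar
  windows, absorbing known disturbances so they do not bend the estimated
  trend — e.g. a Zika-style window August–December 2016, or a
  data-collection break spanning whole years. Shock windows may not overlap
  the exposure window.
* $E(t)$: the exposure indicator; $d_g$ is the average log level change over
  the whole exposed window (no slope change or interaction — a deliberate,
  uniform specification that trades a little per-country flexibility for
  comparability and interpretability).

Fitting is iteratively reweighted least squares with step-halving
(`stats::glm.fit`), relative deviance tolerance $10^{-10}$, at most 100
iterations; non-convergence is flagged and every downstream operation
refuses a non-converged fit. The coefficient covariance is the inverse
Fisher information $\left(X^\top \mathrm{diag}(\hat\mu) X\right)^{-1}$.
The test suite checks the canonical-link score identity
$\sum_t (y_t - \hat\mu_t)\,x_t = 0$ and agreement with a brute-force
likelihood-grid maximiser to $10^{-4}$ on small problems.

## Counterfactual totals, paths, and their standard error

Two related quantities are derived from each fit, and they are intentionally
not the same:

* **Totals** (the inferential quantity): $\hat N_g^{cf} = \sum_{t \in E}
  \exp(\tilde x_t^\top \hat\beta)$ where $\tilde x_t$ zeroes only the
  exposure column. Seasonal and shock terms are *retained*: the total counts
  real births in real calendar periods, and although a window spanning
  roughly whole seasonal cycles makes the seasonal contribution nearly
  cancel, it does not cancel exactly for 54-week/13-month windows.
* **Paths** (the display quantity): the deseasonalised trajectory
  $\exp(a + b_1 \tilde t + b_2 \tilde t^2 + d\,E(t))$, and its counterfactual
  variant with $d$ also removed — the solid and dashed smooth curves of the
  standard ITS display, free of seasonal sawtooth.

The standard error of $\hat N_g^{cf}$ is the delta method,
$se = \sqrt{g^\top \widehat{\mathrm{Cov}}(\hat\beta)\, g}$ with
$g = \sum_{t\in E} \exp(\tilde x_t^\top\hat\beta)\,\tilde x_t$. A
model-simulation alternative (draw $\beta$ from its asymptotic normal,
recompute the total) agrees within a few percent; the acceptance suite
checks agreement within 5% against a 100,000-draw simulation, guarding the
delta-method linearisation.

## Composition inference: the three-step Monte-Carlo CI

Point estimates are plug-in shares: $p_g$ from observed window totals, $q_g$
from counterfactual totals; deltas sum to zero by construction. The 95% CI
for each $\Delta_g$ repeats, 10,000 times:

1. draw $X_g \sim \mathrm{Normal}(\hat N_g^{cf}, se_g)$ independently across
   groups (between-group independence is an assumption, not a result);
2. renormalise: $q_g^{(r)} = X_g / \sum_h X_h$;
3. difference against the *observed* composition:
   $d_g^{(r)} = 100\,(p_g - q_g^{(r)})$;

and takes the empirical 2.5th/97.5th percentiles (type-7 quantiles, linear
interpolation between order statistics, so bounds are bit-reproducible given
the seed). Draws are filled from one random stream in alphabetical group
order, making results independent of row order and parallelisation, and the
same draws are reused for the relative-difference CIs
($100\,(N_g^{obs}/X_g - 1)$) so the two outputs are internally consistent.

Two boundary rules: a replicate whose draws sum to a nonpositive value
cannot be renormalised and raises an error; individual negative draws are
left untruncated by default — faithful to the plain normal scheme, and
immaterial when $se_g \ll \hat N_g^{cf}$ as in register-scale data — with
`truncate_at_zero = TRUE` available for tiny-count scenarios. Percentile
intervals of a nonlinear functional need not contain the plug-in point
estimate, so the code asserts only $lo \le hi$.

A known property of this procedure is mild undercoverage: step 1 propagates
only the counterfactual estimation uncertainty, while the observed share
$p_g$ — itself Poisson-noisy — is treated as fixed. In the package's null
coverage experiments (200 simulated registers, truth $\Delta_g = 0$)
empirical coverage sits around 0.90–0.93 rather than 0.95, which is the
expected behaviour of the procedure, not an implementation defect; the
acceptance suite asserts coverage within [0.90, 0.99].

## The synthetic register

Real national birth registers are access-restricted, so validation runs on a
synthetic module whose generative model mirrors the regression term for
term: Poisson counts with log-linear intercept, scaled linear/quadratic
trend, seasonal effects (reference period fixed at 0; week 53 reuses week
52's effect), optional shock windows and a group-specific exposure effect.
The match is deliberate — every fitted coefficient has an exact generative
counterpart and `true_counterfactual_summary()` gives closed-form targets —
but it also bounds what passing tests can show: the generator emulates the
*statistical structure* of a register, not its pathologies. It does not
simulate overdispersion, delayed registration, stillbirth selection,
migration, day-of-week birth patterns (dates are uniform within period), or
autocorrelated shocks; agreement on synthetic data demonstrates correctness
of the machinery, not robustness of the Poisson assumption on any real
register.

Record-level generation draws the same counts as the series generator under
the same seed (so aggregation reproduces the series exactly) and scatters
dates uniformly within periods; optional covariates (maternal age, parity, a
group-shifted continuous socioeconomic score) exercise the filtering and
quintile-assignment paths.

The built-in scenarios fix the study conditions once: the monthly demo is a
small-country register (~7,100 births/month across advantaged / middle /
disadvantaged / missing groups, 2015–2021, exposure multipliers 1.05 / 1.01
/ 0.97 / 1.00); the weekly demo is a two-group, seven-year design at ~500
births/week per group with a 7% exposure effect in one group — magnitudes in
line with the largest register-based estimates of pandemic birth effects.
Seasonal amplitude is ±6% on the log scale, a typical European seasonal
swing. Validation problem sizes: 200 replicates for the recovery and
coverage experiments, 2,000 Monte-Carlo draws per replicate CI (the bounds
at 2,000 vs 100,000 draws differ by well under 0.2 pp on fixtured inputs),
10,000 draws for reported analyses.

## Preparing real data

* **Quintiles** are assigned from cutpoints of a *pre-pandemic* reference
  distribution only (20/40/60/80 percentiles, type-7), so pandemic-induced
  shifts in incomes or deprivation scores cannot move group boundaries.
  Values at a cutpoint go to the lower quintile (left-closed, deterministic);
  out-of-range values clamp to Q1/Q5; missing scores become a
  missing-information group, which is carried through the analysis as an
  ordinary category rather than dropped.
* **Filters** like `maternal_age > 25` are strict inequalities ("over 25"
  is read as excluding exact age 25); the number of removed records is
  reported.
* Aggregation zero-fills every (period, group) combination over a gapless
  period span, and errors loudly on unparseable dates, naming the record.

## Known limitations

* Equidispersion: Poisson variance equals the mean. Real registers are often
  mildly overdispersed; the model (intentionally uniform across countries)
  does not offer a negative-binomial alternative, so real-data standard
  errors may be somewhat optimistic.
* The three-step CI ignores observed-count noise (see above) and
  between-group dependence.
* The counterfactual is a 13-month/54-week extrapolation of a single fitted
  trend; structural breaks unrelated to the pandemic inside the window are
  attributed to it unless modelled as shocks.
* Cohort misclassification at the window edge (pre-pandemic conceptions born
  after the cutoff and vice versa) is inherent to defining exposure by birth
  date; the window start is a compromise, not a sharp boundary.
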