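# depmslt

Multistate life tables for depression-free life expectancy from
interval-censored panel data.

## What problem this solves

Ageing panel surveys interview people every couple of years, score
depressive symptoms at each interview (here the CESD-8 scale, with a score
of 3 or more marking clinically significant symptoms), and record exact
dates of death. Between interviews the depression state is unobserved:
people move among *no depression* (state 1), *depression* (state 2) and
*death* (state 3, absorbing) at unknown times. `depmslt` estimates the
monthly transition process from such interval-censored data and converts
it into health expectancies:

- **Dep-FLE** — expected remaining years lived free of depression,
- **DepLE** — expected remaining years lived with depression,
- **TLE** — total life expectancy, with `TLE = Dep-FLE + DepLE`,

together with parametric-bootstrap standard errors, and the contrasts an
epidemiologist asks of such tables: female-minus-male gaps and
widowed-minus-married differences, with significance flags.

It is aimed at demographers and epidemiologists studying mental-health
expectancies in surveys of the Health and Retirement Study type, and at
methodologists who want a testable, reproducible embedded-Markov-chain
(IMaCh-class) estimation pipeline.

## The model

Ages are measured in integer months. For each living origin state *i*,
one month of ageing applies a multinomial logit:

    ln( p_x^{ij} / p_x^{ii} ) = alpha_ij + beta_ij * x + gamma_ij * z,

for the four transitions 1→2 (onset), 1→3 (death without depression),
2→1 (recovery), 2→3 (death with depression); `x` is age (centred and
scaled internally), `z` a binary time-constant covariate (0 = married,
1 = widowed). The resulting 3×3 monthly matrices have an absorbing death
row (0, 0, 1). An interview pair observed `h` months apart contributes
the corresponding entry of the ordered product of `h` monthly matrices to
the likelihood; a death contributes survival in some living state to the
month before death times the hazard of dying in that month. Missed waves
simply lengthen `h`. The 12 parameters per sex are estimated by
quasi-Newton maximum likelihood; the covariance comes from the inverse
observed information.

Fitted kernels are turned into life tables by propagating a synthetic
cohort month by month to age 110 and integrating occupancy
(trapezoidally, in years), weighting the origin-conditional expectancies
by either the implied period prevalence of the fitted chain or an
observed prevalence table.

A synthetic-panel generator with known true parameters (biennial waves,
missed interviews, CESD-8 items, exactly dated deaths) and a Monte-Carlo
microsimulation oracle make the whole pipeline testable without any
restricted survey data.

## Worked example

```r
library(depmslt)

truth <- generate_panel(synthetic_config(n_individuals = 2000, seed = 1))
pairs <- extract_pairs(apply_inclusion_filters(truth$panel))
fit   <- fit_transitions(pairs[pairs$sex == "female", ])
glance(fit)
#> # A tibble: 1 × 6
#>   logLik n_pairs n_persons n_parameters converged max_gradient
#> 1 -2339.    2970      1117           12 TRUE          0.000140

tidy(fit)
#> # A tibble: 12 × 7
#>   transition term      estimate std.error statistic   p.value estimate_per_month
#> 1 1->2       intercept   -5.40     0.0919    -58.8    0                 NA
#> 2 1->2       age          0.203    0.0718      2.83   4.63e-3            0.00169
#> 3 1->2       cov          0.807    0.169       4.78   1.77e-6           NA
#> 4 1->3       intercept   -6.88     0.173     -39.7    0                 NA
#> # 8 more rows
```

The `1->2` row says: for a married woman at age 70 the log-odds of
depression onset in one month is −5.40 (a monthly probability of about
0.45%); onset rises with age (0.203 per decade) and is higher among
widows (gamma = 0.81, z = 4.8). Life tables with bootstrap uncertainty:

```r
lt <- life_table(fit, z = 1, B = 200, seed = 2)  # widowed women
subset(lt, origin == "weighted",
       select = c(age_years, dep_fle, dep_le, tle, se_tle))
#>   age_years dep_fle dep_le   tle se_tle
#> 1        50   23.4    7.14 30.5   1.31
#> 2        55   19.3    6.57 25.9   1.24
#> 3        60   15.5    5.94 21.5   1.14
#> 4        65   12.1    5.22 17.3   1.03
#> 5        70    9.06   4.46 13.5   0.902
#> 6        75    6.52   3.67 10.2   0.772
#> 7        80    4.49   2.92  7.40  0.648
```

A widowed woman aged 50 in this synthetic population can expect 30.5
more years of life (SE 1.3), 23.4 of them free of depression. Sex and
marital contrasts come from `sex_gap_table()` and `marital_gap_table()`;
`run_pipeline()` executes the whole chain (simulate/read → filter → fit
per sex → life tables → contrast tables) and persists every artifact as
CSV plus a run log.

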