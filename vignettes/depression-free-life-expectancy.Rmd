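---
title: "Estimating depression-free life expectancy from interval-censored panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating depression-free life expectancy from interval-censored panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depmslt)
```

## The estimation problem

Panel surveys of older adults observe a three-state process — no
depression (1), depression (2), death (3) — only at interview dates a
couple of years apart, except for death, which is dated exactly from
vital-status records. Transitions between the living states happen at
unknown times inside the intervals, people can recover and relapse any
number of times between two interviews, and some interviews are missed
entirely. `depmslt` treats the process as a discrete-time Markov chain on
a one-month step, embeds every observed interval into products of monthly
transition matrices, and maximises the resulting likelihood. This is the
interpolated-Markov-chain (IMaCh-class) approach to multistate life
tables, in contrast to the Sullivan method, which borrows prevalence from
cross-sections and cannot account for incidence or differential mortality
by state.

## The monthly transition model

For a person of age $x$ months with covariate $z \in \{0,1\}$
(married / widowed), each living row $i$ of the monthly matrix is a
multinomial logit with the diagonal as reference:

$$\ln \frac{p_x^{ij}}{p_x^{ii}} = \alpha_{ij} + \beta_{ij}\,x + \gamma_{ij}\,z,
\qquad (i,j) \in \{1\to2,\ 1\to3,\ 2\to1,\ 2\to3\},$$

and the death row is $(0, 0, 1)$ exactly. Twelve free parameters per
stratum; models are fitted separately by sex, so sex-specific
expectancies never share parameters.

**Age conditioning.** Internally age enters as $(x - 840)/120$: centred
at age 70 and scaled per decade. This keeps the optimiser's coordinates
comparably scaled; all matrices and likelihoods are invariant to the
conditioning (a property the test suite checks by re-expressing the
intercepts under a shifted centre). `tidy()` also reports the age slope
per month of age for readers who prefer the natural scale.

**Supported ages.** Matrices are defined on ages 600–1320 months (50 to
110 years, configurable). Outside that range the linear predictor is
evaluated at the nearest boundary rather than extrapolated. The
clamping matters in exactly two places: the burn-in of the implied
prevalence, which starts below age 50, and nothing else in the default
pipeline.

**Numerical guards.** Softmax rows are computed with a max-shift, so
$\eta$ of $\pm 700$ neither overflows nor produces NaN; interval
probabilities are floored at $10^{-300}$ before taking logs, so a
structurally impossible observation surfaces as a finite, hugely negative
contribution that the optimiser can still rank.

## The interval-censored likelihood

An interview pair in states $(s_0, s_1)$ at ages $(x_0, x_1)$ contributes
$\log [M(x_0, x_1)]_{s_0 s_1}$, where $M(x_0, x_1)$ is the ordered
product of the monthly matrices at ages $x_0, \dots, x_1 - 1$. Missed
waves need no special handling: the pair just spans more months. A death
dated in month $x_d$ contributes

$$\log \sum_{j \in \{1,2\}} [M(x_0, x_d - 1)]_{s_0 j}\; p^{j3}(x_d - 1),$$

i.e. survival in some living state to the month before death, then death
within that month. A death dated in the same month as the last interview
is treated as a one-month pair, so no death interval has zero length.
Because interview dates are rounded to integer months on ingestion,
every interval is an exact number of elementary steps and no boundary
interpolation of the likelihood is needed; the month is the finest unit
consistent with how such surveys date interviews and deaths.

These products are implemented in C++ (as the established multistate
packages do for their likelihoods); the module surface — `monthly_matrix()`,
`interval_matrix()`, `pair_loglik()` — is plain R, and the test suite
checks the C++ path against brute-force enumeration over all intermediate
state sequences for horizons up to six months, against
Chapman–Kolmogorov splits, and against simulated outcome frequencies.

## Estimation

`fit_transitions()` maximises the pair log-likelihood with BFGS.
Intercepts start at crude per-month frequency logits (transition counts
divided by person-months at risk from each origin); slopes and covariate
effects start at zero. A second BFGS run from the optimum (which resets
the Hessian approximation) polishes the solution; the tests confirm that
the crude and all-zero initialisations agree to $10^{-4}$ in
log-likelihood and $10^{-3}$ in parameters on a standard fixture. The
convergence flag requires optim's convergence code 0 and a numerically
differenced gradient below $10^{-5} \times \max(1, |\ell|)$ — a relative
criterion, because with $|\ell| \sim 10^4$ an absolute gradient threshold
would sit below the noise floor of finite differences.

The covariance is the inverse of the observed information, computed by
symmetrised central second differences (step $10^{-4}$ on the conditioned
scale). A singular information matrix is reported as an unavailable
covariance with a diagnostic, not an exception, and non-convergence is a
flag on the result. `wald_test()` provides linear-contrast inference;
the duplication invariance ($\hat\theta$ unchanged, SEs shrink by
$\sqrt 2$) and 90–99% CI coverage across 100 replicate studies are part
of the acceptance tests.

## From kernel to life table

`occupancy_curve()` propagates a starting state forward month by month;
`state_expectancies()` integrates occupancy trapezoidally (half credit
for the first and last month) and divides by 12, giving years. Under a
constant monthly survival $s$ with no depression this convention has the
closed form $\mathrm{TLE} = \frac{1}{12}\left(\frac{s}{1-s} +
\frac12\right)$, which the tests require to $10^{-8}$ — that test pins
the integration convention, not just its implementation. The
microsimulation oracle applies the same half-credit weights path by path,
so it is an unbiased estimator of the analytic quantities and occupancy
is additive path by path.

**Closure.** The life table closes at age 110 (1320 months). Survivors
beyond closure are ignored; if their probability exceeds $10^{-6}$ a
leakage warning fires and the mass is recorded on the result. Standard
life-table practice; the generating parameters of the synthetic
population put the leakage near or below that threshold.

**Prevalence weighting.** Status-specific expectancies are combined as
$e^{\cdot j}(x) = (1 - \pi_2(x))\,e^{1j}(x) + \pi_2(x)\,e^{2j}(x)$.
Two prevalence sources are first-class: the *implied* period prevalence
of the fitted chain (the default — the cross-sectional distribution the
fitted rates themselves generate, which is the internally consistent
choice for period expectancies) and an *observed* prevalence table
supplied by the user, matching analyses that weight by the survey's
observed cross-section. The implied prevalence is computed by running
the living-state distribution forward from below age 50, renormalising
among the living each month. The burn-in starts at 600 months and is
doubled (up to 64-fold) until two extreme initialisations — everyone
depressed versus no one depressed — agree to $10^{-8}$ at every
requested age; if they never do, the point estimate errors. Bootstrap
parameter draws can be degenerate (an onset rate indistinguishable from
zero mixes arbitrarily slowly), so inside the bootstrap the
all-non-depressed initialisation is used as the fallback when the check
fails — the demographically natural starting distribution at adult ages.

**Uncertainty.** `life_table()` draws $B$ parameter vectors (default
500, minimum 100) from $N(\hat\theta, \hat\Sigma)$ and recomputes every
expectancy per draw; the SE is the draw standard deviation and the
default interval is the symmetric normal-theory one (percentile
intervals are an option). Within one fitted model the $z = 0$ and
$z = 1$ life tables built with the same seed share their draws, so
`marital_gap_table()` computes widowed-minus-married SEs from paired
draw-wise differences; across sexes the models are independent and
`sex_gap_table()` pools variances. Degenerate covariances collapse the
intervals to the point estimates, as they should.

## The synthetic population

The generator is a first-class module, not a test fixture: it defines
the study conditions under which every quantitative claim about the
package is validated.

| Parameter | Default | Emulates |
|---|---|---|
| waves | 4, spaced 24 months | biennial interviews over a 7-year window |
| entry ages | uniform 600–1080 months | a 50+ study population |
| wave jitter | integer months, SD 2 | irregular field periods (surveys do not document a jitter law; this is a nominal choice) |
| missed waves | 5% per non-first wave | intermittent non-response, producing long pairs |
| share female | 0.546 | the sex mix of such samples |
| share widowed | 0.23 | the marital mix after the study filters |
| CESD mode | `state` (or `items`) | item mode draws 8 binary items whose score reproduces the latent state with probability 1 (depressed: score 3–8; else 0–2) |
| deaths | exact month recorded | mortality-register linkage |

The true transition parameters (`example_params()`) were fixed once to
reproduce the qualitative regime reported for populations of this kind:
onset rising with age and roughly doubled by widowhood, recovery
declining with age, Gompertz-like mortality (log-hazard slope ≈ 1.1 per
decade) that is higher from the depressed state and higher for men, a
widowhood mortality penalty concentrated among men, and a widowhood
onset penalty larger for men. Under these values the implied depressed
prevalence at age 70 is about 13% for married women and 26% for widowed
women, total life expectancy at 50 is about 31 years for married women
and 29 for married men, and the female-minus-male gap in depression-free
life expectancy is several times larger among the widowed than among the
married — the pattern the pipeline's direction checks assert.

Entry states are drawn from the kernel's implied prevalence at the entry
age, which avoids initial-condition artifacts in recovery tests. Wave
jitter is truncated so consecutive interviews stay at least one month
apart, deliberately exercising the unequal-interval likelihood path.

What the generator does **not** emulate — and what green tests therefore
do not establish about real data: measurement error in the CESD
classification (items reproduce the latent state exactly), informative
missingness (waves are missed completely at random), sampling weights,
marital transitions during follow-up (the study design excludes those
individuals), and any violation of the Markov assumption such as
duration dependence in depression episodes.

## Validation sizes and budgets

The problem sizes in the test suite were chosen as the smallest that
make each check informative: parameter recovery and the acceptance
script use 5,000 persons × 4 waves (the scale at which all 24 parameters
are recovered within 3 SEs); coverage uses 100 replicate studies of 800
persons with 200 bootstrap draws each; microsimulation agreement uses
100,000 paths; the likelihood-vs-frequency check uses 50,000. The
coverage replicates are generated under a covariate-null truth, which
lets the same simulation verify CI coverage for all 12 parameters, TLE
bootstrap coverage, and the ~5% false-rejection rate of the covariate
Wald tests.

## Known limitations

- One binary time-constant covariate, as in the motivating design;
  multi-covariate or time-varying extensions would change the likelihood
  plumbing only, but are not implemented.
- No sampling weights and no multiple imputation of missing items; a
  record with any missing included CESD item has a missing state.
- The month grid is assumed exact; sub-month interview dates are rounded
  on ingestion rather than interpolated in the likelihood (the optional
  interpolation mode described for fractional intervals was not needed
  once dates are integer months, and is out of scope).
- Normal-theory bootstrap intervals can include implausible values when
  the fit is very noisy; percentile intervals are available.
- The false-rejection and coverage guarantees are Monte-Carlo statements
  at the validation sizes above, not finite-sample exactness claims.
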