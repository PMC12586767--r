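---
title: "Methods: cause-decomposed life tables for attributable mortality burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cause-decomposed life tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifedecomp)
```

## The model

`lifedecomp` estimates how much premature mortality (death before age 70)
in a high-risk cohort is attributable to competing exposures — in the
shipped configuration, tobacco smoking versus illegal drugs among people
who use illegal opioids. The inputs are aggregate: deaths $d_{a,c}$ and
person-years $T_a$ per single year of age $a \in \{18, \dots, 69\}$ and
cause category $c$. Six categories partition all deaths: smoking-specific
diseases (respiratory cancers and COPD), other cancers, cardiovascular
diseases, drug poisoning, viral hepatitis, and all other causes.

**Rate smoothing.** For each cause, and for all causes combined, the
death count is modelled as Poisson with a log link and person-time
offset,

$$d_a \sim \mathrm{Poisson}(m(a)\,T_a), \qquad
  \log m(a) = \beta_0 + \mathrm{ns}(a; 3\,\mathrm{df})\,\beta,$$

where $\mathrm{ns}$ is a natural cubic spline. A period life table
assumes these cross-sectional rates persist over a lifetime; smoothing
borrows strength across neighbouring ages where single-year counts are
noisy.

**Life table.** A closed cohort of 100 000 starts at exact age 18.
Within each one-year interval the hazard is constant, so the death
probability is $q_a = 1 - e^{-m_{\mathrm{all}}(a)}$. Deaths are split
across causes in the ratio of the modelled cause-specific rates, which
defines additive cause hazards
$h_{a,c} = m_{\mathrm{all}}(a)\, m_c(a) / \sum_c m_c(a)$.

**Attribution.** An attribution map gives $AF_{e,c}$, the fraction of
cause $c$'s deaths attributable to exposure $e$. Defaults: drug poisoning
and viral hepatitis 1.0 to illegal drugs; respiratory cancer/COPD 1.0,
cardiovascular 0.5 and other cancers 0.3 to tobacco. These are external
epidemiological assumptions, not estimates, and results are sensitive to
them; the map is config-driven so variants (for example adding a
stimulant effect on cardiovascular deaths) need no code change.

**Counterfactuals.** Eliminating a set $E$ of exposures scales each
cause hazard by $1 - \sum_{e \in E} AF_{e,c}$ and rebuilds the life
table. Survivors of the removed causes remain exposed to everything else,
so the net risk reduction is smaller than the eliminated bucket —
competing risks. This models *never-exposure*, not cessation: no taper of
risk after quitting is attempted.

**Burden measures.** Risk of premature death is total life-table deaths
over the radix. A death in $[a, a+1)$ is timed at the interval midpoint,
losing $70 - a - 0.5$ years of life (so a death at 69 loses 0.5 years, at
68 loses 1.5). Both measures decompose exactly into exposure buckets plus
a remainder ("others").

**Attribution after elimination.** In a counterfactual table the
eliminated exposure's fractions are zero — its attributable hazard is
exactly what was removed — and a surviving exposure's fraction of the
*remaining* hazard rescales to $AF_{e',c} / (1 - \sum_{e \in E}
AF_{e,c})$ (`counterfactual_attribution()`). This keeps two invariants
that any coherent reading must satisfy: the eliminated bucket is exactly
zero, and no surviving bucket shrinks when a competing exposure is
removed.

**Uncertainty.** Confidence intervals come from parametric Monte-Carlo:
every observed count $d_{a,c}$ is replaced by a
$\mathrm{Poisson}(d_{a,c})$ draw (person-years fixed — they are
denominators, not random), the full pipeline reruns, and the 0.025/0.975
empirical quantiles over 1000 replicates form the 95% CI. Counts are
resampled per (age, cause) independently, before smoothing.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| spline degrees of freedom | 3 | basis columns | flexible enough for one mode or plateau over 52 ages, stiff enough for sparse tails |
| boundary knots | 18, 69 | years | the modelled range |
| interior knots | person-year-weighted age terciles | years | knots where the data are |
| radix | 100 000 | persons | presentation scale only; results are radix-invariant |
| horizon | 70 | years | definition of "premature"; fixed to the age range |
| hazard→probability | $1-e^{-m}$ | — | exact under piecewise-constant hazards; `actuarial` ($m/(1+m/2)$) available for sensitivity |
| Monte-Carlo draws | 1000 | replicates | quantile noise well below reporting precision |
| IRLS control | tol $10^{-8}$, 100 iter | — | standard GLM convergence |

## The synthetic world

Real cohort-level inputs of this kind come from linked primary-care and
death-registry records and cannot ship with a package. The generator
builds worlds with the statistical structure the analysis assumes:

* death counts Poisson given age-specific hazards and a person-years
  schedule;
* four hazard shapes — constant; log-linear (Gompertz-like, for the
  monotone disease causes, slopes 0.075–0.085/year); log-quadratic
  unimodal (drug poisoning, peak at 47); logistic-plateau in the rate
  (hepatitis, midpoint 48, steepness 0.25, near its plateau by 58);
* a right-skewed person-years profile: lognormal entry age (median 35.1)
  convolved with gamma follow-up (median 8.7 years), 1 million
  person-years in total.

Cause levels are calibrated so expected premature deaths per cause equal
the totals of the cohort being emulated (4373 drug poisoning, 1179
respiratory cancer/COPD, 1168 other cancers, 1101 cardiovascular, 303
viral hepatitis, 4886 other; 13 010 in all). `reference_counts()`
freezes the expected counts into a deterministic table (largest-remainder
rounding preserves the totals exactly); `generate_counts()` adds Poisson
noise under a caller seed.

Everything above is an *input-side* calibration. The resulting
premature-death risk (51.9% in the default world) is an output and was
never tuned; published headline results of the emulated cohort (63.2%
risk, etc.) differ from the synthetic world's, as they must, since the
world fixes only marginal totals and qualitative shapes, not the joint
age-by-cause surface. A green test on this world therefore establishes
that the *machinery* is correct (conservation, apportionment,
competing-risks accounting, CI coverage), not that any real cohort's
numbers are reproduced. Features of real data deliberately not emulated:
calendar-time trends (e.g. hepatitis C treatment scale-up), covariates
other than age, and between-cause correlation beyond shared person-years.

## Numerical choices

* Weighted knot quantiles interpolate the cumulative person-year weights
  at their midpoints; degenerate weights collapse to fewer knots.
* Ages with zero person-years are excluded from the likelihood but still
  receive predictions (the spline extrapolates linearly beyond the
  boundary knots, a property of the natural basis).
* A cause with zero total deaths returns a flat near-zero curve
  ($10^{-12}$/year) with a warning flag rather than failing: the Poisson
  MLE is degenerate at $-\infty$ on the log scale.
* Additivity of independently fitted curves is checked, not assumed:
  `check_rate_consistency()` reports the maximum relative gap between the
  summed cause curves and the all-cause curve. In the default synthetic
  world the gap is 0.054, concentrated at the boundary ages where the
  natural spline's end-constraints bind hardest; apportionment against
  the all-cause model makes the life-table hazards additive regardless.
* Monte-Carlo quantiles use linear interpolation between order statistics
  (R type 7), applied uniformly; at 1000 replicates the choice of rule
  moves bounds by well under 0.1 percentage points.
* One master seed draws one sub-seed per simulation, so results are
  independent of loop chunking; all generator randomness is local and
  restores the caller's RNG state.

## Design decisions that were genuinely open

* **Governing hazard.** Whether the life table should follow the fitted
  all-cause curve or the sum of the cause curves is undetermined by the
  method's description; we use the all-cause fit and apportion it, which
  bounds the impact of the choice by the additivity gap and keeps
  counterfactual hazard arithmetic exact.
* **Elimination without refitting.** Scenarios transform the fitted
  hazards rather than refitting models to thinned counts: elimination is
  a deterministic function of one fitted model, which keeps scenario
  differences free of refitting noise and matches the never-exposed
  interpretation.
* **Independent per-cause resampling.** The alternative — resampling
  all-cause counts and reallocating — would induce negative dependence
  between causes; independent Poisson draws per (age, cause) follow
  directly from treating each cell as a Poisson count.

## Known limitations

* The spline family cannot represent every hazard shape: the
  logistic-plateau curve's deep lower tail (log-rate strongly convex) and
  the log-quadratic curve at the boundary knots are approximated with
  relative errors that can be large exactly where absolute rates are
  negligible. Parameter-recovery guarantees in the tests are therefore
  stated for spline-representable shapes and for well-observed ages.
* Attributable fractions are assumptions with no sampling uncertainty
  attached; the Monte-Carlo intervals reflect count noise only.
* The period interpretation assumes today's age-specific rates persist;
  cohort effects (drug-market changes, antiviral roll-out) are folded
  into the age pattern.
* Truncation at 70 means "premature" is a definition, not a discovery;
  nothing is said about mortality beyond the horizon.
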