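# lifedecomp

Cause-decomposed period life tables for attributable mortality burden.

## The problem

Cohorts of people who use illegal opioids die young, and they die of two
broad families of causes: the direct toll of the drugs (poisoning
overdoses, blood-borne viral hepatitis) and the slower toll of tobacco,
which almost all of this population smokes (respiratory cancers and COPD,
and parts of cardiovascular disease and other cancers). Quantifying which
exposure causes more premature death in the *same* cohort is a
competing-risks question: preventing an overdose at 35 leaves a person
exposed to lung cancer at 60, so cause-specific death counts alone
mislead.

`lifedecomp` answers it with a multiple-decrement period life table:

1. **Rates.** From aggregate data — deaths `d(a, c)` and person-years
   `T(a)` per single year of age `a` (18–69) and cause category `c` — fit,
   for each cause and for all causes combined, a Poisson regression

   `d(a) ~ Poisson(m(a) T(a))`, `log m(a) = β₀ + ns(a; 3 df) β`

   where `ns` is a natural cubic spline (boundary knots 18 and 69,
   interior knots at person-year-weighted age terciles).

2. **Life table.** A closed cohort of 100 000 walks from exact age 18 to
   70 under the modelled all-cause hazard, `q(a) = 1 − exp(−m_all(a))`;
   deaths in each interval are split across causes in the ratio of the
   modelled cause-specific rates, giving additive cause hazards
   `h(a, c) = m_all(a) · m(a,c) / Σ_c m(a,c)`.

3. **Attribution.** Attributable fractions map causes to exposures
   (shipped defaults: drug poisoning and viral hepatitis 100% to illegal
   drugs; respiratory cancer/COPD 100%, cardiovascular 50% and other
   cancers 30% to tobacco). Each bucket's risk of death before 70 and
   mean years-of-life lost (YLL; a death in `[a, a+1)` loses
   `70 − a − 0.5` years) follow by summation.

4. **Scenarios.** Eliminating an exposure scales each cause's hazard by
   `1 − AF` and rebuilds the life table, so survivors remain at risk of
   everything else (competing risks handled by construction).

5. **Uncertainty.** 95% CIs by Monte-Carlo: every death count is replaced
   by a Poisson draw with the observed count as mean, the whole pipeline
   reruns (default 1000 times), and the 0.025/0.975 quantiles are
   reported.

## Worked example

```r
library(lifedecomp)

table  <- reference_counts()          # deterministic synthetic cohort
curves <- fit_all(table)              # 6 cause models + all-cause model
check_rate_consistency(curves)        # additivity gap of the fits
#> [1] 0.05397747

lt <- build_life_table(cause_curves = apportion_hazards(curves))
print(lt)
#> life_table: radix 100 000, ages 18-69, 6 causes
#>   risk of death before 70: 51.9%; mean YLL 11.19 years

attribute_burden(lt, default_attribution())
#> burden_summary 'baseline' (horizon 70)
#>   risk of premature death: 51.9%; mean YLL: 11.19 years
#>   illegal_drugs  risk  16.8% (32.3% of deaths)  YLL  4.27 (38.2%)
#>   tobacco        risk   9.5% (18.3% of deaths)  YLL  1.28 (11.4%)
#>   others         risk  25.6% (49.4% of deaths)  YLL  5.64 (50.4%)

no_drugs <- run_scenario(table, spec = scenario_spec("no_drugs", "illegal_drugs"))
no_drugs$risk_total
#> [1] 0.3998496
```

Read this as: in the default synthetic world, 51.9% of the cohort dies
before 70; about a third of those deaths (and 4.3 of the 11.2 mean YLL)
are attributable to illegal drugs. Eliminating drugs cuts the risk to
40.0% — less than the 16.8-point drug-attributable share, because people
saved from overdose remain exposed to the other causes.

Confidence intervals and a full file bundle:

```r
ci <- monte_carlo(table, n_sims = 1000, seed = 1)
ci_for(ci, "baseline.risk.total")
#>     point     lower     upper
#> 0.5185802 0.5111817 0.5259434

run_pipeline(pipeline_config(output_dir = "out", n_sims = 1000, seed = 1))
```

A command-line interface with verbs `simulate`, `fit`, `run`, `ci` and
`report` ships at `inst/cli/lifedecomp`.

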