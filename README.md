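# claimscreen

Statistical fraud screening for daily COVID-19 antigen-test billing claims.

Reimbursement-per-test schemes gave test centres an incentive to inflate,
fabricate or round their reported test counts and to suppress positive
results. Health authorities traditionally find such centres through
complaints, whistleblowers and sporadic inspections. `claimscreen`
implements a systematic alternative that needs only the daily billing
stream — per centre and day: category (pharmacy, doctor's/dentist's office,
private test centre), tests invoiced, positives — and screens every centre
with four detectors:

1. **High volume** — mean daily tests beyond the 90th percentile of the
   centre's category (top `ceil(0.10·n)` per category).
2. **Low positivity** — a Poisson regression of daily positives with offset
   `log(tests)`, crossed random intercepts for centre *j* and calendar week
   *k*, and category as fixed effect,
   `log μ_jk = log(tests) + β₀ + β_cat + u_j + v_k`;
   a centre is flagged when its empirical-Bayes intercept is significantly
   low, `û_j/se(û_j) < Φ⁻¹(α)` (one-sided, α = 0.05).
3. **Benford leading digits** — per-centre chi-squared of the leading-digit
   histogram of daily counts against `p_d = log10(1 + 1/d)`; top decile of
   centres with ≥ 30 active days.
4. **Uniform last digits** — the same rule against the uniform expectation
   on final digits 0–9 (excess 0s/5s betray rounding).

A centre is *statistically conspicuous* when at least one — or, more
conservatively, at least two — detectors fire. Against external labels the
package computes the agreement metrics of the screening literature:
positive overlap `a/(a+b)` (sensitivity analogue), negative overlap
`d/(c+d)` (specificity analogue), incremental share `c/(c+d)`, and the
incremental predictive validity — among flagged centres, the share that
were not previously suspected and whose fraud suspicion was corroborated by
subsequent investigation.

Because real billing data of this kind are confidential, the package
includes a synthetic claims generator (`simulation_config()`,
`simulate_claims()`) with category-calibrated volumes, a weekly positivity
curve near 2%, heterogeneous centre lifetimes, four injectable fraud
behaviours and imperfect suspicion/corroboration labels, so the full
pipeline runs end to end with known ground truth.

## Worked example

```r
library(claimscreen)

cfg <- simulation_config()            # 907 centres, 73 weeks, ~2% positivity
sim <- simulate_claims(cfg, seed = 7)
labels <- sim$truth[c("centre_id", "suspected_conventional", "corroborated")]
res <- run_pipeline(sim$claims, labels = labels)
print(res)
#> fraud-screening pipeline result
#>   high_volume      91 flagged /  907 eligible /  907 centres
#>   low_positivity  231 flagged /  907 eligible /  907 centres
#>   benford          75 flagged /  749 eligible /  907 centres
#>   last_digit       75 flagged /  749 eligible /  907 centres
#>   any_method      362 flagged /  907 eligible /  907 centres
#>   at_least_2       99 flagged /  907 eligible /  907 centres
```

91 = `ceil(0.10·60) + ceil(0.10·390) + ceil(0.10·457)` centres are beyond
their category's 90th volume percentile; 749 of the 907 centres billed on
at least 30 days and are eligible for the digit screens, of which the top
decile (75) is flagged. The fitted mixed model reports its variance
components — the centre-level spread of log positivity (σ_u) and the
week-level epidemic variation (σ_v):

```r
print(res$positivity_fit)
#> Poisson positivity model: 104378 rows, 907 centres
#>   sigma_u (centre) = 0.4002, sigma_v (week) = 0.3431
#>   fixed effects:
#>      (Intercept) categorypharmacy  categoryprivate
#>          -3.8635          -0.0284           0.0087
```

(`exp(-3.86) ≈ 2.1%` baseline positivity for the reference category.)
Evaluating the conservative at-least-two combination against the simulated
conventional-suspicion and corroboration labels:

```r
print(res$evaluation$at_least_2$agreement)
#>               conspicuous not conspicuous
#> suspected              36              90
#> not suspected          63             718
print(res$evaluation$at_least_2$overlap)
#> positive overlap 28.6%, negative overlap 91.9%, incremental share 8.1%
print(res$evaluation$at_least_2$validity)
#> conspicuous 99: already suspected 36, new corroborated 25,
#>   new not corroborated 38 (incremental predictive validity 25.3%)
```

So 28.6% of conventionally suspected centres were also flagged by at least
two statistical methods, 8.1% of unsuspected centres were newly flagged,
and a quarter of all flagged centres were both new and subsequently
corroborated. Flags are screening signals to prioritise investigation,
never evidence of fraud.

The methods vignette (`vignettes/fraud-screening.Rmd`) documents the model,
the generator's calibration and the package's design decisions. A thin CLI
(`inst/cli/claimscreen.R`) exposes `simulate` / `detect` / `evaluate` /
`run` subcommands over the same functions.

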