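---
title: "Statistical screening of antigen-test billing claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical screening of antigen-test billing claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(claimscreen)
```

## The problem

During the COVID-19 pandemic, rapid-antigen test centres were reimbursed
from public funds per reported test, which created an incentive to inflate
test counts, fabricate them outright, or suppress positive results (a
positive test triggered follow-up obligations that made repeat business less
likely). Health authorities traditionally relied on sporadic, labour-intensive
signals — complaints, whistleblowers, on-site inspections, police
investigations — to decide which centres to investigate.

`claimscreen` implements a systematic statistical alternative that needs
only the daily billing stream: per centre and day, the centre category
(pharmacy, doctor's/dentist's office, private test centre), the number of
tests invoiced and the number of positives. Four detectors each produce a
per-centre flag; a centre is *statistically conspicuous* when at least one
(or, more conservatively, at least two) of them fire. Because real billing
data of this kind are confidential, the package ships a synthetic claims
generator with injectable fraud behaviours, so every stage is testable end
to end with known ground truth.

## The four detectors

**High volume.** Within each centre category, centres are ranked by mean
invoiced tests per active day; the top `ceil(0.10 * n)` are flagged (the
centres beyond the category's 90th percentile). Stratification matters:
pharmacies, medical practices and private centres operate at very different
scales, and an unstratified rule would flag only private centres.

**Low positivity.** Daily positive counts are modelled by a Poisson
regression with a log link and an offset of log daily tests, so the linear
predictor describes the positive *rate*:

$$\log \mu_{jk} = \log(\text{tests}_{jk}) + \beta_0 + \beta_{\text{cat}}
  + u_j + v_k, \qquad
  u_j \sim N(0, \sigma_u^2), \; v_k \sim N(0, \sigma_v^2),$$

with crossed random intercepts for centre $j$ and calendar week $k$ (weeks
absorb the epidemic's changing incidence; centre category is a fixed
effect). A centre's intercept $u_j$ is its deviation of log positivity from
the category mean; a centre is flagged when its empirical-Bayes conditional
mode is significantly low, $\hat u_j / \mathrm{se}(\hat u_j) < \Phi^{-1}(\alpha)$,
by default at $\alpha = 0.05$ one-sided. The model is fitted with
`lme4::glmer()` under the Laplace approximation — adaptive quadrature is
unavailable for crossed designs, and on small single-factor designs we have
verified the Laplace variance estimate against a mode-centred 50-node
Gauss–Hermite integration of the marginal likelihood to three decimals.

**Benford leading digits.** Daily test counts of an honest centre with
widely varying volumes have leading digits approximately distributed as
$p_d = \log_{10}(1 + 1/d)$ (about 30% ones, about 5% nines). Each centre
with at least 30 active days is scored by the Pearson chi-squared statistic
of its leading-digit histogram against this expectation, and the top decile
of eligible centres is flagged. Fabricated counts drawn from a narrow band
concentrate their leading digits and score extreme values.

**Uniform last digits.** True counts' final digits are close to uniform on
0–9; counts rounded to multiples of 5 or 10 are not. The same
30-day/top-decile rule is applied to the last-digit histogram against the
uniform expectation.

The chi-squared statistics are used as *ranking scores*, not calibrated
p-values: no small-expected-count correction is applied, and the flagged
fraction is fixed at the configured decile rather than derived from a
reference distribution.

## Outcome metrics

Against an external per-centre suspicion label (the conventional process),
the package computes from the 2×2 agreement table $(a, b, c, d)$:

* positive overlap $= a/(a+b) \times 100$ — the sensitivity analogue;
* negative overlap $= d/(c+d) \times 100$ — the specificity analogue;
* incremental share $= c/(c+d) \times 100 = 100 -$ negative overlap —
  conspicuous centres the conventional process missed.

Where a corroboration label is available (the outcome of a subsequent
investigation), `predictive_validity()` partitions the flagged centres into
already-suspected / newly-corroborated / newly-not-corroborated and reports
the newly-corroborated share of all flagged centres. Percentages are
rounded half away from zero to one decimal for reporting; exact fractions
are retained in the `*_raw` fields.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `quantile_level` (volume) | 0.90 | category-wise 90th-percentile outlier rule |
| `positivity_alpha` | 0.05 | one-sided EB z-test level; the flagging rule is an explicit package convention, exposed so alternatives (quantiles of $\hat u_j$, likelihood-ratio tests) can replace it |
| `min_active_days` (digits) | 30 | below ~30 daily values a digit histogram is uninterpretable |
| `flag_fraction` (digits) | 0.10 | top decile of eligible centres |
| `combine_k` | 2 | at-least-two combination; the most efficient use of limited investigative capacity |

Two conventions are deliberate and documented rather than inherited:
the "top 10%" rules are implemented as *count* rules,
`ceil(fraction × n_eligible)` with ties broken by (score descending,
centre id ascending) — an interpolated quantile threshold does not yield
reproducible flag counts under ties — and digit-screen eligibility counts
only days with at least one invoiced test, since a zero has no digits and
contributes no information.

## The synthetic claims generator

`simulation_config()` encodes the study conditions the package is tested
under: 60 pharmacies, 390 practices and 457 private centres over a 508-day
(73-week) window; per-category daily volumes that are discretised
log-normal with medians near 64 / 5 / 115 tests per day and centre-level
spreads (0.6 / 1.5 / 0.6 on the natural-log scale) calibrated so the
combined centre-plus-day spread reproduces the corresponding mean/median
ratios (108/64, 21/5, 194/115) — the practice category is genuinely the
most heterogeneous; a weekly positivity curve that is sinusoidal on the
logit scale around 2%; centre positivity offsets with sd 0.3 on the logit
scale; and centre lifetimes that are log-normal (median 220 days, log-sd
1.2) with uniform start dates and per-centre opening probabilities in
0.4–1, which yields a realistic share of centres billing on fewer than 30
days. A log-normal rather than Poisson volume model is essential: real
daily volumes are heavily over-dispersed (1 to tens of thousands), and the
heavy right tail is what makes honest leading digits approach Benford.

Fraud behaviours are injected per centre, each with 5% prevalence by
default: volume inflation (×3) scales the expected volume before the daily
draw; fabrication replaces the draw with a uniform integer in 480–520;
digit rounding snaps the final count to the nearest multiple of 5; rounding
is applied after inflation and fabrication so that it controls the last
digit; positivity suppression multiplies the daily positive probability by
0.3. Effect sizes are config knobs — the available public record gives no
quantitative description of fraudulent behaviour, so the defaults are
chosen once to be plausible and to make the behaviours separable.
Suspicion and corroboration labels come from a two-coin misclassification
model (P(suspected | fraud) = 0.5, P(suspected | honest) = 0.05,
P(corroborated | fraud) = 0.8, P(corroborated | honest) = 0.1), so
agreement tables are imperfect in the way real ones are.

Randomness uses one root seed with per-centre derived substreams, so adding
centres to a configuration never changes the draws of existing centres, and
identical configurations produce byte-identical claims files.

What the generator does **not** emulate: spatial structure, opening hours,
day-of-week or holiday effects, centres changing behaviour mid-stream,
correlated fraud across centres, and reporting artefacts of the real
portal. Passing tests therefore demonstrate that the detectors recover the
behaviours they target under the stated noise model — not that they would
achieve the same operating characteristics on real billing data.

## Numerical and design choices

* **Zero-test days** are kept in the claims table but dropped from the
  positivity model (log 0 offset) and from digit histograms, means and
  active-day counts.
* **Duplicate (centre, date) rows are a hard error**, not summed: duplicate
  billing rows are themselves a fraud signal and must surface to the
  analyst.
* **Calendar weeks** are consecutive 7-day blocks anchored at the study
  window's start (not ISO weeks); the reference window 2021-04-08 to
  2022-08-28 spans exactly weeks 1..73.
* **Missing suspicion labels** (e.g. pharmacies supervised by a different
  authority) are treated as not-suspected by default, which reproduces
  published margin conventions; `missing_label_policy = "exclude"` drops
  them and reports the exclusion count.
* **Reference category** for the fixed effect is `practice`; arbitrary and
  documented.
* **Boundary variance estimates** ($\hat\sigma \approx 0$) produce a
  warning, not an error; a non-converged mixed model aborts the detector,
  and `run_pipeline()` then degrades to a three-detector run with a
  prominent warning.
* **Low-variance centres** (fewer than 5 distinct daily values) get a
  diagnostic mark on the digit screens rather than being excluded: constant
  reporting is a known limitation of digit forensics, but also itself a
  suspicious pattern.

## Calibration checks and problem sizes

The test suite validates the statistical behaviour at sizes chosen to keep
a full run in tens of seconds while leaving the conclusions stable across
seeds:

* *Variance recovery*: 300 centres × 50 weeks × 3 active days/week
  (45,000 rows) with $\sigma_u = 0.5$, $\sigma_v = 0.3$; both are recovered
  within ±0.1.
* *Null calibration*: with no fraud and homogeneous centres
  (`centre_pos_sd = 0`), the low-positivity flag rate stays below
  $\alpha$ plus twice its Monte-Carlo error. With real centre
  heterogeneity the EB z-test flags genuinely low centres at a higher
  rate — that is the method working as designed, not a false-positive
  excess, and it is why the detector reports *conspicuousness*, not fraud.
* *Benford calibration*: honest centres whose day-level spread is wide
  (log10-sd 0.8) and who are active ≥ 300 days exceed the 0.95 quantile of
  $\chi^2_8$ about 5% of the time. At the generator's realistic default
  day-level spread (natural-log sd 0.8) honest centres deviate measurably
  from Benford — mirroring the variance prerequisite that limits digit
  forensics on real low-variance data.
* *Detector enrichment*: in a controlled single-category cohort of 400
  long-lived centres with strong effect sizes (inflation ×8, the other
  behaviours at their defaults), each behaviour is recovered by its matched
  detector with recall ≥ 0.7. The controlled design is deliberate: in the
  full three-category mixture, the practice category's honest heterogeneity
  and short-lived (ineligible) centres confound *attribution*, which is a
  property of the screening problem, not of the implementation.

## Known limitations

The low-positivity detector cannot distinguish suppression from honestly
low positivity (e.g. a centre serving a low-incidence clientele); the digit
screens have no power against fraud that preserves digit distributions; the
volume screen always flags a fixed fraction of every category regardless of
whether any fraud is present. All flags are screening signals intended to
prioritise investigation, never evidence of fraud.
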