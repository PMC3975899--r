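---
title: "Methods: static microsimulation of the economic costs of early retirement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: static microsimulation of the economic costs of early retirement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retiresim)
```

## The problem

When a chronic condition such as diabetes forces people out of the labour
force before retirement age, the costs fall on the individual (lost earnings)
and on government (lost income-tax revenue, extra welfare payments, lost
national output). Quantifying these costs for a national population requires
person-level data that combine health, labour-force and detailed economic
information — data that in practice live in different sources. The standard
solution is a static microsimulation: take a nationally representative health
survey as the base population, reweight it to the reference year, impute
detailed economics from a second source by statistical matching, and then run
counterfactual analyses on the fused file.

`retiresim` implements this pipeline end to end for the population aged
45–64, with diabetes as the bundled condition of interest and 2010 Australia
as the bundled reference setting. Because the original unit-record inputs
(a national disability survey and a dynamic microsimulation snapshot) are
confidential, the package also contains a first-class synthetic-data
generator that emulates their statistical structure; every downstream stage
runs end-to-end on generator output with no external file.

## Stage 1: synthetic survey and donor populations

A `population_spec()` fully determines both generated datasets. The bundled
default encodes the study conditions:

* **Groups and sizes.** Seven labour-force/condition groups. The five
  analysis groups use the published record counts and weighted sizes
  (full-time employed with no chronic condition: 6,606 records / 1,413,511
  persons; part-time no condition: 2,373 / 467,796; full-time with diabetes:
  345 / 88,889; part-time with diabetes: 105 / 25,329; out of the labour
  force due to diabetes: 46 / 11,310). The unemployed and other-NILF groups
  are not tabulated in the source study; their sizes (300 records / 80,000
  persons and 2,000 / 600,000) were chosen once as realistic for the 2010
  Australian 45–64 population so that counterfactual-employment calculations
  have a complete labour-force denominator. They are not revisited.
* **Income.** Log-normal per group. The location ties the group median to
  the published median annual income; the scale comes from the published
  SD/mean ratio via `sdlog = sqrt(log(1 + CV^2))`. Log-normal is the minimal
  right-skewed family consistent with the reported mean > median pattern.
  A common set of small log-scale covariate effects (age group, sex,
  education; centred against the population-average covariate mix so group
  medians stay anchored) makes income covariate-dependent, which is what
  gives the adjusted regression something to adjust for.
* **Welfare.** A point mass at zero plus a log-normal positive part. For
  employed groups (published median 0) the positive part is moment-matched to
  the group mean and SD given a default zero mass of 0.65–0.80. For the
  early-retiree group (median AU$986 > 0) the zero mass is 0.25 and the
  location and scale are solved so the mixture median and mean both match;
  the implied SD is then larger than the published one — a single log-normal
  cannot match all three moments of so skewed a distribution, and we
  prioritise the median (the headline descriptive) and the mean (which
  drives totals).
* **Tax.** Computed from income through a configurable piecewise-linear
  marginal schedule, defaulting to 2010-era Australian brackets with a 1.5%
  levy folded into the rates. The source study reports only resulting
  liabilities, never the schedule, so the default is an approximation; it
  guarantees `tax <= income` and monotonicity by construction.
* **Hours bands.** `1–15, 16–24, 25–34, 35–40, 41+` partition weekly hours;
  non-employed records carry the sentinel `"none"`. (A published variant
  listing a "26–24" band is treated as a typographical error for 16–24,
  since the bands must partition.)
* **Income quintiles** are derived from a latent (survey) or actual (donor)
  income draw using configurable band edges (default 0 / 16k / 30k / 48k /
  70k / Inf AU$), which keeps the quintile consistent with the income
  ordering on both sides of the match. The original survey's band boundaries
  are not published, hence config-driven.

Design weights are jittered uniformly (±20%) around `pop_size/sample_size`
and renormalised within group so each group's weighted total is exact before
calibration. Everything is reproducible from `spec$seed`.

**What the generator does *not* emulate:** survey design effects
(clustering, stratification, non-response adjustment), confidentialisation
perturbation, within-household correlation, and the donor model's dynamic
ageing. Tests passing on generator output therefore validate the pipeline's
algorithms and their contracts, not the published point estimates, which
depended on the confidential inputs.

## Stage 2: weight calibration (bounded GREG)

`calibrate_weights()` adjusts design weights `d` to weights `w` hitting
benchmark totals: minimise the chi-squared distance
`sum((w_i - d_i)^2 / (2 d_i))` subject to `X'w = T`, where `X` holds cell
indicators for one or more margins. The unconstrained solution is the
generalized-regression form `w = d (1 + x'lambda)` with `lambda` solved from
the weighted cross-product equations; bounds `w/d` in `[L, U]` (default
0.3–3.0, the common production setting) are enforced by
truncate-and-resolve: weights hitting a bound are fixed there and the
regression is re-solved on the rest, up to `max_iter = 50` iterations, with
the maximum relative constraint violation reported even on non-convergence.
Rank-deficient constraint systems (overlapping margins always share the
population total) are handled with a pseudoinverse. A record in no benchmark
cell passes through unchanged with a warning.

The 2003/2009 pooled survey file is treated as a single frame reweighted to
the 2010 population; the default benchmark margins are the group totals plus
age-by-sex. Tests check the implementation against an independent oracle
that solves the full Karush–Kuhn–Tucker block system of the same quadratic
program.

## Stage 3: synthetic matching

Detailed income, welfare and tax are copied onto each survey record from a
donor record agreeing on ten categorical matching variables: labour force
status (4 levels), income-unit type (4), income quintile (5), age-pension
receipt (2), disability-pension receipt (2), sex (2), age group (4), hours
band (5), education (2), home ownership (2) — a key space of 51,200 cells.
When a record's full ten-variable cell has no donors, variables are relaxed
one at a time from the end of a configurable priority list (default: the
listing order above, so labour force status — the analysis axis — is never
dropped). Ties are broken uniformly at random under a stated seed, donors
are reused with replacement (the donor pool need not exceed the recipient
count), and a record unmatched even on labour force status alone is a hard
error. The match report records per-record relaxation depth and pool size
plus the exact-match rate. With the default 20,000 donors, the exact-match
rate on the default survey is about 93%.

## Stage 4: descriptives and adjusted group differences

Weighted descriptives use `weighted_mean`, a weighted population-form SD and
the weighted median convention *smallest value whose cumulative weight
reaches half the total weight* (documented and tested by enumeration; with
values 10, 20, 30 and weights 1, 1, 2 it returns 20).

Group differences come from ordinary least squares on `log(y + offset)` with
main-effect dummies for group, age group, sex and education — no
interactions — with full-time employed, no chronic condition as the
reference. A coefficient `b` with standard error `se` is reported as a
percent difference `(exp(b) - 1) * 100` with 95% CI
`(exp(b ± 1.96 se) - 1) * 100`; the normal multiplier reflects the large
samples this design targets. Offsets: 0 for income (the generator guarantees
income ≥ 1) and 1 AU$ for welfare and tax, which have legitimate zeros; how
the original analysis handled zeros is not stated, so the choice is an
explicit, isolated parameter. The regression is unweighted on person records
by default (weights enter descriptives and national totals only), with a
weighted-least-squares switch, since the original weighting treatment is
also unstated. `model_diagnostics()` provides advisory residual-normality
(Shapiro–Wilk to n = 5000, Anderson–Darling beyond) and Breusch–Pagan
checks, flagging a zero-residual fit as degenerate.

All monetary quantities are treated as annual AU$; a published table caption
mentions weekly amounts, but the modelled quantities are annual and the
package follows the annual interpretation throughout.

## Stage 5: national impact and sensitivity

For each person out of the labour force due to the condition, the
counterfactual assumes they would have faced the same full-time /
part-time / non-employment split as the no-chronic-condition reference
population (computed from calibrated weights, or supplied directly). The
counterfactual outcome is the mixture, over those three states, of the
covariate-adjusted median-scale prediction `exp(x'beta)` in the two employed
states (a median predictor, consistent with interpreting the log-model
coefficients as percent differences; no smearing correction) and the
person's actual value in the non-employed state. Per-record losses are
`counterfactual − actual`, floored at zero for income and tax; the welfare
difference is sign-flipped into "extra welfare". National totals are
weight-summed and reported in AU$ million, with rounding (money to 0.1
AU$M, persons to integers) applied only at reporting, never mid-pipeline.

GDP loss values the removed workers through the output identity
`GDP = GDP/H × H/EMP × EMP/LF × LF/Pop15+ × Pop15+` in its marginal form
`dGDP = GDP/H × H/EMP × n`, holding productivity and hours fixed; this
equals the difference form exactly (GDP depends on employment only through
the product), and the second-order participation-rate feedback is dropped.
The default `gdp_parameters()` (AU$68.5/hour, 1,710 hours/worker/year,
employment rate 0.948, participation rate 0.657, 17.8M adults) are
**illustrative 2010-era assumptions** — the hourly-productivity and
average-hours components were not published alongside the study estimates —
and should be replaced with official aggregates for any substantive use.

The preventable-fraction scenario multiplies the person count and every
monetary total by the fraction of cases with the preventable (Type 2) form
of the condition, 0.89 for ages 40–59 by default. Applied to rounded base
figures this reproduces the published sensitivity row exactly for persons,
income, welfare and tax; for GDP, scaling the rounded base of AU$1,324M
gives 1,178.4, i.e. within AU$1M of the published 1,179 (which was scaled
from an unrounded base) — a documented rounding gap, not a defect.

## Parameter recovery and what the tests show

`population_spec_from_effects()` builds a generating world in which the
group effects on log income are known exactly: group locations are
`log(54,795) + log(1 + pct/100)` with the bundled adjusted percent
differences (−56.3, −6.5, −52.4, −88.3), and the log-income scale is common
to all groups (the reference group's 0.52). The common scale matches the
homoscedasticity assumption of the fitted regression — the original analysis
reports that its diagnostics confirmed the model assumptions — and is what
makes nominal CI coverage a meaningful check; with group-specific scales the
pooled-variance CIs for the smallest group are anti-conservative, which is a
property of OLS, not of this pipeline. The default spec keeps the
group-specific scales for descriptive realism.

The recovery study (100 replicates of 10,000 records, regression on the five
analysis groups) recovers the early-retiree income effect to within a
fraction of a percentage point on average (e.g. −88.1 vs −88.3 generating,
seed 1) with CI coverage at the nominal rate. Problem sizes throughout the
test suite (10,000-record populations, 20-record calibration instances,
5-donor matching fixtures) were chosen as the smallest sizes at which the
checked properties are informative.

## Numerical and degenerate-input choices

* Calibration tolerance 1e-6 relative per cell; already-satisfied
  benchmarks return the design weights in one iteration.
* Singular calibration systems use `MASS::ginv`; the weight solution is
  unique whenever the program is feasible.
* Matching tie-breaks are uniform draws under the stage seed; identical
  inputs and seed give byte-identical output.
* A perfect regression fit yields a degenerate diagnostics report rather
  than a spurious normality p-value.
* `apply_preventable_fraction` is the only function that rounds, because its
  contract is defined at reporting precision.

## Known limitations

* The synthetic world is simpler than the real data (covariate independence
  within group, no design effects, invented unemployed/other-NILF group
  parameters), so published descriptive and base-case totals are not
  reproduction targets; structural invariants and parameter recovery stand
  in for them.
* The GDP figures inherit the illustrative identity parameters.
* No variance estimation for calibrated estimators, no small-area
  estimation, no distance-based matching variants, and no absenteeism,
  presenteeism, premature-mortality or carer-cost components — the scope is
  early retirement only, valued by the human-capital approach over a
  12-month horizon.
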