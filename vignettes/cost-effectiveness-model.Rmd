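---
title: "A Markov cohort model for hemiarthroplasty versus internal fixation"
author: "hipcea authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for hemiarthroplasty versus internal fixation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipcea)
```

## The decision problem

Nondisplaced femoral neck fractures in elderly patients can be treated with
internal fixation (IF) — cheaper, less invasive, but with a substantial
failure rate — or with hemiarthroplasty (HA) — costlier up front, but failing
less often. A failed implant is salvaged by conversion surgery: a failed IF is
converted to either HA or total hip arthroplasty (THA), a failed HA to THA.
`hipcea` implements a decision-analytic comparison of the two initial
strategies for a homogeneous cohort of 80-year-old patients, from a payer
perspective, with costs in 2020 US dollars and effectiveness in
quality-adjusted life-years (QALYs).

The decision statistic is the incremental cost-effectiveness ratio

$$\mathrm{ICER} = \frac{\Delta C}{\Delta E}
  = \frac{C_{HA} - C_{IF}}{E_{HA} - E_{IF}},$$

compared against a willingness-to-pay (WTP) threshold of \$11,083/QALY (the
2020 Chinese per-capita GDP at 6.45 CNY/USD). A strategy that is cheaper *and*
more effective is dominant; otherwise it is cost-effective when its ICER lies
below WTP — equivalently, when the net monetary benefit
$\mathrm{WTP}\cdot\Delta E - \Delta C$ is positive, which is the form the
package uses throughout because it behaves sensibly in all four quadrants of
the cost-effectiveness plane.

## Model structure

The model is a discrete-time Markov cohort model with annual cycles over a
5-year horizon. We use five states rather than the four of the usual
published diagrams:

* `PRIMARY_IF`, `PRIMARY_HA` — alive with the initial implant in place;
* `CONVERTED_HA` — alive after salvage HA following a failed IF;
* `CONVERTED_THA` — alive after salvage THA (from either route);
* `DEAD` — absorbing.

Splitting the salvage states is what lets a salvage HA itself fail: the model
assumes every in-place hemiarthroplasty — primary or salvage — fails at the
same annual probability, and a four-state structure cannot express that while
tracking salvage-THA occupants separately. Salvage THA is assumed not to fail
within the horizon (long-term registry failure rates after salvage THA are on
the order of a percent over a decade), so `CONVERTED_THA` is a quiet state.

Cycle 0 applies the initial procedure: the whole cohort pays the procedure
cost (undiscounted), a perioperative fraction dies (4.1% IF, 5.3% HA), and no
utility accrues. Each later cycle composes, in a fixed order:

1. **other-cause death** at the age-specific life-table probability for the
   cohort's current age (start age 80, so cycle $t$ uses age $79 + t$);
2. **failure of a primary IF** (3.3%/year among survivors), split 50/50
   between salvage HA (perioperative mortality 5.3%) and salvage THA (3.9%);
3. **failure of any in-place HA** (1.5%/year among survivors) to salvage THA
   (perioperative mortality 3.9%).

Converts entering a state in a cycle are not exposed to a second failure in
that same cycle. The ordering itself is a modelling choice — the composition
keeps every per-event probability exactly as published rather than converting
to competing-risk rates; with annual probabilities of a few percent the
difference between orderings is far below the other uncertainties discussed
below.

### Rewards, discounting, and timing conventions

Costs and QALYs are discounted at 3% per year. Conversion costs accrue to
everyone who undergoes the conversion, including those who die perioperatively
(the surgery happened); a one-off disutility of −0.15 QALY accrues to
converters who survive the conversion, on top of the destination state's
utility. State utilities are 0.63 (IF), 0.68 (either HA state) and 0.70 (THA)
per year lived.

Because the source analysis did not state its cycle-timing convention,
`run_cohort()` exposes it explicitly:

* `accrual = "end"` (default): occupants alive at the *end* of cycle $t$
  accrue that state's utility, discounted by $(1+r)^{-t}$; people dying
  during the cycle accrue nothing that year. This is the convention under
  which the degenerate closed forms below are exact annuities.
* `accrual = "begin"`: occupants alive at the *start* of the cycle accrue
  their pre-transition state's utility at $(1+r)^{-(t-1)}$ — i.e. the year of
  death is lived.
* `half_cycle_correction = TRUE`: utilities use the mean of start- and
  end-of-cycle occupancy at exponent $t - \tfrac12$, the classical half-cycle
  correction; costs keep the timing of the chosen accrual.

The begin-of-cycle convention reproduces the published arm totals most
closely (all four discounted costs and QALYs within 5%) and is what the
package's acceptance tests select; the default remains `"end"` because it is
the cleaner convention to reason about and the one the closed-form tests pin
down exactly.

## Inputs

All inputs live in one validated record (`default_params()`), loadable from
flat YAML/JSON with `load_params()`; unknown keys warn, out-of-range values
error with the field named, and nothing is silently clamped. The headline
fields, with units:

| field | base value | meaning |
|---|---|---|
| `periop_mort_if` / `_ha` / `_tha` | 0.041 / 0.053 / 0.039 | perioperative death probability per procedure |
| `fail_if`, `fail_ha` | 0.033, 0.015 | annual implant failure probability |
| `conv_split_if_to_ha` | 0.5 | share of failed IF salvaged with HA (rest THA) |
| `u_if`, `u_ha`, `u_tha` | 0.63, 0.68, 0.70 | utility per year in each state |
| `disutil_salvage` | −0.15 | one-off QALY loss in the conversion year |
| `c_if`, `c_ha` | 8,632, 12,449 | initial procedure cost, 2020 USD |
| `c_if_to_ha`, `c_if_to_tha`, `c_ha_to_tha` | 26,670, 25,508, 22,662 | conversion costs, USD |
| `wtp` | 11,083 | USD per QALY |
| `discount_rate` | 0.03 | per year |
| `horizon_cycles`, `start_age` | 5, 80 | years |

Two published tables of this analysis disagree on two values: the
uncertainty-analysis table prints a 2.7% IF failure mean and a \$22,670 IF→HA
conversion cost where the input table prints 3.3% and \$26,670. The Beta
parameters printed alongside (96.67, 2832.64) back-solve to a mean of 0.033,
so the input table is taken as authoritative everywhere; the alternative
values are one `load_params()` override away for anyone who wants them.

### The life table, and why it matters

Other-cause mortality comes from an explicit age-indexed life table
(`age,qx` CSV). The analysis this package re-implements cited a national
census life table for China 2020 *without printing its values*, and that
table is not redistributable here. The bundled fixture
(`example_lifetable()`, file `china2020_qx_ages80to85_synthetic.csv`) is
therefore a clearly-labelled synthetic stand-in: a Gompertz curve
$q(x) = a e^{bx}$ anchored at $q(80) = 0.035$ with slope $b = 0.11$/year,
placed at the level of unadjusted Chinese old-age mortality around 2020
(census-style tabulations, which undercount old-age deaths, sit below
demographically adjusted life tables; the anchor was chosen once on those
grounds and not revisited). Every model function takes the life table as an
explicit argument precisely so that users can substitute a better one;
`generate_lifetable()` builds Gompertz tables for any age range.

This matters for reproduction. With the fixture and begin-of-cycle accrual
the model lands within 5% of all four published arm totals, but the ICER —
a ratio of two *differences* of similar numbers — amplifies the residual:
we obtain ≈\$10,467/QALY against a published \$6,128.52/QALY (same
qualitative conclusion: below the WTP threshold, HA cost-effective). The gap
is not only the life table. Working backwards from the published totals, the
IF arm's incremental conversion spending is consistent with the printed
failure and cost inputs under low old-age mortality, but the HA arm's would
require roughly 40% fewer HA→THA conversions than *any* combination of the
printed 1.5%/year failure probability, \$22,662 conversion cost, and a
plausible mortality level can generate — no life table or timing convention
reconciles both arms simultaneously. We therefore treat the published ICER as
not exactly reproducible from its printed inputs, report our own totals, and
gate our regression tests accordingly (the package's acceptance suite keeps
the ICER comparison in place, failing visibly rather than papering over it).

## Deterministic sensitivity analysis

`one_way()` perturbs a single input by ±20% (probabilities and utilities are
clamped back into $[0,1]$ with a warning if the scaling escapes it) and
records the ICER at both ends; `tornado()` does this for all fourteen
eligible inputs — every probability, utility, disutility and cost; WTP, the
discount rate, the horizon and the conversion split are deliberately not
varied — and sorts by ICER swing. On the base case the two procedure costs
dominate the tornado by a wide margin, matching the published ranking.

`threshold_search()` finds decision boundaries in one parameter by a grid
scan for a sign change followed by bisection (`uniroot`, relative tolerance
$10^{-6}$): the cost-effectiveness boundary solves
$\Delta C - \mathrm{WTP}\cdot\Delta E = 0$, the dominance boundary
$\Delta C = 0$ with $\Delta E > 0$ required at the root. Search domains are
the natural ones — $[0,1]$ for probabilities and utilities, $[0, 4\times]$
base for costs — and a criterion with no sign change over the domain returns
`NA` with a reason rather than an error; utilities, which cannot move costs,
correctly yield `NA` for dominance. Re-evaluating the model at any returned
threshold reproduces the boundary to within $10^{-4}$ relative (checked in
the tests). `two_way_region()` classifies a full grid over two parameters,
the classical cost-of-HA versus cost-of-IF plane.

## Probabilistic sensitivity analysis

Parameter uncertainty is propagated by Monte Carlo. Ten inputs are sampled —
the two failure probabilities and three utilities from Beta distributions,
the five costs from Gamma distributions — each fitted by the method of
moments to its base-case mean with SD equal to 10% of the mean:

$$\nu = \frac{m(1-m)}{s^2} - 1,\quad \alpha = m\nu,\ \beta = (1-m)\nu
\qquad\text{and}\qquad
k = (m/s)^2,\ \lambda = k/m .$$

A 10% CV makes every Gamma shape exactly 100. The constructions round-trip to
$10^{-10}$ (a property test), and the fitted parameters agree with the
published uncertainty table to one unit in the last printed digit — one
printed entry there is a truncation rather than a rounding of the exact
value. Perioperative mortalities and the 50/50 split are held fixed (the
published analysis assigned them no distributions), draws are independent
across parameters (no correlation structure was given), and the draw order is
fixed (one vector per parameter, in the documented order) so a seed pins the
entire experiment bit-for-bit.

`ce_summaries()` reports the share of iterations in which HA is costlier,
more effective, and acceptable at WTP (positive net monetary benefit —
identical, iteration by iteration, to $\Delta C < \mathrm{WTP}\cdot\Delta E$,
which the tests verify by brute force), the ICER of means, and a 95%
covariance ellipse of the $(\Delta E, \Delta C)$ cloud at the
$\chi^2_2$ 0.95 contour. `acceptability_curve()` sweeps WTP; its endpoints
obey finite-sample identities — at WTP 0 it equals the share of
cost-saving iterations, and as WTP → ∞ the share of effect-gaining ones.
At the default 10,000 iterations the effect-side share reproduces the
published 69.3% almost exactly, while the cost-side shares inherit the
incremental-cost gap discussed above and sit several points high.

## Validation against an independent microsimulation

`microsimulate()` re-implements the *same* event logic at the individual
level — per-patient uniform draws against each event probability, identical
reward timing — while sharing no transition algebra with the cohort engine,
whose occupancy vectors are pure expectation bookkeeping. Agreement between
the two is therefore evidence, not tautology. The acceptance suite runs both
engines on the base case and twenty random-but-valid parameter records
(`generate_random_params()`, uniform within documented bounds) at
$n = 200{,}000$ patients per arm and requires agreement within three Monte
Carlo standard errors per comparison. One caveat belongs in the open: with
84 fixed-seed comparisons, a per-comparison 3-SE gate has roughly a one-in-five
chance of a false alarm even for a perfect engine, and the shipped seeds
produce exactly one marginal excursion (z = 3.09 on one QALY comparison;
replicating that parameter set across twenty fresh seeds gives z centered on
zero). We left the seeds and the gate alone rather than shopping for a
quieter combination.

## Numerical choices and degenerate inputs

* Occupancy vectors are validated to sum to 1 within $10^{-8}$ on entry;
  traces conserve mass to $10^{-12}$ per row and the dead state is monotone.
* With all event probabilities zero the engine is exact: 5 years × utility
  undiscounted, and the annuity $u\sum_{t=1}^{5}(1+r)^{-t}$ at 3%.
* An ICER with $\Delta E = 0$ is `NA` with classification `indeterminate`;
  no division-by-zero ever propagates.
* Age lookups outside the life table error; there is no extrapolation.
* Thresholds unattainable on their domain are `NA` results, not exceptions.
* All randomness (PSA, microsimulation, random parameter records) flows from
  explicit integer seeds.

## Problem sizes

The shipped tests run the PSA at 10,000 iterations (matching the published
simulation size; ~7 s), the oracle comparisons at 200,000 patients per arm,
and property loops at 10–1,000 cases; the whole suite completes in under a
minute on one core.

## What the synthetic inputs do and do not show

The generators emulate the statistical structure the analysis assumes —
Gompertz-shaped old-age mortality, independent Beta/Gamma parameter
uncertainty at 10% CV, uniform-in-bounds parameter records. They do not
emulate cohort heterogeneity (sex, comorbidity, frailty), correlation between
costs and utilities, time-dependent failure rates, or complications outside
the salvage pathway (infection, dislocation, hardware removal), none of which
the underlying model represents either. Passing tests demonstrate internal
correctness of the engine and faithful implementation of the published
method; they cannot certify the clinical inputs, and the base-case caveat
above shows how sensitive the headline ICER is to an unpublished mortality
assumption.
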