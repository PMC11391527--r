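# hipcea

Decision-analytic cost-effectiveness analysis of **hemiarthroplasty (HA)
versus internal fixation (IF)** for nondisplaced femoral neck fracture in
elderly patients, from a payer perspective.

Clinicians and health-economics analysts face a genuine trade-off here: IF is
cheaper and less invasive but fails more often (non-union, osteonecrosis),
and failed implants need costly salvage arthroplasty; HA costs more up front
but revises less. `hipcea` turns that trade-off into a tested, reusable
model: a five-state Markov cohort model (primary IF, primary HA, salvage HA,
salvage THA, dead) run in annual cycles over a 5-year horizon for a cohort of
80-year-olds, accumulating discounted costs (2020 USD, 3%/year) and
quality-adjusted life-years.

The decision statistic is the incremental cost-effectiveness ratio

```
ICER = ΔC / ΔE = (C_HA − C_IF) / (E_HA − E_IF)   [USD per QALY]
```

judged against a willingness-to-pay threshold of $11,083/QALY, with
dominance handled through the net monetary benefit `WTP·ΔE − ΔC`. Around the
core engine the package provides:

* validated parameter records and age-indexed life tables (YAML/JSON/CSV);
* one-way (±20% tornado), two-way, and threshold sensitivity analyses
  (bisection on the cost-effectiveness and dominance boundaries);
* Monte Carlo probabilistic sensitivity analysis with method-of-moments
  Beta/Gamma distributions (`ν = m(1−m)/s² − 1`; Gamma shape `(m/s)²`),
  cost-effectiveness plane summaries, a 95% covariance ellipse, and
  acceptability curves;
* an independent patient-level microsimulation used to validate the cohort
  engine, plus generators for synthetic Gompertz life tables and random
  parameter records.

## Worked example

```r
library(hipcea)

params <- default_params()      # published base-case inputs
lt     <- example_lifetable()   # bundled ages-80..85 table (synthetic stand-in)

arm_if <- run_cohort("IF", params, lt, accrual = "begin")
arm_ha <- run_cohort("HA", params, lt, accrual = "begin")
arm_ha
#> Strategy HA: discounted cost $13758.33, 2.8061 QALYs (accrual: begin)
#>   alive at horizon end: 75.3%; in primary state (of survivors): 93.0%

compute_icer(arm_if, arm_ha, wtp = params$wtp)
#> Incremental cost $1840.20, incremental QALYs 0.1758
#> ICER: $10466.54/QALY (WTP $11083/QALY)
#> Classification: cost_effective
```

HA buys 0.176 extra QALYs per patient for $1,840 extra spending — about
$10,467 per QALY, below the $11,083 threshold, so HA is classified
cost-effective (though not dominant: it is not cheaper). Uncertainty around
that verdict:

```r
psa <- sample_psa(params, lt, n_iter = 2000, seed = 42, accrual = "begin")
ce_summaries(psa, params$wtp)[1:3]
#> $share_more_costly        [1] 0.876
#> $share_more_effective     [1] 0.691
#> $share_acceptable_at_wtp  [1] 0.513

head(tornado(params, lt, accrual = "begin")[, c("parameter", "bar_width")], 2)
#>   parameter bar_width
#> 1      c_ha 28322.559
#> 2      c_if 19638.552
```

HA gains QALYs in 69% of parameter draws and is acceptable at the threshold
in roughly half of them; the two procedure prices are by far the most
influential inputs, and `threshold_search("c_ha", "dominant", params, lt)`
gives the HA price at which it would dominate IF outright.

A caveat documented in detail in the vignette
(`vignettes/cost-effectiveness-model.Rmd`): the analysis this package
re-implements did not publish the life-table values it used, so the bundled
table is a clearly-labelled synthetic stand-in and the headline ICER is
sensitive to that assumption — pass your own `life_table()` to every function
to use better mortality data.

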