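# gtbias

Tools for studying **guarantee-time bias** (immortal time bias) in cohort
studies of cumulative drug exposure, written for biostatisticians and
pharmacoepidemiologists who want to see — and quantify — what goes wrong
when a time-varying exposure is analyzed as if it were fixed at baseline.

A subject initiates a drug at time *W* after cohort entry and accumulates
dose from then on. Coding subjects by the cumulative-dose group they
*eventually* reach, applied from time 0, credits the event-free time they
had to survive before reaching it to the exposed state: high dose then
looks protective even under the null. The package provides

* a **discrete-time cohort simulator** with this structure: per-interval
  event probability
  `P(t) = logit⁻¹(β₀ + β₁Z₁(t) + β₂Z₂(t) + β₃Z₃(t))`, where
  `Z₁, Z₂, Z₃` indicate low / moderate / high cumulative dose
  (`simulate_cohort()`);
* the three competing analyses as design builders feeding a common Cox
  fitter (`survival::coxph`, Efron ties): naive time-fixed Cox
  (`make_naive_design()`), time-dependent Cox on (start, stop] counting-
  process data (`make_counting_process()`), and landmark Cox with
  exposure frozen at the landmark time τ (`make_landmark_design()`);
* the **closed-form landmark conditional densities**
  `f(t | Z(τ₀)=0)` and `f(t | Z(τ₀)=1) = q₁(t)/Q₁(τ₀)`, and a numerical
  check of the identity `f(t|Z=0) = f(t|Z=1) = q₀(t)/Q₀(τ₀)` under
  `q₀ = q₁` for any initiation distribution (`verify_null_identity()`);
* a **Monte-Carlo harness** aggregating rejection counts (type I error /
  power), bias and MSE of hazard ratios per method × dose group
  (`run_scenario()`, `tabulate_scenarios()`), with manifest-driven
  byte-identical reruns (`export_scenario_tables()`,
  `rerun_from_manifest()`).

See `vignettes/guarantee-time-bias.Rmd` for the model, the default
parameter choices and their rationale, and known small-sample caveats.

## Worked example

```r
library(gtbias)

coh <- simulate_cohort(sim_config(seed = 42))   # N = 5000, 5% users, null effect
coh
#> Simulated cohort: 5000 subjects, 728 events, 235 realized drug users
#>           event
#> dose       FALSE TRUE
#>   none      4054  711
#>   low         73    5
#>   moderate    64   10
#>   high        81    2

fit_cox(make_naive_design(coh$subjects))
#> Cox fit (naive design, efron ties): 5000 subjects, 728 events
#>     group     hr  log_hr     se  wald_z p_value estimable
#>       low 0.4151 -0.8792 0.4488 -1.9590  0.0501      TRUE
#>  moderate 0.8666 -0.1432 0.3184 -0.4497  0.6530      TRUE
#>      high 0.1496 -1.8999 0.7081 -2.6831  0.0073      TRUE

fit_cox(make_counting_process(coh$long))
#> Cox fit (counting_process design, efron ties): 5000 subjects, 728 events
#>     group     hr  log_hr     se  wald_z p_value estimable
#>       low 0.5209 -0.6523 0.4489 -1.4530  0.1462      TRUE
#>  moderate 1.6698  0.5127 0.3199  1.6027  0.1090      TRUE
#>      high 0.6438 -0.4403 0.7105 -0.6198  0.5354      TRUE
```

The drug does nothing in this cohort (all β's for dose are 0), yet the
naive fit reports a significantly protective high-dose hazard ratio of
0.15 (p = 0.007) — pure guarantee-time bias. The time-dependent fit,
which classifies each interval by the dose actually accrued so far, sees
hazard ratios compatible with 1 everywhere. A landmark fit at τ = 7
behaves similarly on the post-landmark cohort; note that with the default
cutpoints the high-dose group is not reachable by τ = 5 (maximum
cumulative dose 2.5 < 3.0), and such structurally empty groups are
reported as non-estimable rather than as numbers.

Scenario-level, over many replications:

```r
spec <- scenario_spec(sim_config(seed = 1), n_replications = 300)
res  <- run_scenario(spec)           # rejection counts, bias, MSE per method × group
tabulate_scenarios(res, "type1")
```

A thin command-line front end over the same functions lives in
`inst/cli/gtbias.R` (subcommands `simulate`, `fit`, `scenario`,
`densities`).

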