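# strokecea

Decision-analytic modelling of acute ischemic stroke (AIS) care
improvement targets: a 90-day decision tree feeding a lifetime Markov
cohort model, with incremental cost-effectiveness analysis, deterministic
and probabilistic sensitivity analysis, and a synthetic country-input
generator.

## Who this is for

Health-economics and stroke-policy analysts who want a tested, scriptable
version of the standard two-stage AIS cost-effectiveness framework: value
a change in national stroke care (treatment rates, onset-to-treatment
times, prevention) against baseline care in terms of lifetime costs,
quality-adjusted life-years (QALYs) and disability.

## The model in brief

**Stage 1 (day 0–90).** The incident cohort splits over three arms —
standard medical care, intravenous thrombolysis (IVT), endovascular
treatment (EVT) — each with a 90-day outcome distribution over modified
Rankin Scale bands mRS 0–2 / 3–5 / 6 (dead). The cohort distribution is
the arm-share-weighted mixture.

**Stage 2 (lifetime).** A yearly Markov cohort model over
{mRS 0–2, mRS 3–5, recurrent stroke (one-year tunnel), dead}. Recurrence
risk declines with time since the stroke; death combines stroke-related
excess mortality with life-table background mortality as independent
competing risks, `1-(1-a)(1-b)`. Costs and utilities accrue per cycle and
are discounted at `1/(1+r)^t`.

**Targets.** (1) IVT rate to 15%; (2) EVT rate to 5%; (3) onset-to-needle
under 120 min; (4) onset-to-puncture under 200 min; (5) recurrent stroke
−10%; (6) first-time stroke −10% via a general-population pathway
mixture. Time targets act on the treated arm: `+0.0008` mRS 0–2
probability per minute saved, and 90-day death odds divided by
`1.16^(hours saved)` (odds ratio per hour of delay; the United Kingdom
carries an onset-to-puncture override of OR = 1). Results are reported as
incremental cost, incremental QALYs, and the ICER
`Δcost/ΔQALY` — or "Dominant" when a target gains QALYs while saving
costs.

Seven European countries ship as fixtures with their published baseline
performance (e.g. Germany: onset-to-needle 96 min, onset-to-puncture
160 min, IVT 17.5%, EVT 5.2%). Unpublished national inputs — mRS-band
costs, life tables, cohort start age, incidence — are synthetic
stand-ins, generated deterministically from a seed and flagged in each
config's `synthetic_fields`; see the vignette for exactly what that does
and does not let you conclude.

## Worked example

```r
library(strokecea)
configs <- fixture_countries()

# What is raising Sweden's EVT rate from 2.2% to 5% worth?
run_comparison(configs$Sweden, scenario_spec(2))
#> <scenario_result: Sweden, target 2 (Increase EVT rate)>
#>   incremental cost:      -85.63 EUR
#>   incremental QALYs:     0.0342
#>   ICER:              Dominant
#>   mRS 0-2 change:    +0.67 pp (cohort scope)
```

Moving 2.8% of the cohort from standard care to EVT lifts the 90-day
independence (mRS 0–2) share by 0.67 percentage points
(2.8% × (0.46 − 0.22)), gains 0.034 QALYs per patient over a lifetime,
and saves money under the synthetic Swedish cost set — a dominant
strategy. A full matrix:

```r
m <- run_matrix(configs[c("Sweden", "Italy")], lapply(c(2, 5), scenario_spec))
render_report(m, "structured-text", "report.txt")
```

```text
Target 2 -- Increase EVT rate
  country          inc cost (EUR)  inc QALYs           ICER  d mRS 0-2  d mRS 3-5
  Sweden                   -85.63     0.0342       Dominant       0.67      -0.42
  Italy                    -97.63     0.0447       Dominant       0.79      -0.50

Target 5 -- Reduce recurrent stroke incidence
  country          inc cost (EUR)  inc QALYs           ICER  d mRS 0-2  d mRS 3-5
  Sweden                   496.55     0.0126       39460.88       0.00       0.00
  Italy                    436.35     0.0136       32052.35       0.00       0.00
```

Countries whose baseline already meets an absolute target (Targets 1–4)
are reported as NA — Germany meets all four. Sensitivity analysis:

```r
tor <- one_way_dsa(configs$Italy, scenario_spec(2))        # tornado
psa <- run_psa(configs$Italy, scenario_spec(2),
               psa_spec(n_draws = 1000, seed = 1))         # PSA + CEAC
```

A command-line front end is included
(`Rscript inst/cli/strokecea.R <verb> ...` with verbs `validate-config`,
`make-fixtures`, `gen-config`, `run`, `dsa`, `psa`, `report`).

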