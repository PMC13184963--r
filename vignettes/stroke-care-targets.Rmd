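---
title: "Modelling the value of closing gaps in acute ischemic stroke care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the value of closing gaps in acute ischemic stroke care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokecea)
```

## The model

`strokecea` implements a two-stage decision-analytic model of acute
ischemic stroke (AIS) care and uses it to value six care-improvement
targets in seven European countries.

**Stage 1 — the 90-day decision tree.** An incident AIS cohort splits into
three treatment arms: standard medical care, intravenous thrombolysis
(IVT), and endovascular treatment (EVT). Each arm carries a 90-day outcome
distribution over three modified Rankin Scale (mRS) bands — mRS 0–2
(functionally independent), mRS 3–5 (dependent), and mRS 6 (dead). The
cohort-level 90-day distribution is the arm-share-weighted mixture. The
arm-level distributions (0.22/0.27/0.46 reaching mRS 0–2 under standard
care/IVT/EVT) are shared across countries; the arm shares and
onset-to-treatment times are country-specific.

**Stage 2 — the lifetime Markov cohort model.** From day 90 the cohort is
projected through yearly cycles over four states: mRS 0–2, mRS 3–5, a
*recurrent stroke* tunnel state, and death. Recurrence risk depends on
time since the stroke (0.111 in year 1, 0.041 in years 2–5, 0.027 in
years 6–10, 0 beyond), and is the same from both live mRS bands. The
tunnel lasts exactly one cycle and redistributes to
(mRS 0–2, mRS 3–5, death) = (0.250, 0.605, 0.145). Stroke-related excess
mortality (0.008/year from mRS 0–2, 0.039/year from mRS 3–5) is combined
with background life-table mortality as independent competing risks,
$1-(1-a)(1-b)$, which can never exceed 1. There is no improvement pathway
from mRS 3–5 back to mRS 0–2; dependency arises only through recurrent
stroke.

Each cycle accrues utilities (0.71/year in mRS 0–2, 0.20/year in mRS 3–5,
0 when dead) and costs (annual mRS-band costs; a one-off event cost on
entering the recurrent state; arm- and band-specific costs for the first
90 days). Cycle $t$ is discounted by $(1+r)^{-t}$ (end-of-cycle
convention), with country-specific rates.

## The six targets

1. Raise the IVT rate to 15%.
2. Raise the EVT rate to 5%.
3. Reduce onset-to-needle time to under 120 minutes.
4. Reduce onset-to-puncture time to under 200 minutes.
5. Reduce recurrent-stroke incidence by 10% (secondary prevention).
6. Reduce first-time stroke incidence by 10% (primary prevention).

Targets 1–4 are absolute: where the baseline already meets them the cell
is reported as NA. Targets 5–6 are relative and always apply.

Rate targets move cohort share from standard care into the reperfusion
arm; the other arm is untouched. Time targets act only on the treated arm
(onset-to-needle on IVT patients, onset-to-puncture on EVT patients):
every minute saved adds 0.0008 to the arm's mRS 0–2 share (a presumed
linear dose–response of 4.8 percentage points/hour), and 90-day mortality
falls through an odds ratio of 1.16 per hour of delay — the odds of death
are divided by $\mathrm{OR}^{h}$ for $h$ hours saved, with mRS 3–5 as the
residual bin. For the United Kingdom the onset-to-puncture OR is
overridden to 1 (the published association is not supported at very long
onset-to-groin times), so the whole mRS 0–2 gain is drawn from mRS 3–5.
Strict "<" thresholds are honoured by aiming one minute below the
threshold; this convention reproduces all of the published time-target
disability changes (e.g. 34 minutes × 0.08 %/min = 2.72 percentage points
for France, 179 × 0.08 = 14.32 for the United Kingdom).

Target 5 multiplies every recurrence probability by 0.9. Target 6 routes
10% of the cohort down a *general-population pathway* — background
mortality only, a configurable general-population utility (default: the
mRS 0–2 utility, a deliberately conservative choice that uses only
in-model utilities), and zero stroke costs — while the remaining 90%
follow the unchanged stroke model. Scenario totals are the exact mixture,
which makes the population-mixture linearity testable to machine
precision.

## Reporting conventions

Incremental costs and QALYs are computed at full precision; the ICER is
the ratio of the full-precision increments, never of rounded display
values. Strategies that gain QALYs while saving costs are *dominant* (no
ICER reported); those that lose QALYs at extra cost are *dominated*.
Disability changes are reported in percentage points: at cohort scope for
the rate targets, and at treated-arm scope for the time targets — the only
convention under which the per-minute effect appears undiluted by the arm
share (3.6 = 45 × 0.08 for France regardless of its 5.3% EVT share).
Display rounding is 2 decimals for percentage points and euros, 4 for
QALYs.

```{r example}
configs <- fixture_countries()
res <- run_comparison(configs$Sweden, scenario_spec(2))
res
```

## What is published input and what is synthetic

The treatment profiles of the seven countries (times, rates), the shared
outcome table, transition probabilities, utilities, and acute-effect
parameters are published values and are embedded in
`fixture_countries()`. Four national inputs are **not** published at the
required granularity: the per-country mRS-band costs, the all-cause
mortality life tables, the cohort starting age, and the annual incident
cohort size. These are replaced by the synthetic-data module and flagged
in each config's `synthetic_fields`:

* **Costs** — six per-mRS-category annual cost levels are drawn monotone
  increasing in severity and collapsed to the model's two live bands by
  configurable weights (default equal); acute 90-day costs are ordered
  EVT > IVT > standard care. The ordering constraints make the
  qualitative economics (e.g. possible dominance of time targets)
  reachable, but the *euro magnitudes are synthetic*: the package
  therefore does not attempt to reproduce the published per-country
  lifetime cost and QALY totals or ICER values, which depend on those
  unpublished tables. What it does reproduce exactly is everything
  upstream of costs — the 90-day disability changes, the attainment/NA
  pattern, and the transition machinery.
* **Life tables** — Gompertz–Makeham hazards
  ($h(x) = 5\times10^{-4} + a\,e^{bx}$ with $a = 2\times10^{-5}$,
  $b = 0.10$, seeded jitter), closed at age 100. These give remaining
  life expectancies at 70 in the low-to-mid teens, typical of Western
  European populations.
* **Cohort start age** — 70 for all fixtures (a standard AIS modelling
  convention), configurable per country.
* **Discount rates** — national HTA guideline conventions (France 2.5%,
  United Kingdom 3.5%, 3% elsewhere; a single rate is used for costs and
  effects).
* **Annual incidence** — round plausible magnitudes used only for linear
  population scaling.

Passing tests therefore demonstrate the correctness of the *machinery* on
realistic inputs, not agreement with any country's actual cost level.

## Numerical and design choices

* **Cycle conventions.** One-year cycles; the first Markov cycle begins at
  day 90 and is treated as a full reward year (the model's probabilities
  are annual and no fractional-cycle rule is published). No half-cycle
  correction is applied. The 90-day decision-tree costs are strictly
  additive to the Markov stream. The recorded trace runs one cycle past
  the life-table closure age so it ends fully absorbed in death.
* **Recurrence clock.** Whether the recurrence schedule restarts after a
  recurrent event is ambiguous ("time since the initial event"). The
  default keeps a single clock from the index stroke;
  `reset_clock = TRUE` restarts the year-1 schedule on exiting the
  tunnel. The engine tracks occupancy per clock bin, so both conventions
  run through identical code; resetting re-exposes survivors to the high
  early-year hazards and weakly increases recurrent person-years.
* **Mortality rule for time effects.** The per-hour parameter is an odds
  ratio, so the default divides the odds of 90-day death by
  $\mathrm{OR}^{h}$; a risk-scale division is retained as a switch
  (`mortality_rule = "risk"`). Neither rule combined with the
  residual-bin convention exactly recovers the published France mRS 3–5
  changes for the time targets (−1.21 and −1.6); the package exposes the
  switch and does not force a fit.
* **Infeasible rows.** A transition row whose stay-probability would go
  negative raises an error rather than silently renormalising — this is
  what surfaces infeasible parameter draws during probabilistic
  sensitivity analysis. At the closure age ($q_x = 1$) the row is certain
  death by construction.
* **PSA sampling.** Probabilities are drawn from
  $\mathrm{Beta}(1000p,\,1000(1-p))$; multinomial blocks use independent
  constrained betas with rejection of draws whose residual bin leaves
  $[0,1]$ (a Dirichlet sampler with the same pseudo-counts is provided
  for comparison). Draws feed both comparison arms, so parameter
  uncertainty is fully correlated across arms. The draw count (default
  1000) and seed are explicit; costs are held fixed unless
  `vary_costs = TRUE`.
* **DSA ranges.** Published ranges where they exist (the OR confidence
  interval 1.05–1.28, utilities, transition probabilities); ±10% of base
  elsewhere, the pattern evident in the published ranges. Tornado bars
  are ordered by incremental-QALY swing. Note that swinging a parameter
  moves *both* arms, so parameters common to baseline and scenario
  largely cancel in the increments: on a rate-target tornado the moved
  arm's outcome leads, not the standard-care outcome, even though the
  latter dominates the *absolute* totals.
* **Validation oracle.** An individual-level microsimulation of the
  identical yearly process (`microsim_oracle()`) provides an independent
  estimate of the lifetime totals; the deterministic cohort projection
  must agree within three Monte-Carlo standard errors. The test and
  acceptance runs use 50,000 patients per config (about a third of a
  second each), and 10,000 PSA draws for the sampling checks.

## Limitations

The synthetic generator does not emulate between-country correlation of
costs with care organisation, within-cohort age heterogeneity, sex
structure, or non-stroke causes of dependency. Recurrence is independent
of the mRS band, as in the source model. Implementation and investment
costs of actually reaching the targets are out of scope, as are societal
and indirect costs, stacked multi-target scenarios, and the stroke-unit
capacity target.
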