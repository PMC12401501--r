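---
title: "Model structure, parameters and verification methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, parameters and verification methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`twincua` evaluates three cervical-length (CL) screening strategies for
dichorionic diamniotic twin pregnancies — no screening, one-step universal
screening at 18–20 weeks, two-step universal screening at 18–20 and 20–22
weeks — on lifetime costs (2023 CAD), QALYs and clinical outcomes. This
vignette documents the model's structure and assumptions, the parameters
that matter, the numerical conventions, and what the package's verification
machinery does and does not establish.

## Decision tree

Every pregnancy carries a latent CL stratum: ≤ 15 mm, 15–25 mm, or > 25 mm,
defined by the *shortest* CL over the screening window. Because CL is
assumed never to increase on repeat measurement, the two-step strategy
observes the shortest CL, and the two-step detection totals double as the
population prevalences of the strata. One-step screening detects only what
is already short at 18–20 weeks; the pregnancies that would first screen
positive at 20–22 weeks remain undetected and untreated under one-step, but
still carry their (short-stratum) baseline risk. This latent-stratum reading
is what makes the three strategies collapse to identical clinical outcomes
when all treatment effects are set to 1 — a property the test suite enforces
— whereas treating undetected short-CL pregnancies as if they had a long
cervix would not.

Screen-1 positives in the 15–25 mm stratum are *not* re-classified to
≤ 15 mm at the second screen: the published conditional detection
probabilities condition only on screen-1 negativity, and the tabulated
two-step detection totals (0.12 / 0.05 at ≤ 25 / ≤ 15 mm) follow exactly
from that reading. An upgrade path would require a transition probability
that was never reported.

Detected patients receive vaginal progesterone (CL ≤ 25 mm) or cerclage plus
progesterone (CL ≤ 15 mm); the combined effect of cerclage and progesterone
is conservatively modelled as cerclage alone. Treatment multiplies each
preterm GA category's birth probability by a relative risk, blended with
uptake $u$ (default 1):

$$p'(g) = p(g)\,[u\,\mathrm{RR}(g) + (1-u)], \qquad
  p'(\text{term}) = 1 - \sum_{g \in \text{preterm}} p'(g).$$

The residual-to-term convention keeps every distribution on the simplex and
is also what makes one-way sensitivity analysis on a single birth-timing
entry well defined (the term category absorbs the perturbation). If sampled
relative risks and birth-timing draws jointly push preterm mass above 1 the
inputs are inconsistent; the evaluator raises an error and the PSA rejects
and redraws such parameter sets (the rejection count is reported on the PSA
object).

Stillbirth is computed as the dot product of the birth-timing distribution
with GA-specific stillbirth probabilities, per 1000 pregnancies. By default
it is reported as a clinical outcome and does **not** remove mass from the
lifetime cohort — the two published couplings (per-fetus vs per-pregnancy,
reducing cohort entry or not) are not distinguished in the source text, so
the coupling is a flag (`options.stillbirth_reduces_cohort`), off by
default.

## Lifetime cohort model

For each GA category a two-state (alive / dead) cohort model runs on integer
ages 0–100 inclusive — 101 one-year cycles. Survival follows
$S(0)=1,\; S(a{+}1)=S(a)(1-q_g(a))$ with

$$q_g(a) = 1 - (1 - q_{\text{term}}(a))^{\mathrm{HR}(g,a)}, \quad a \le 45,
  \qquad q_g(a) = q_{\text{term}}(a), \quad a \ge 46,$$

i.e. hazard ratios are applied on the hazard scale (the source describes
*rates multiplied by hazard ratios*; hazard-scale multiplication is the
reading that can never produce a probability outside $[0,1]$), and hazards
are equal across GA categories from age 46, where the source cohort data
end.

Rewards (utility and cost) accrue for every cycle the cohort is alive at its
start; year-0 rewards are undiscounted and year $a$ is discounted by
$(1+r)^{-a}$ with $r = 1.5\%$/year for both costs and QALYs. There is no
half-cycle correction by default; enabling `options.half_cycle` removes half
of each cycle's deaths from that cycle's reward mass and, by construction,
changes QALYs by less than one utility-year (tested). Life expectancy is the
undiscounted sum of the survival curve, so a degenerate immortal cohort
accrues 101 reward-years — the stated "maximum of 100 years" is implemented
as the inclusive age grid 0–100 with a 1-year cycle.

Annual costs follow a tabulated ages 0–9 trajectory per GA category and are
constant afterwards at the age-9 cross-category average (the source's
stated assumption; it likely understates late-life costs). Utilities are
HUI3 trajectories per GA category, built as the linear blend
$\pi_g u_{\text{NSI}}(a) + (1-\pi_g) u_{\text{no NSI}}(a)$ with $\pi_g$ the
neurosensory-impairment proportion. The blended matrix is the input the
cohort model consumes; the package does not re-derive population HUI3 trends
from survey microdata.

Strategy totals are GA-weighted sums of the five cohort runs multiplied by
the twin multiplier (default 2: one pregnancy, two concordant neonates;
varied 1–2 in scenario analysis). Screening proportions are per pregnancy
and unaffected by the multiplier.

## Parameters, file format and distributions

Parameters are addressed by dot-paths (`screening.p_s1_le25`,
`rr_cerclage.ga_le28`, `costs.nicu_per_admission.ga_34_37`,
`utility.a50.ga_gt37`, …). A set is one YAML master document plus four CSV
sidecars for the large tables (lifetable `age,probability`; hazard ratios,
utilities and annual costs `age,category,value`). Two ranges attach to each
parameter: the *clinical range* (drives default DSA grids) and the
*mathematical support* (drives validation; DSA and overrides may exceed the
clinical range by design — some published cost thresholds lie outside it).

Uncertainty families follow the published table: beta (event / non-event
counts) for probabilities, lognormal (log-mean, SE) for relative risks,
gamma (mean, CV) for unit costs. One family is added: the five-entry
birth-timing rows are sampled **jointly as dirichlet** (normalized gamma
draws). Independent per-category betas with a residual term category would
produce invalid simplexes with non-negligible probability in the ≤ 15 mm
stratum, whose preterm mass is ~0.84. Draws consume the RNG in the fixed row
order of the priors table, so a seed identifies the same joint draw
anywhere. The source does not say whether cost parameters were gamma or
fixed in its PSA; here the six unit costs and five NICU costs are gamma, and
the annual-cost and utility tables, lifetable, hazard ratios, discount rate,
uptake and twin multiplier are fixed in the PSA and explored through DSA and
scenarios — the bundled file records the choice per parameter.

### Scan schedule

Screened patients' ultrasound costs are a per-strategy scan count times a
unit cost, both configurable. The default counts are the
*screening-attributable* scans (0 / 1 / 2) at $95 per scan: the published
per-pregnancy ultrasound costs ($95 one-step, $194 two-step) are in a 1:2
ratio that no single unit cost can produce once weekly surveillance scans to
24 weeks are added to both arms, so surveillance is treated as part of usual
twin care (or as folded into the unit cost) rather than as a
strategy-attributable cost. Analysts who prefer the surveillance-inclusive
reading can set `n_scans` to (0, 6, 7).

Progesterone is costed per treated week from the detecting screen's start
week (19 for screen 1, 21 for screen 2 — midpoints of the stated windows) to
36 weeks or birth, whichever is sooner, with gestational week at birth taken
as the GA-category midpoint (26, 30, 33, 35.5, 38.5 weeks) since no
within-category distribution is reported.

## Synthetic parameter generation

The complete parameter table behind the published analysis lives in
supplementary material that is not machine-readable. The package therefore
separates *what is printed* from *what is emulated*:

* **Anchored exactly**: the four screening detection probabilities with
  their beta counts, and the eight treatment relative risks with their
  lognormal SEs.
* **Calibrated to printed population-level figures**: the > 25 mm stratum's
  baseline birth timing is solved so that the untreated population mixture
  equals the no-screening GA distribution consistent with the published
  cumulative PTB proportions (0.04 / 0.07 / 0.13 at ≤ 28 / ≤ 32 / ≤ 34
  weeks) and the 62.7% PTB < 37 weeks external-validation figure; the two
  short-CL strata use fixed severity-graded vectors.
* **Synthetic shapes**: Gompertz lifetable with an infant-mortality spike
  (≈ 0.4% infant mortality, senescent doubling time ≈ 7 years); hazard
  ratios starting at (60, 15, 6, 2.5, 1) at birth — the extreme-preterm
  value encodes neonatal mortality of roughly 20% — decaying exponentially
  toward 1 by mid-adulthood; quadratically declining HUI3 trajectories
  (0.93 at birth to ≈ 0.70 at 100) with a constant 0.25 NSI decrement and
  NSI proportions (28%, 14%, 8%, 3%, 1.5%); annual costs decaying
  geometrically over ages 0–9 from (30000, 15000, 8000, 2500, 400) CAD to a
  common floor; stillbirth probabilities (1.2%, 0.6%, 0.4%, 0.3%, 0.9%) —
  term risk deliberately high relative to late preterm, as reported for
  dichorionic twins, which is what makes screening raise the stillbirth
  rate marginally while lowering PTB.

`generate_parameter_set()` with `jitter > 0` produces seeded families of
such sets, rejecting draws that break the severity gradient (shorter cervix
must carry more preterm mass). Every generated set passes the full
validator.

What passing tests on these sets shows: the *pipeline* is correct — the
arithmetic of the tree, the cohort model, the CEA statistics, and their
mutual consistency with an independent per-individual microsimulation. What
it does not show: that the synthetic lifetime inputs equal the study's; any
quantity downstream of the supplementary tables (absolute costs, QALYs,
credible intervals, CEAC levels) is reproduced in structure and rough
magnitude, not to the printed digit. A transcribed supplementary table
loaded through `load_parameters()` slots into the same pipeline unchanged.

## CEA statistics and numerical conventions

* ICER $= \Delta\text{cost}/\Delta\text{QALYs}$ versus no screening,
  undefined (NA) when $|\Delta\text{QALYs}| \le 10^{-9}$; dominance is
  classified with the same $10^{-9}$ zero-delta tolerance, ties going to
  "trade-off".
* PSA summaries are means with linear-interpolation empirical 2.5/97.5
  percentiles. Both ICER conventions are emitted — ratio of mean deltas and
  mean of per-draw ratios — because the tabulated one-step ICER matches the
  former while the published two-step ICER does not equal its ratio of
  means; per-draw ratios are unstable when QALY deltas change sign, so the
  ambiguity is surfaced, not hidden.
* The CEAC assigns each draw to the strategy with the strictly greatest net
  monetary benefit $\lambda\,\text{QALYs} - \text{cost}$; exact ties split
  the draw's mass equally, so probabilities sum to 1 at every $\lambda$.
  Within a draw all three strategies share the identical sampled parameter
  set (common random numbers), and the sampled values are recorded on the
  result so any draw can be replayed.
* DSA winners use a configurable criterion (net benefit at
  $\lambda = \$100{,}000$/QALY by default — the customary ceiling — or
  lowest cost, highest QALYs, lowest PTB); switch points between adjacent
  grid values with different winners are refined by bisection to a relative
  tolerance of $10^{-6}$ and are tested against a dense-grid argmax scan.

## Verification battery and problem sizes

The package treats verification as part of the model: a per-individual
microsimulation (`microsim_oracle()`) re-implements the whole pathway with
Bernoulli draws — screening cell, uptake, GA category, stillbirth, Cesarean,
NICU admission, then annual survival with per-cycle discounted accrual — and
its means must agree with the cohort pipeline within 3 Monte-Carlo standard
errors on every outcome field. The test suite runs this at 200,000
pregnancies per strategy (and checks the error shrinks from n = 10³ to 10⁵),
alongside exact closed-form checks: hazard-scale mortality, geometric
annuity QALYs under constant hazard (tolerance $10^{-10}$), the discrete
annuity at 1.5%, and the all-RR-=-1 strategy collapse. PSA-based tests use
25–200 draws and property tests use 25–100 seeded replicates; these sizes
were chosen to keep the default suite under a minute while leaving
Monte-Carlo bounds far from their tolerances.

## Known limitations

* The bundled lifetime inputs are synthetic stand-ins; conclusions about
  absolute cost/QALY levels require a transcribed supplementary table.
* PSA samples parameters independently (no correlation structure was
  reported); joint draws are truncated to coherent sets by rejection.
* No modelling of miscarriage before viability, treatment disutility,
  monochorionic or higher-order pregnancies, screening-program
  implementation costs, or value-of-information analysis.
* NSI-subgroup mortality is not differentiated, and costs after age 9 are
  constant by assumption.
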