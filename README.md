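# twincua

Decision-analytic cost-utility model of universal second-trimester
cervical-length (CL) screening in dichorionic diamniotic twin pregnancy.

## The problem

Twins contribute a disproportionate share of preterm births (PTB), and a
short cervix on transvaginal ultrasound predicts PTB. Two interventions with
evidence in twins are available once a short cervix is found: daily vaginal
progesterone for CL ≤ 25 mm, and ultrasound-indicated cervical cerclage (plus
progesterone) for CL ≤ 15 mm. Whether *universal* CL screening of low-risk
twin pregnancies is worth paying for — and whether one measurement at 18–20
weeks suffices or a second at 20–22 weeks adds value — is a policy question
this package models for a Canadian (2023 CAD) setting.

`twincua` is aimed at health-economics analysts: it implements the full
pipeline — decision tree, lifetime cohort model, incremental cost-utility
statistics, probabilistic and deterministic sensitivity analysis — as tested,
reusable R functions driven by a plain-text parameter file.

## The model

Three strategies are compared: no screening, one-step universal screening
(18–20 weeks) and two-step universal screening (18–20 and 20–22 weeks; the
shortest of the two measurements drives treatment, and CL is assumed never to
increase).

1. **Decision tree.** Every pregnancy has a latent CL stratum (≤ 15 mm,
   15–25 mm, > 25 mm). Screening detects part of the short-CL population;
   detected patients receive treatment whose effect multiplies the
   probability of birth in each preterm gestational-age (GA) category by a
   relative risk RR, with the term category absorbing the residual mass:
   `p'(g) = p(g) · [u·RR(g) + (1 − u)]` for the four preterm categories
   (uptake `u`, 1 in the base case). The tree yields the GA-at-birth
   distribution over five categories (≤ 28, 28–32, 32–34, 34–37, > 37
   weeks), screen-positive proportions, stillbirths/1000, and pregnancy-phase
   costs (scans, progesterone, cerclage, birth at a 60% Cesarean rate, NICU
   admission).
2. **Cohort state transition model.** For each GA category, a two-state
   (alive/dead) Markov model with 1-year cycles follows a child from age 0 to
   100. Mortality is the national lifetable scaled on the hazard scale by GA-
   and age-specific hazard ratios up to age 45
   (`q(a) = 1 − (1 − q_term(a))^HR(g,a)`), equal hazards thereafter. Cycles
   accrue HUI3 utilities (blended by the neurosensory-impairment proportion
   of each GA category) and annual costs (ages 0–9 tabulated, constant
   after), discounted at 1.5%/year.
3. **Aggregation and CEA.** Strategy outcomes are GA-weighted sums of the
   cohort results, doubled for the two (assumed concordant) twins. Versus no
   screening the package reports Δcost, ΔQALYs, ICER = Δcost/ΔQALYs and
   dominance; PSA (beta/lognormal/gamma/dirichlet parameter uncertainty, 1000
   draws) gives means, 95% credible intervals and the cost-effectiveness
   acceptability curve via net monetary benefit `λ·QALYs − cost`; one- and
   two-way DSA locate decision thresholds by bisection.

The eight published screening/treatment inputs (detection probabilities
0.044, 0.468, 0.076, 0.377; progesterone RRs 0.53/0.71/0.64/1.02; cerclage
RRs 0.56/0.78/0.30/1.00, with their beta/lognormal distributions) are built
in. The remaining tables (birth timing by stratum, stillbirth, lifetable,
hazard ratios, utilities, costs) come from a supplementary table that is not
machine-readable, so the package bundles a **synthetic, calibrated stand-in**
(`inst/extdata/synthetic_base_case.yaml`) and a generator
(`generate_parameter_set()`); a transcribed real table in the same YAML/CSV
schema can be dropped in via `load_parameters()`.

## Worked example

```r
library(twincua)
params <- base_case_parameters()   # synthetic base case, printed values anchored
fit <- twin_cua(params)
fit
```

```
              outcome no_screen  one_step  two_step
      screen_pos_le15     0.000     0.021     0.048
      screen_pos_le25     0.000     0.044     0.117
             ptb_le28     0.040     0.036     0.030
             ptb_le32     0.070     0.065     0.056
             ptb_le34     0.130     0.122     0.109
             ptb_lt37     0.627     0.619     0.607
 stillbirths_per_1000     5.748     5.752     5.759
      life_expectancy   155.793   156.012   156.349
      cost_ultrasound     0.000    95.000   190.000
    cost_progesterone     0.000    13.000    31.000
        cost_cerclage     0.000    74.000   172.000
           cost_birth  6300.000  6300.000  6300.000
            cost_nicu 24025.000 22564.000 20300.000
       pregnancy_cost 30325.000 29045.000 26993.000
        lifetime_cost 27325.000 26725.000 25797.000
           total_cost 57650.000 55770.000 52789.000
          total_qalys    78.968    79.102    79.309

Incremental versus no screening:
 strategy comparator delta_cost delta_qalys   icer dominance
 one_step  no_screen      -1880       0.134 -14026  dominant
 two_step  no_screen      -4861       0.340 -14281  dominant
```

Reading this: screening detects 4.4% (one-step) or 11.7% (two-step) of
pregnancies at CL ≤ 25 mm; treatment moves birth mass out of the preterm
categories (PTB ≤ 28 weeks falls from 4.0% to 3.0% under two-step), which
cuts NICU and lifetime costs by more than screening and treatment cost, so
both screening strategies are *dominant* (cheaper, more QALYs); stillbirths
rise marginally because term carries a relatively high stillbirth risk in
twins. A negative ICER for a dominant strategy is reported for completeness
but dominance, not the ratio, is the conclusion. Quantities are per pregnancy
(two concordant twins, costs in 2023 CAD, 1.5%/year discounting).

Sensitivity analysis:

```r
psa <- run_psa(params, n = 1000, seed = 1)
psa                      # means and 95% credible intervals
plot(psa)                # incremental cost-effectiveness plane
plot(ceac(psa))          # acceptability curve
one_way_dsa(params, "rr_cerclage.ga_le28",
            grid = seq(0.3, 1.6, length.out = 7), criterion = "ptb_le28")
```

The last call locates the treatment-effect threshold above which no screening
minimizes extreme PTB (a harmful cerclage effect), refined by bisection.

A thin command-line wrapper lives at `inst/cli/twincua.R`
(`Rscript twincua.R run-psa --out DIR --seed 1`), and `run_analysis()` writes
CSV reports plus a `manifest.json` that records seed, parameter-file digest
and settings for exact re-runs.

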