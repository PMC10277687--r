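# hfcem

Cohort state-transition cost-effectiveness modelling for add-on therapy in
heart failure with reduced ejection fraction (HFrEF).

## The problem

Decision-makers weighing a new add-on drug (an SGLT2 inhibitor such as
empagliflozin) against standard of care (SoC) alone need lifetime estimates
of cost and health benefit, not just trial-horizon event counts. `hfcem`
implements the standard instrument for that question: a Markov cohort model
whose health states are KCCQ-CSS quartiles (Q1 0–54 … Q4 90–100, higher =
less disease burden) or, alternatively, NYHA classes, plus an absorbing
death state split into cardiovascular (CV) and non-CV causes. It is aimed at
health economists and HTA analysts who want a scriptable, fully tested
engine rather than a spreadsheet.

## The model

Monthly cycles with half-cycle (trapezoid) correction. Within each cycle the
cohort mass in every `(state, treatment stratum)` cell

1. dies of CV or non-CV causes — per-cycle conditional probabilities come
   from proportional-hazards Weibull equations,
   `S(t|x) = exp(−exp(η(x))·t^γ)` with
   `η = β₀ + β_trt·treated + β_state`, and non-CV death is floored by the
   age- and sex-specific general-population life table
   (`max(q_all−q_cv, model difference)`);
2. transitions between alive states under one of three period-specific
   row-stochastic matrices (months 1–3, 4–8, 9+) of the stratum's
   effective arm;
3. may discontinue treatment (exponential time-to-discontinuation),
   moving to the off-treatment stratum, which uses comparator matrices,
   risks and drug costs thereafter.

Recurrent heart-failure hospitalisations (hHF) accrue as expected Poisson
counts `exp(η)` per patient-cycle (rate ratio ≈ 0.70 on treatment); eight
adverse-event types accrue at constant per-arm incidences. Costs (2021 RM:
drug, hHF admission, CV death, disease management, adverse events) and
QALYs (state utilities minus one-cycle event decrements) are discounted at
3 %/year at cycle midpoints. Outcomes: per-arm totals and event rates,
ΔCost, ΔQALY, ICER, net monetary benefit against a threshold of
RM 47,439/QALY, tornado-style one-way sensitivity analysis, probabilistic
sensitivity analysis (Dirichlet/beta/gamma/normal families) with CEAC, and
scenario runs (NYHA states, short horizons, procurement prices, older
cohort, exponential survival).

Because the full trial-derived parameter tabulation is not public, the
package ships a synthetic parameter generator that emulates its statistical
structure, and a patient-level micro-simulation oracle that revalidates the
cohort engine on every test run.

## Worked example

```r
library(hfcem)

ps  <- generate_parameter_set(generator_knobs(seed = 1))
res <- run_ce(ps)
res$comparator
#> <hfcem_arm_results> arm: comparator
#>   cost RM 32695.90 | QALYs 3.6373 | LYs 4.8213 (discounted)
#>   years on treatment 0.000 | hHF rate 21.03 /100PY
res$intervention
#> <hfcem_arm_results> arm: intervention
#>   cost RM 36327.31 | QALYs 3.7680 | LYs 4.9551 (discounted)
#>   years on treatment 3.287 | hHF rate 17.68 /100PY
res$ce
#> <hfcem_ce_results>
#>   dCost RM 3631.40 | dQALY 0.1307 | dLY 0.1338
#>   ICER RM 27785/QALY (RM 27132/LY)
#>   NMB at CET RM 47,439: RM 2568.76 -> cost-effective
```

Adding the drug costs RM 3,631 extra per patient over a lifetime, buys
0.131 QALYs (mostly via 3.3 fewer hHF admissions per 100 patient-years and
a small survival gain), and lands at RM 27,785 per QALY — under the
threshold, so the add-on is cost-effective under these synthetic
conditions. Scenario runs move the ICER the way one expects:

```r
run_scenario(ps, list(state_space = "NYHA"))$ce$icer_per_qaly  # 15993
run_scenario(ps, list(prices = "moh"))$ce$icer_per_qaly        # 5471
```

Sensitivity machinery:

```r
torn <- run_dsa(ps, dsa_default_spec(ps))              # tornado table
psa  <- run_psa(ps, psa_default_spec(ps, 1000, seed = 2))
psa$quadrant_shares; psa$ceac                          # CE plane + CEAC
```

A thin command-line wrapper lives at `inst/cli/hfcem`
(`hfcem run|dsa|psa|scenario|synth`), writing trace CSVs, result JSON and a
run manifest.

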