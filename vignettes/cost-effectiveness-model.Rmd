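---
title: "A Markov cohort cost-utility model for add-on therapy in HFrEF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort cost-utility model for add-on therapy in HFrEF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfcem)
```

## The model

`hfcem` evaluates adding a drug (an SGLT2 inhibitor) to standard of care
(SoC) versus SoC alone in heart failure with reduced ejection fraction.
Disease burden is tracked through KCCQ-CSS quartile health states — a
patient-reported score where higher quartiles mean less burden — plus an
absorbing death state split into cardiovascular (CV) and non-CV causes; an
alternative NYHA-class state space supports scenario analysis. The cohort
is followed in monthly cycles over a lifetime horizon.

Each cycle applies, in this order:

1. **Death.** The CV and all-cause survival equations are
   proportional-hazards Weibull models on study time,
   $S(t\mid x)=\exp\{-e^{\eta(x)}t^{\gamma}\}$ with
   $\eta = \beta_0 + \beta_{\text{trt}}\,\mathbb{1}[\text{on drug}] +
   \beta_{\text{state}}$. The per-cycle conditional probability over
   $[t_0,t_1)$ is $1-S(t_1)/S(t_0)$, computed through the
   cumulative-hazard increment $e^{\eta}(t_1^{\gamma}-t_0^{\gamma})$ so the
   exponential special case ($\gamma=1$) is exactly time-constant and
   nothing underflows at extreme ages. Non-CV death is the all-cause minus
   CV difference, floored by the same difference from an age- and
   sex-specific general-population life table (weighted by the cohort's
   male fraction, 76%): modelled background mortality can never fall below
   the general population's.
2. **Health-state transitions** among survivors, using one of three
   period-specific row-stochastic matrices (months 1–3, 4–8, 9 and later),
   reflecting early post-initiation dynamics before transition behaviour
   stabilises. The on-treatment stratum uses the intervention arm's
   matrices; everyone else uses the comparator's.
3. **Treatment discontinuation** (exponential time-to-event by default),
   moving mass from the on- to the off-treatment stratum. Discontinuers
   take on comparator transition matrices, risks, adverse-event profile and
   drug cost from the next cycle onward.

Heart-failure hospitalisations (hHF) are transient, recurrent events: a
log-linear Poisson rate per patient-cycle, so expected counts may exceed
one. Eight adverse-event types (urinary tract infection, genital mycotic
infection, acute renal failure, hepatic injury, volume depletion,
hypotension, hypoglycaemia, bone fracture) occur at constant per-arm
monthly incidences.

## Accrual and outcomes

State-occupancy quantities — life years, state QALYs, disease-management
cost, drug cost on the stratum membership — use trapezoid ("half-cycle")
membership $(start+end)/2$; one-off event quantities (hHF cost and
utility decrement, CV-death cost, adverse-event cost and decrement) accrue
at full value in their cycle. Event tallies use the cycle-start mass net of
half that cycle's deaths, the exposure consistent with the trapezoid view.
Everything is discounted at cycle midpoints, $(1+r)^{-t}$, $r=3\%$/year
for both costs and outcomes.

The comparison reports ΔCost, ΔQALY, ΔLY, the ICER in the trade-off
quadrants, a dominance flag otherwise, and net monetary benefit
$\mathrm{NMB}=\lambda\,\Delta E-\Delta C$ at the threshold
$\lambda = \mathrm{RM}\,47{,}439$/QALY (one-time 2021 GDP per capita). The
verdict is $\mathrm{NMB}>0$; an NMB of exactly zero counts as *not*
cost-effective, the same tie rule the CEAC uses. A |ΔQALY| below $10^{-12}$
yields an undefined ICER (`NA`), as data rather than an error.

## Parameters that matter

| Parameter | Unit | Default | Why |
|---|---|---|---|
| cycle length | months | 1 | chronic disease with monthly-scale event risks |
| horizon | — | lifetime | stop at age 100 or alive mass < 1e-6 |
| discount (costs, outcomes) | %/yr | 3, 3 | local HTA convention |
| CET | RM/QALY | 47,439 | one-time 2021 GDP per capita |
| drug cost (int., comp.) | RM/month | 285.83, 175.17 | published market acquisition costs |
| hHF treatment rate ratio | — | 0.70 | trial-reported 30% reduction in hHF risk |
| death hazard ratios | — | 0.92 | trial-scale mortality benefit |
| starting age / male share | yr, % | 60, 76 | national HF registry cohort |
| initial KCCQ distribution | % | 24.3/25.1/27.2/23.4 | trial baseline quartiles |

"Lifetime" is operationalised as: stop when the alive mass drops below
$10^{-6}$ or the cohort reaches age 100, whichever is first, with a hard
cap of 2,400 cycles as a non-termination guard. Cohort age advances 1/12
year per cycle from the starting age; the life-table floor is looked up at
completed integer age. Survival time is study time, not age — the
trial-derived equations are on-study clocks — so ageing enters only through
the life-table floor.

## The synthetic generator

The risk-equation coefficients, transition matrices, utilities and unit
costs of the source analysis live in an unpublished supplementary
tabulation, so the package generates synthetic parameter sets with the same
statistical structure: Dirichlet-sampled diagonally-dominant matrices
(effective sample size 400) whose intervention version tilts toward better
states; Weibull coefficients anchored so the comparator arm reproduces
registry-scale event rates (the baseline monthly CV-death hazard 0.0053 and
hHF rate 0.0112 in the reference state were chosen so the comparator's
lifetime hHF, CV-death and non-CV-death rates land near the published
per-100-patient-year values); severity gradients on the log-hazard scale;
utilities interpolated between 0.64 (worst) and 0.87 (best); and a
deterministic Gompertz life table (level 6.5e-5/4.0e-5 per year for
males/females, slope 0.092, CV share 36%). Alternative blocks — an NYHA
parameterisation, an MoH-style procurement price table, and
cumulative-hazard-matched exponential survival equations (matched at 60
months) — support the scenario grid.

What the generator does **not** emulate: correlation between risk-equation
coefficients (no covariance matrices), seasonal or secular trends,
subgroup heterogeneity, and real utility-mapping noise. Passing tests
therefore demonstrate that the *machinery* is correct under realistic
structure, not that any specific published ICER is reproduced.

## Validation design

Three independent oracles guard the engine:

- **Quadrature**: per-cycle conditional probabilities agree with numeric
  integration of the declared hazard to $10^{-8}$ over 100 random
  parameterisations (and $10^{-10}$ on spot checks).
- **Independent summation**: discounted totals match a brute-force
  cycle-by-cycle re-summation written directly against the trace to
  $10^{-9}$.
- **Micro-simulation**: a patient-level simulator samples deaths,
  transitions, discontinuation, Poisson hHF counts and Bernoulli adverse
  events from the *same* per-cycle quantities the cohort engine uses, and
  accrues with the same conventions. It deliberately shares the hazard
  arithmetic (tested separately against quadrature) so that it
  independently exercises the cohort aggregation, stratum bookkeeping and
  half-cycle accrual — the parts most prone to silent error. Cohort totals
  must lie within 4 Monte-Carlo standard errors at $n=50{,}000$ patients.

Conservation (alive + dead mass $=1\pm10^{-9}$ every cycle), absorbing
death, arm-neutrality when all treatment effects are zeroed, and exact
Weibull($\gamma=1$) ≡ exponential equivalence are asserted as properties.

## Numerical choices and degenerate inputs

- Transition rows whose sums deviate from 1 by at most $10^{-6}$ are
  renormalised (rounding noise); larger deviations are rejected as data
  corruption, with arm/period/row named.
- The life-table floor can push CV + non-CV death marginally above 1 in
  the oldest ages; excesses up to $10^{-9}$ are rescaled proportionally,
  anything larger is an error naming state and cycle.
- Dirichlet redraws in the PSA clamp concentration parameters at
  $10^{-12}$ so structurally-zero transition entries stay (essentially)
  zero; draws failing validation are rejected and redrawn, with the count
  reported.
- PSA families: Dirichlet (rows), beta (utilities, incidences), gamma
  (costs, decrements), normal (log-scale coefficients) — conventional
  choices matching each parameter's support, since the source analysis
  names none. Zero dispersion reproduces the base value exactly, so a
  degenerate PSA equals the deterministic analysis.
- The PSA summarises central tendency both as the mean of per-draw ICERs
  over north-east-quadrant draws (unstable when ΔQALY approaches zero) and
  as the ratio of means (stable); both are reported.
- Tornado spans are $|ICER_{high}-ICER_{low}|$; parameters the engine
  never reads produce span 0 and sort last.

## Problem sizes in the test-suite and acceptance runs

Unit tests run the engine on shortened horizons (36–240 cycles) and
micro-simulations of 150–4,000 patients; the acceptance checks use full
lifetime traces (480 cycles), a 1,000-draw PSA, and 50,000-patient
micro-simulations — sizes at which Monte-Carlo standard errors are small
enough for 3–4 SE bands to be discriminating while runs stay in the
minutes range on one CPU.

## Known limitations

- Within-cycle event ordering (death → transition → discontinuation) is a
  modelling choice; the discontinuation probability is evaluated at the
  post-transition state. Other orderings would perturb results at
  the size of one cycle's cross terms.
- A single cohort with a fixed male fraction weights the life table; sexes
  are not simulated as separate sub-cohorts.
- The drug-cost schema carries one monthly cost per arm; the
  utilisation-weighted construction of the SoC basket is left to config
  authors, since the engine only ever consumes the total.
- Coefficients are consumed as given (declared PH form); estimating them
  from patient-level data, utility mapping and cost micro-costing are out
  of scope.
- hHF counts are expected values in the cohort engine; the variance of
  recurrent admissions matters only to the micro-simulation oracle.
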