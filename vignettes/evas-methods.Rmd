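---
title: "Valuing additional states in Markov cohort models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing additional states in Markov cohort models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evas)
```

## The problem

Decision-analytic disease models trade realism against simplicity. Every
candidate complication added as a health state makes a model harder to
build, check and explain, so a modeller needs a principled way to ask:
*how much does this state actually contribute, and how robust is that
contribution to parameter uncertainty?*

This package implements a quantitative answer for Markov cohort models.
Let model A be the basic model and model B the same model augmented with
one candidate complication state. With discounted cumulative costs
$C_A, C_B$ (yen) and effectiveness $E_A, E_B$ (QALYs), the **value of the
additional state** converts both differences to the QALY scale with a
willingness-to-pay threshold $\lambda$ (yen per QALY):

$$V \;=\; \frac{C_B - C_A}{\lambda} \;+\; \left(E_A - E_B\right).$$

$V$ is positive when the complication adds cost and/or removes health —
i.e. when leaving the state out would misrepresent the disease. Repeating
the comparison over Monte-Carlo draws of the transition probabilities
gives per-trial values $v_1,\dots,v_n$; the **uncertainty** of the
additional state is their summed absolute deviation from the average,
$U = \sum_i |v_i - \bar v|$, and the **expected value of the additional
state** is

$$\mathrm{EVAS} \;=\; V_{\mathrm{cum}} - U, \qquad
  V_{\mathrm{cum}} = \sum_i v_i .$$

Candidate complications are then ranked by EVAS: a state with a large but
wildly uncertain contribution may rank below a smaller, more robust one.
Both quantities are reported on the cumulative scale (summed over the $n$
trials), mirroring how the case study tabulates them; per-trial means are
`cumulative / n`.

## The cohort engine

`cohort_model()` defines a discrete-time Markov cohort model: an ordered
set of `health_state()`s (utility in $[0,1]$ and annual cost attached per
state, one absorbing death state with utility and cost 0), a sparse
`transition_schedule()` keyed by (from, to, cycle), an initial
distribution, a horizon in annual cycles, and a discount rate.
`run_cohort()` propagates the occupancy distribution,
$\pi_{t+1} = \pi_t P_t$, and accrues rewards.

Numerical and timing conventions, chosen once and used consistently by
every oracle and test:

* **Cycle length is one year** — all case-study rates are annual — and
  **no half-cycle correction** is applied. This is deliberate and worth
  stating prominently: absolute cumulative costs and QALYs therefore sit
  a half-cycle "early" relative to a half-cycle-corrected engine. The
  method's outputs are *differences* between paired models, which are far
  less sensitive to this convention than the absolute totals.
* **Rewards accrue on start-of-cycle occupancy.** The year-$t$ QALY
  increment is $\sum_s \pi_t(s)\,u(s)\,(1+r)^{-t}$, so cycle 0 (the first
  model year) is undiscounted; `discount_factor(rate, cycle)` is
  $(1+r)^{-t}$. A consequence is that deaths during a cycle accrue no
  partial-year utility in the death cycle: mass that dies in cycle $t$
  was counted alive at the start of $t$ and contributes nothing
  afterwards. Whether partial-year accrual was intended by any particular
  source model is usually unstated; we flag the choice rather than guess.
* **Residual ("stay") probabilities are never read from configuration.**
  Only exits are specified; each row's residual $1-\sum(\text{exits})$ is
  assigned to the state's declared `residual_to` target (itself by
  default). This guarantees row-stochasticity by construction and errors,
  naming the state and cycle, whenever specified exits exceed 1.
* **Competing risks within a cycle are mutually exclusive**: event
  incidences and background mortality are added and subtracted from the
  residual, with validation rejecting any combination that exceeds 1.
* **Carry-forward**: cycles beyond `carry_forward_cycle` reuse the last
  specified probabilities, matching the convention of stating rates for
  early post-event years and holding the last one constant.
* **Time-since-event dependence uses tunnel states** — one sub-state per
  post-event year up to the carry-forward year, then a steady sub-state;
  survivors advance through the tunnel via the residual link. This is the
  only mechanism by which a memoryless chain can honor year-indexed
  post-event rates.
* **One-time costs**: event-entry costs (acute-phase hospitalization,
  recovery care) are attached to the year-1 tunnel state, which every
  entrant occupies for exactly one cycle; costs triggered by a transition
  itself (productivity loss at death) are `transition_costs`, charged to
  the flow along that transition in its cycle.
* Cycle indexing is 0-based internally; exported tables label years
  `1..horizon`.

`run_cohort()` is verified against an independent oracle that enumerates
every state path of small models (≤ 4 states, ≤ 5 cycles), weights each
path by its exact probability and accrues rewards along it; engine and
oracle agree to 10⁻⁹ across hundreds of random models.

## Probabilistic sensitivity analysis

Transition probabilities are sampled from beta distributions
parameterized by method of moments from a mean $\mu$ and an SD expressed
as a fraction $f$ of the mean ($\sigma = f\mu$):

$$\alpha = \mu\!\left(\frac{\mu(1-\mu)}{\sigma^2}-1\right),\qquad
  \beta = (1-\mu)\!\left(\frac{\mu(1-\mu)}{\sigma^2}-1\right).$$

The case study sweeps $f \in \{0.0625, 0.125, 0.25, 0.50\}$ ("±6.25% to
±50% of the SD from the mean"). We read that phrase as SD $= f \times$
mean; it is the only reading that produces the observed near-exact
doubling of cumulative uncertainty from one range to the next.
`beta_from_mean_sd()` enforces the feasibility bound
$\sigma^2 < \mu(1-\mu)$ and errors with the parameter's name when an SD
range is too wide for a probability.

Sampling design (`psa_uniforms()` / `sample_trial_params()`):

* One uniform draw per (trial, parameter) from a single root seed; the
  sampled value is the beta quantile of that uniform.
* **Common random numbers, twice over.** Within a trial, models A and B
  are rebuilt from the *same* sampled values, so sampling noise in shared
  states cancels in $v_i$ and the uncertainty statistic reflects
  predominantly the additional state. Across SD ranges, the same
  uniforms are pushed through wider or narrower betas, so a sweep is a
  smooth deformation of one set of trials rather than four independent
  experiments. Whether the original analysis paired its draws this way is
  not stated anywhere we could check; pairing is this package's design
  decision, documented as such.
* All transition probabilities of both models are sampled; utilities,
  costs, the mRS discharge allocation and the background life table are
  held fixed (distributions are assigned to clinical transition
  parameters only).
* `(seed, n_trials, specs)` fully determine every output, bit for bit.

## The grade-I hypertension case study

`build_base_model()` assembles the basic stroke model of a cohort of
55-year-old men followed for 10 years: a hypertensive-well state (utility
1), a first-stroke branch allocated at hospital discharge over modified
Rankin Scale bands mRS 0–5 (utilities 1, 0.83, 0.67, 0.45, 0.24, 0.09,
held constant over time), post-stroke mortality 20.7%, 6.7%, 5.8%, 5.9%,
5.9% in years 1–5 since the stroke (carried forward thereafter) realized
as 6 × 5 tunnel states, background all-cause mortality from the life
table in every alive state, and death. Annual first-stroke incidence is
4.9/1000; the analysis assumes no treatment effect, because the point is
the value of model states, not of an intervention.

Three single-complication augmentations (`with_recurrence()`,
`with_chd()`, `with_esrd()`):

* **Stroke recurrence** — 12.9% in the first post-stroke year, 8.2% in
  later years — is realized as re-entry transitions into the year-1
  tunnel state of the *same* mRS band: the mortality clock restarts
  (recurrent strokes reuse the first-stroke schedule), acute-phase costs
  are charged again, and disability remains constant. No new states are
  needed; the tunnel already encodes time since the latest stroke, so
  this augmentation adds transitions, not states.
* **CHD** — incidence 1.17/1000 from the well state; an entry-year state
  (7% in-hospital mortality, acute hospitalization cost, utility 0.68)
  then a chronic state (20.4/1000 annual mortality carried forward,
  utility 0.72).
* **ESRD** — incidence 0.21/1000 from the well state; one state with
  9.7% annual mortality, utility 0.75 and an annual cost set by the
  treatment mode, dialysis or conservative management.

Complication states are mutually exclusive: CHD and ESRD incidence apply
to the well state only, and a post-stroke patient cannot enter them. This
follows the one-addition-at-a-time structure of the comparison (each
augmented model adds exactly one branch, and stacking two augmentations
is an error). Whether incidence should also apply to post-stroke states
is not specified by the sources; restricting it keeps the augmentations
orthogonal.

### Synthetic stand-ins, and what the tests do and do not show

The published case study depends on three inputs that are not printed in
it: the itemized yen costs (a supplementary file), the mRS discharge
allocation, and the Japanese life table. The package ships clearly
labelled synthetic stand-ins, each flagged `"synthetic": true` in the
bundled parameters file and in every run manifest:

* **Costs** (yen): stroke acute-phase hospitalization 1.5M, recovery-phase
  care (≈ 88 days) 2.0M, ambulant care 0.2M/yr, nursing care (mRS 2–5,
  until death) 1.2M/yr; CHD acute hospitalization (≈ 25 days, with
  revascularization) 3.5M, ambulant cardiology care 0.4M/yr; ESRD
  dialysis 5.0M/yr vs conservative management 0.6M/yr plus 0.1M/yr clinic
  visits. CHD carries no nursing-care or productivity cost (little
  lasting functional impairment). The values were chosen once, at
  realistic Japanese magnitudes, so that each complication's cost/QALY
  split has the same order of magnitude as the printed splits; they are
  *not* the study's actual costs, and absolute reproduction of the
  printed cumulative values is explicitly not claimed.
* **Productivity loss**: a flat synthetic wage of 4.0M yen/yr, charged at
  death from a post-stroke state for each year from the age at death to
  64 (retirement at 65). Following the cost-category grid, it applies to
  stroke deaths only (any mRS band), not to CHD/ESRD deaths or background
  deaths from the well state.
* **Life table**: $q(\mathrm{age}) = 0.005\,e^{0.08(\mathrm{age}-55)}$,
  capped at 0.99 — annual all-cause mortality rising smoothly from 0.005
  at 55 to ≈ 0.010 at 64, the right scale for middle-aged men. Because it
  is synthetic, the package's annualized overall mortality
  (`overall_mortality_rate()`) is a scale sanity check, not an
  external-validity result.
* **mRS discharge allocation**: (0.15, 0.25, 0.20, 0.15, 0.15, 0.10) over
  mRS 0–5 — a plausible discharge mix, overridable in configuration.

Consequently the test suite verifies the *method* — engine correctness
against enumeration, beta moment recovery, linear scaling of the
uncertainty statistic, EVAS monotonicity in the SD range, the identity
EVAS = value − uncertainty on the transcribed printed table, and the
robust ranking (CHD first, conservative ESRD last) — and does not verify,
on real data, the absolute printed magnitudes, which no desk
re-implementation lacking the unprinted inputs could honestly reproduce.

### The transcribed printed table

`load_table4_fixture()` returns the checksummed transcription of the
printed cumulative results (value, uncertainty and EVAS per complication,
SD range and discount rate). One printed cell — ESRD with dialysis,
±25% SD, discounted — reads value 137, uncertainty 27, EVAS 120, which
contradicts EVAS = value − uncertainty by 10. The cell is flagged
`inconsistent` and excluded from identity assertions; we do not guess
which of the three numbers was misprinted. Two further cells differ from
the identity by exactly 1, which integer printing explains.

## Reported scales and numerical choices

* Per-range results report cumulative value, cumulative uncertainty and
  EVAS at each discount rate (3% and 0% by default, the undiscounted run
  accrued from the same occupancy traces). Each row satisfies
  `evas = cumulative_value - cumulative_uncertainty` exactly.
* The printed-style wide table (`evas_table()`) shows one value column
  per complication; since the SD ranges share underlying draws, their
  cumulative values differ only by Monte-Carlo noise and the narrowest
  range's value is printed. Whether a printed "value of additional
  state" is the sum of trial values or `n` times the deterministic value
  is ambiguous in general; the sum is the default and
  `value_method = "deterministic"` exposes the alternative.
* Display rounding is to the nearest integer on the cumulative scale;
  CSV exports keep full precision.
* Ties in `rank_states()` break alphabetically and are flagged; the
  ranking also reports whether uncertainty reorders the value-based
  ranking — the situation the method exists to detect (in the case study
  it is the dialysis-vs-recurrence pair).
* Degenerate inputs: a horizon of 0 returns the initial occupancy with
  zero rewards; an SD fraction of 0 fixes parameters at their means and
  reproduces the deterministic run; zero-probability declared edges are
  legal (they keep a structure valid under degenerate parameterizations).

## Problem sizes used by the shipped checks

The bundled tests run the engine-vs-enumeration comparison on 200 random
small models, beta moment recovery at 10,000 draws per parameter and SD
range, uncertainty-scaling on a toy model whose per-trial value is
exactly linear in one sampled probability at 10,000 trials per range, and
the full case-study pipeline at 2,000 trials per SD range; the
command-line default remains 10,000 trials. These sizes are the package's
own choice of a thorough-but-quick regression surface; all of the
statistics scale as $1/\sqrt{n}$ and none of the qualitative conclusions
change at 10,000 trials.

## Known limitations

* Cohort (expected-value) simulation only: no individual-level
  microsimulation, no continuous-time semantics, no half-cycle or
  Simpson-type corrections, and no treatment comparators.
* The uncertainty statistic is the summed absolute deviation over trials;
  it is not a confidence interval, an EVPI, or an acceptability curve,
  and the package deliberately computes none of those.
* All transition parameters of a state share one SD range in the sweep;
  real parameter uncertainty is heterogeneous, and a real application
  should replace the common fraction with parameter-specific evidence.
* The threshold $\lambda$ linearly rescales only the cost term of $V$,
  so rankings can change with $\lambda$; 5,000,000 yen/QALY is the
  default, not a recommendation.
* With synthetic costs, wages, life table and discharge allocation, the
  case study is a *runnable fixture* of the method, not a reproduction of
  the published absolute values.
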