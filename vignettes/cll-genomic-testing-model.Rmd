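---
title: "A Markov cohort model of genomic testing-guided CLL treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model of genomic testing-guided CLL treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The decision problem

Fit ("go-go") patients with chronic lymphocytic leukaemia are usually offered
FCR (fludarabine + cyclophosphamide + rituximab) chemotherapy first line, but
roughly a quarter do not respond or relapse early, largely driven by *TP53*
lesions. Two kinds of pre-treatment test can redirect likely non-responders to
other therapy: low-resolution genetic testing (FISH + Sanger sequencing of
*TP53*) and genomic testing (a targeted NGS panel), the latter flagging more
true non-responders. The expensive alternative therapy is ibrutinib, a BTK
inhibitor taken continuously until non-response.

`cllcea` evaluates five test-treatment strategies from the perspective of the
UK NHS (with a societal extension):

* **A** - genetic testing; *TP53*-wild-type patients receive FCR/BR
  chemotherapy lines, then refractory ofatumumab (a proportion consolidated
  with allogeneic transplant, BMT); *TP53*-mutated patients receive
  ofatumumab (± BMT) then a second ofatumumab course.
* **B** - as A, but the refractory treatment for everyone is ibrutinib.
* **C** - no testing; everyone follows the wild-type pathway of A, and
  because no testing happens there is no route from first-line treatment to
  refractory therapy (emerging high-risk mutations cannot be recognised).
* **Int1** - genomic testing; likely non-responders receive first-line
  ibrutinib until non-response, then best supportive care (BSC); likely
  responders receive FCR/BR with a 20% improvement in mortality,
  non-response and progression (the effect of correctly targeted treatment),
  then refractory ibrutinib.
* **Int2** - as Int1, but likely non-responders receive first-line
  ofatumumab (± BMT) and ibrutinib at the refractory line.

Genomic strategies re-test before every new treatment line, so the test cost
recurs per line; genetic strategies test once on entry.

## Model structure

The engine is a cohort Markov model with 28-day cycles (one chemotherapy
cycle) over a 30-year horizon: `floor(30 * 365.25 / 28) = 391` whole cycles,
no partial final cycle. Each FCR/BR/ofatumumab line is expanded into six
tunnel states so that the six-cycle treatment maximum is enforced; patients
can leave any tunnel state for the next line (non-response) or death.
Ibrutinib has a single unbounded treatment state, as treatment continues
until non-response. Patients undergoing BMT pass through a dedicated
one-cycle tunnel carrying the full transplant cost, then a BMT remission
state. CLL-related death is reachable from every non-remission state;
other-cause death from every alive state.

Transition rows follow an additive competing-risk convention: each row lists
its event probabilities (non-response, progression, CLL death), the
age-dependent other-cause probability is added, and the residual mass goes to
the state's persistence target (next tunnel state, remission, or itself). A
negative residual - competing probabilities summing above one - is an error
that names the state, rather than something to silently renormalise. This
convention makes the engine exactly checkable against brute-force path
enumeration, which the test suite does on small models at 1e-8.

Other-cause mortality is the only time-varying quantity: a Gompertz annual
hazard `a * exp(b * age)` converted per cycle via
`p = 1 - exp(-h * 28/365.25)` (the same rate-to-probability convention is
used everywhere). Defaults (`a = 2.7e-5`, `b = 0.095`) put the annual hazard
at 65 near 0.013, i.e. a residual life expectancy of roughly 20 years, so the
30-year horizon is effectively lifetime for the base cohort. Treatment
efficacy probabilities are time-homogeneous within a state; the benefit of
ibrutinib is constant over the model course by default, with an optional
waning switch (`ibr_waning_rate`, a per-cycle multiplicative increase of the
ibrutinib non-response probability) that is off by default.

Costs and outcomes accrue from half-cycle-corrected occupancies (the
trapezoid of successive cycle boundaries), applied exactly once, to both
costs and outcomes (each side is switchable). One-off costs - tests on line
entry, societal event costs - are charged on state *arrival* at the arrival
cycle's discount factor, not half-cycle corrected, since they are events
rather than occupancies. Both costs and outcomes are discounted at 3.5% per
year, as `(1 + r)^(-cycle * 28/365.25)`.

## Parameters

Everything the model consumes is a named scalar in a `cll_parameter_set`:
value, low/high range, distribution family (`beta` for probabilities,
utilities and proportions; `gamma` for costs and rates; `fixed`) and a
variance source. Sets are read and written as YAML
(`schema: cllcea-parameters/1`); loading validates ranges, role/distribution
consistency and completeness against all five strategies, and unknown keys
are rejected.

The per-cycle state costs (GBP, 2013 price year) and the utility weights are
published and embedded verbatim as fixtures (`published_state_costs()`,
`published_utility_weights()`). First-, second- and subsequent-cycle chemotherapy
costs are distinct keys; two gaps in the printed table are bridged
explicitly: Intervention 2's ofatumumab second/subsequent first-line cycles
are bound to the A/B values, and genomic-strategy responders are modelled
FCR-then-BR only (the printed table prices no second-line FCR for the
interventions, so the BR-first ordering exists only in A/B/C, where a
`p_first_line_br` share of patients starts on BR).

The ibrutinib per-cycle cost is decomposed into a drug component of 2,300
GBP - an annual cost of 30,000 GBP at 13.04 cycles/year, the assumed UK
price - plus non-drug care of 404 GBP (interventions) or 480 GBP (strategy
B), reproducing the published per-cycle totals of 2,704 and 2,780 GBP. The
drug component is the scenario and threshold lever, which is why the
published "reduced by 75% to 575 GBP per cycle" scenario corresponds to a
multiplier of 0.25.

Utility weights are treated as already adjusted for complication rates
(`utility_mode = "pre-adjusted"`, the default). A second mode applies
`utility - rate * 0.133` per treatment state from explicit per-cycle
grade-3/4 complication probabilities, for users who supply unadjusted
weights.

## The synthetic parameter generator

The published article prints the fixtures above, the test-accuracy
proportions, and the analysis settings - but the transition probabilities,
complication rates and societal unit costs live in supplementary appendices.
`generate_parameter_set()` therefore synthesises a complete, internally
consistent world around the printed constraints; it is the study-conditions
generator, not a fitting device, and its defaults are fixed:

* Responder-status FCR probabilities are anchored so that the implied
  36-month progression-free proportions bracket the printed residual-group
  figure (0.69): first-line per-cycle non-response 0.010, CLL death 0.003,
  remission progression 0.0062 for responders, with TP53-mutated multipliers
  of 4-6 on FCR/BR. Ofatumumab is only mildly status-dependent (multiplier
  1.2) - the clinical rationale for stratifying mutated patients to it.
* Ibrutinib's per-cycle non-response is 25% of refractory ofatumumab's
  (median time on treatment about 3.5 years), strictly below it by
  construction at any `efficacy_ordering_strength`.
* The genetic test flags 7% of patients (78% true positives); the genomic
  test 17% (82%). The test-negative group is split into true and false
  negatives by solving the mixing weight at which the residual group's
  implied 36-month PFS equals 0.69; with the default curves this implies a
  non-responder prevalence near 0.16, and the genomic test's residual PFS
  figure is derived from that same prevalence, so both tests describe one
  underlying population.
* Lognormal noise with coefficient of variation `noise_cv` (default 0.10)
  perturbs generated values; ordering constraints are enforced by floors, so
  they hold strictly at every noise level, and `noise_cv = 0` returns the
  deterministic defaults. Generation is seeded and bit-reproducible, and
  restores the caller's RNG state.
* Societal unit costs (daily wage 74 GBP, friction period 90 days, informal
  care 15 GBP/hour, age-banded employment rates, per-state care hours and
  out-of-pocket costs) are scaled so the 65-year-old societal increment is a
  few thousand GBP per patient while the 25-year-old human-capital increment
  reaches several hundred thousand - the orders of magnitude the published
  societal tables display.

The shipped `inst/extdata/base_case.yaml` is the generator's deterministic
default (seed 2013, `noise_cv = 0`), also available as
`default_parameter_set()`.

What passing tests on this generated world do and do not show: the engine,
stratification, dominance analysis, sensitivity machinery and societal
accounting are exercised end to end under realistic structure and printed
constraints, but the generated transition values are not the unpublished
supplementary values, so per-strategy means and optimal strategies in this
world are not expected to equal the published ones numerically. The direct
numerical contact with the published results is the incremental analysis
recomputed from the printed per-patient means (`frontier_from_table()` on
`reference_results()`), which reproduces every printed dominance label.

## Incremental analysis

`frontier()` sorts strategies by ascending cost, marks strict dominance
(costlier and no more effective; exact ties keep the earlier-listed
strategy), ladders ICERs over the survivors, then removes extendedly
dominated strategies - ICER at least that of the next more effective
strategy - iteratively, recomputing the ladder after each removal, until the
frontier's ICERs strictly increase. `optimal_at(lambda)` returns the
highest-effect frontier strategy whose ICER does not exceed the
willingness-to-pay, which provably coincides with the net-monetary-benefit
argmax; the tests cross-check both, and check the whole algorithm against an
independent monotone-chain convex-hull oracle on random instances.

## Uncertainty analysis

Univariate analysis varies each parameter to its stored low/high (±50% of
base unless a range is supplied, truncated to valid ranges) and reports the
optimal strategy at 30,000 GBP. Scenarios 1-7 cover the ibrutinib price
multiplier (0.25 by default), the 56,000 GBP/year list price, the 40%
responder effect, starting ages 25/85, 10- and 50-year horizons, and
equalising the genomic test's cost and accuracy with the genetic test's.
The id-2 and horizon scenarios are this package's reading of the otherwise
unnamed slots in the seven-scenario scheme. Threshold analysis bisects a
single parameter (default tolerance 1 GBP) for the value at which a target
strategy becomes optimal, verifying decision monotonicity at the bracket
ends.

The PSA samples every non-fixed parameter independently (no correlation
structure is published): beta or gamma by role, method-of-moments
parameterisation, `sd = 0.10 * mean` when no variance is reported. Event
probabilities sharing a transition row are renormalised if their sampled sum
exceeds 0.95 (leaving room for other-cause mortality), and the event count is
logged on the result. Acceptability curves count, per threshold on a
0-100,000 GBP grid in 2,500 GBP steps, the fraction of draws in which each
strategy maximises net monetary benefit, splitting exact ties evenly so the
probabilities sum to one.

## Societal perspective

Three cost categories are added to NHS costs, outcomes untouched:

* **Productivity** (friction-cost): chemotherapy and BMT tunnels accrue
  absenteeism by tunnel index until the 90-day friction period is exhausted;
  open-ended episodes (ibrutinib treatment, BSC) are charged one friction
  period on entry; remission accrues a small intermittent absence.
* **Informal care and out-of-pocket** costs per cycle by state group.
* **Premature mortality**: production losses on entry into CLL-death states
  for deaths before retirement age. Although the friction-cost approach is
  named for absenteeism, the published 25-year-old societal costs are far too
  large for friction-period losses alone, so mortality losses default to the
  human-capital approach (wage times employment rate summed to retirement),
  with `mortality_cost_approach = "friction"` available as a switch.
  Other-cause deaths carry no disease-attributable production loss.

A zero specification reproduces the NHS perspective exactly, which the tests
assert, along with societal >= NHS costs and identical health outcomes.
Nursing-home admission costs are deliberately excluded.

## Numerical choices and degenerate inputs

One cycle is 28/365.25 years everywhere (discounting, life-years, ageing).
Occupancy conservation is enforced at 1e-10 over all 391 cycles. Equal-cost
equal-effect frontier ties are broken toward the earlier-listed strategy for
deterministic output; zero effect differences make the ICER undefined and are
handled by dominance logic rather than returned as infinities. Beta sampling
clips an infeasible standard deviation to 95% of the feasibility bound;
parameters at exactly 0 or 1 are treated as fixed. The acquired-*TP53* route
(first-line remission to refractory therapy) exists in strategies A and B
only: C cannot recognise emerging mutations, and the genomic strategies'
responders already route to refractory ibrutinib through ordinary
progression.

## Problem sizes

The shipped analyses use the full 391-cycle horizon and all five strategies
throughout; the PSA uses 1,000 draws (the published simulation count). Test
oracles that enumerate exhaustively (path enumeration, hull comparison) run
on models of up to 4 states and 10 cycles, and 1,000 random frontier
instances of up to 6 strategies - sizes where exhaustive enumeration is exact
and fast.

## Known limitations

The generated parameter world is structurally faithful but numerically its
own: conclusions about *which* strategy is optimal in that world are
illustrations of the machinery, not reproductions of the published
base case. Utilities are line-specific, not treatment-specific. The model is
a cohort model: no patient-level heterogeneity beyond the test-defined
subcohorts, and no microsimulation mode. Treatment-efficacy probabilities do
not vary with time on treatment apart from the optional ibrutinib waning
switch. PSA draws are independent across parameters. Only the five published
strategies are wired; the strategy set is fixed by design.
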