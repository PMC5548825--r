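# cllcea

Cost-effectiveness modelling of genomic testing-guided treatment in chronic
lymphocytic leukaemia (CLL).

Pre-treatment testing can redirect CLL patients who are unlikely to respond to
standard FCR chemotherapy (mostly carriers of *TP53* lesions) to targeted
therapy with ibrutinib — but ibrutinib costs far more than the tests that
select patients for it, so whether test-guided stratification is worth paying
for is an economic question. This package implements, as reusable and tested
R code, a Markov cohort model that answers it for five test-treatment
strategies in the UK NHS: three current-practice comparators (A: genetic
FISH/Sanger testing with FCR-based pathways; B: the same with ibrutinib as
refractory treatment; C: no testing) and two genomic-testing interventions
(Int1: likely non-responders get first-line ibrutinib; Int2: they get
first-line ofatumumab then refractory ibrutinib). It is written for health
economists and methodologists who want a scriptable, fully seeded version of
this class of evaluation.

## The model in brief

* Cohort Markov model, 28-day cycles, 30-year horizon (391 cycles), cohort
  entering at age 65, six-cycle chemotherapy lines enforced by tunnel states,
  a single unbounded ibrutinib state, a one-cycle BMT tunnel, and
  age-dependent (Gompertz) other-cause mortality.
* Per-patient discounted (3.5%/year) mean costs $C_s$ and effects $E_s$
  (life-years for the CEA, QALYs for the CUA) with half-cycle correction.
* Incremental analysis: strategies sorted by cost, strictly dominated and
  extendedly dominated comparators excluded, ICERs
  $\Delta C / \Delta E$ laddered along the frontier, and the optimal strategy
  at willingness-to-pay $\lambda$ chosen where the ICER stays below
  $\lambda$ (equivalently, by maximal net monetary benefit
  $\lambda E_s - C_s$).
* Uncertainty: univariate ±50% sensitivity analysis, seven scenario analyses,
  threshold search on the ibrutinib price, and a 1000-draw probabilistic
  sensitivity analysis (beta/gamma distributions by method of moments,
  CV = 0.10 default) summarised as cost-effectiveness acceptability curves.
* A societal costing extension: friction-cost productivity losses, informal
  care, out-of-pocket costs and premature-mortality production losses.

The published per-cycle state costs and utility weights are embedded verbatim
as fixtures. Every unpublished scalar (transition probabilities, complication
rates, societal unit costs) comes from a seeded generator of complete,
internally consistent parameter sets that honours the printed constraints —
see the methods vignette (`vignettes/cll-genomic-testing-model.Rmd`) for what
that generated world does and does not share with the published one.

## Worked example

```r
library(cllcea)

ps <- default_parameter_set()     # seeded generator defaults; also shipped as
                                  # inst/extdata/base_case.yaml
bc <- run_base_case(ps)
print(bc$results[, c("strategy", "cost", "ly", "qaly")], digits = 5)
#>   strategy   cost      ly   qaly
#> 1        A  87991  8.4972 7.5073
#> 2        B 130711  9.2700 7.7863
#> 3        C  92449  8.5752 7.5599
#> 4     Int1 108146  9.9699 8.6414
#> 5     Int2 110637 10.1676 8.7450

print(bc$cua)
#> <cll_frontier (qaly)>
#>   strategy     cost  effect   label icer_excl_dom icer_excl_ext_dom
#> 1        A  87991.2 7.50728                    NA                NA
#> 2        C  92448.9 7.55985 EXT.DOM       84798.4                NA
#> 3     Int1 108145.7 8.64142               14513.0           17770.7
#> 4     Int2 110636.9 8.74505               24041.0           24041.0
#> 5        B 130710.9 7.78632     DOM            NA                NA
```

Read: in this generated parameter world strategy A is cheapest (£87,991 per
patient) and Int2 yields the most QALYs (8.745). B is dominated (costlier and
less effective than Int2), C is extendedly dominated, and the remaining
ladder climbs from A through Int1 (£17,771/QALY) to Int2 (£24,041/QALY), so
Int2 is the optimal choice at the £30,000/QALY threshold in this world.

Feeding the *published* per-patient means through the same frontier operation
reproduces the published incremental analysis:

```r
fr <- frontier_from_table(reference_results("nhs"), "qaly")
fr$dominated               # character(0)
fr$extendedly_dominated    # "B"  "Int2"
fr$frontier                # "C"  "A"  "Int1"
fr$optimal_at(30000)       # "A"
```

The numbered scripts under `analysis/` walk the full study: parameter world
(`01`), deterministic base case (`02`), incremental analysis of the published
means (`03`), univariate/scenario/threshold analyses (`04`), PSA and CEACs
(`05`, `--seed`/`--n-sims` flags), and the societal perspective at ages 65
and 25 (`06`). Each writes its tables under `results/`.

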