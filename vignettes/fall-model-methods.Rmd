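---
title: "Methods: consensus analysis and microsimulation structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus analysis and microsimulation structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallsim)
```

## Overview

`fallsim` implements both halves of the conceptualization of an economic
model for fall prevention in older adults (65+): the *consensus analysis*
that selected which health states, events and patient attributes matter, and
the *individual-level state-transition (microsimulation) engine* that embodies
the resulting six-state structure. Because the conceptual model deliberately
carries no empirical parameter values, a synthetic scenario layer supplies
internally consistent defaults so the engine and the cost-effectiveness
machinery can be exercised and tested end to end.

## The modified Delphi consensus engine

An eleven-member expert panel rated candidate items on a 0–5 Likert scale
with an explicit "Don't Know" option, over two survey rounds (all eleven
responded in round 1; ten in round 2). The package ships the full rating
distributions as a fixture (`delphi_fixture_path("ratings")`; 96 item-round
rows) together with the published per-item panel averages and classification
blocks used for validation.

The classification rule is:

* **Inclusion** — at least 80% of respondents rate the item 4 or greater;
* **Exclusion** — at least 80% rate it 2 or less;
* **Non-consensus** — everything else; these items are re-rated in the next
  round alongside newly proposed items, and the process stops when no items
  remain or after three rounds.

Two numerical choices deserve comment, both validated against every fixture
row before being frozen:

1. **The denominator excludes "Don't Know" responses.** The rule's prose
   ("% of respondents") does not fix the denominator. Only the
   informative-respondent denominator reproduces the published outcomes: a
   boundary item with ratings 4+ from 8 of 10 informative respondents is
   included (8/10 = 80%), whereas 8/11 = 72.7% would not be; and the
   published mean 4.89 for the top-rated fracture item is exactly 44/9, the
   informative mean. Panel averages use the same denominator.
2. **Threshold comparison is `>=` in exact rational arithmetic.** 8/10
   compared against 0.80 must not fail by floating-point representation, so
   the comparison multiplies through by a rationalized denominator instead
   of comparing doubles.

Published averages are reproduced with half-up rounding to two decimals
(e.g. 31/8 = 3.875 prints as 3.88). Half-up matches every one of the 96
published values; the rounding convention is inferred from the tables rather
than stated, which is why the raw quotient is also retained. A checksum test
guards the fixture transcriptions against drift.

One bookkeeping subtlety: the survey documentation gives both 23 and 24 as
the number of health states/events ever rated. The tables support 24
distinct items (20 in round 1, plus ankle fracture, humerus fracture,
alternate level of care and transitional care unit added in round 2); the
fixtures follow the tables. Dementia/cognitive impairment was rated twice —
once as a biological risk factor and once as a health condition — and is
kept as two distinct item ids, as in the source tables.

Running the rule over the fixtures reproduces the published outcomes
exactly: 9 of 20 health states/events and 18 of 38 attributes included in
round 1, five and eight more in round 2, no exclusions anywhere, and
cumulative inclusion sets of 14 health states/events and 26 attributes.

```{r delphi}
hs <- delphi_analysis("health_state_event")
hs$rounds[[1]]$tally
length(hs$included)
```

## From consensus items to model structure

The 14 included health states/events cannot all be model states (they are
not mutually exclusive — one can have a hip fracture *and* be hospitalized),
so the schema uses care settings as states: community, residential aged
care, hospital, rehabilitation hospital, death due to a fall, and death from
other causes. Death-other was added despite not being panel-selected, to
make the state set exhaustive over a lifetime horizon; it is kept distinct
from fall death so attributable mortality is reportable.

`incorporation_report()` documents the mapping: 5 items become states, 7
become tracked events (12 incorporated), "post-fall" is folded into event
history as a recency flag, and specialized dementia care is folded into the
community state — adding one specialized sub-setting while omitting the
others (independent supported living, assisted living, short-term stays,
all non-consensus) would have been inconsistent, so all supportive-housing
variants live inside the community state.

The transition topology is encoded as an explicit edge list because the
published structure diagram does not enumerate edges textually. The default
is: community ↔ residential aged care; either living setting → hospital
(gated on an emergency department visit in the same cycle, reflecting how
community-dwelling Canadians are admitted after a fall); hospital →
{rehabilitation, community, residential aged care}; rehabilitation →
{community, residential aged care}; every living state → both death states.
Whether residential aged care → community moves occur is not specified
anywhere; the default topology permits them with a per-cycle probability
that can be set to zero, so the question is a configuration choice rather
than a code change. Injury definitions follow the clinical clarifications:
head injury means intracranial bleed; moderate injuries are dislocations or
fractures not named elsewhere; minor injuries are soft-tissue injuries. Only
a hip fracture can trigger hip surgery, and surgery requires admission.

The attribute registry fixes the 26 consensus attributes. Value kinds are
not specified by the survey, so the default is parsimonious: binary flags
except age (continuous) and polypharmacy (a medication count).

## The microsimulation engine

Cycles are 14 days — the resolution at which "at most one fall per cycle"
was judged clinically reasonable for the target population (it is knowingly
wrong for very frequent fallers, who are outside the model's scope). Each
cycle executes a fixed draw order: background (non-fall) mortality; a single
fall draw for individuals in a living setting; a single injury draw
conditional on the fall; the pathway cascade (ED visit → admission → hip
surgery); fall death conditional on injury; then length-of-stay and
relocation bookkeeping. The order is fixed because reproducibility demands
one; nothing in the source material dictates it.

Engineering choices:

* **Fall probability.** Attributes and history act multiplicatively on a
  per-cycle rate λ, with `p = 1 − exp(−λ·m)`; this keeps p in [0, 1] for any
  multiplier product. History effects cover any prior fall, any prior
  injurious fall, and a fall within the previous `recent_fall_window` cycles
  (default 6, the "post-fall" construct; its multiplier defaults to a
  neutral 1.0).
* **Falls occur only in community and residential aged care** by default
  (the interventions of interest are community-based; in-hospital falls are
  out of scope). A flag re-enables them.
* **Lengths of stay are geometric** (memoryless) with configurable means, so
  the homogeneous limit of the engine is exactly Markov; fixed durations are
  available by configuration.
* **Background mortality is Gompertz-shaped** (exponentially age-increasing
  hazard) with synthetic parameters; any per-cycle schedule can be
  substituted via the constant-rate model or a replacement function block.
* **Random numbers**: each individual owns one L'Ecuyer-CMRG stream derived
  from the master seed, split into named substreams per purpose (mortality,
  fall, injury, pathway). Results are independent of the order individuals
  are simulated, identical cohorts are byte-reproducible, and adding draws
  to one purpose never perturbs another — which is also what makes common
  random numbers across intervention arms exact.

The engine's key structural guarantees — one fall per cycle, one injury per
fall, absorbing death states, occupancy conservation — are audited in the
test suite on every run, and `multiple_injury_share()` exposes the
one-injury audit to users (it is 0 by construction on engine output; the
assumption is a known limitation of the structure, adopted because only
about 2% of older adults report multiple injuries from one fall).

### The homogeneous Markov limit

The stated rationale for microsimulation is heterogeneity and history
tracking, so the homogeneous, history-free limit of the engine must agree
with a cohort Markov chain. The test suite collapses the within-cycle draw
tree into a 6×6 transition matrix by independent enumeration and compares
occupancy at cycles 1, 10 and 50 for 20,000 simulated individuals against
the matrix powers, within three binomial standard errors per cell. The
binomial law of fall counts under constant hazard (mean within 3 SE at
10,000 individuals over 30 cycles) is checked the same way. These problem
sizes were chosen to make three standard errors a tight band while keeping
the default suite fast.

## Synthetic scenarios

Every hazard, probability, cost and utility in
`generate_default_scenario()` is a synthetic default — the conceptualization
supplies none — and the scenario metadata records `provenance = "synthetic
default"` so no number can be mistaken for an estimate. Magnitudes were
chosen once for plausibility: community fall rates around 0.3
falls/person-year (residential aged care ~5× higher), an injury split in
which most falls are uninjurious and hip fractures are rare but severe, ED
and admission probabilities increasing with injury severity, hospital stays
of a few weeks, and a 1.5% annual discount rate (the convention of Canadian
economic-evaluation guidance). Passing tests therefore demonstrate the
*mechanics* — classification, topology enforcement, distributional
convergence, accounting identities — not calibration to any real population;
none of the package's numerical outputs should be read as estimates for any
health system.

Intervention arms mirror the seven effective intervention bundles of the
2017 network meta-analysis that motivates the model (exercise alone and in
combinations with vision assessment, environmental assessment, and other
co-interventions), plus usual care. Effects act as homogeneous rate ratios
on the fall hazard only — the simplest mechanism consistent with how the
bundles were evaluated; nothing specifies how attribute heterogeneity should
modify effects, so no effect modification is applied by default. Intervention
effects on injury splits are likewise not modelled (configurable in
principle by editing the scenario's split matrix per arm).

## Economics

Costs and QALYs accumulate per cycle with start-of-cycle discounting,
`d(t) = (1+r)^(−t·Δ/365)` for cycle length Δ days, and no half-cycle
correction — event timing is already cycle-resolved in a microsimulation, so
the usual correction for cohort models would add nothing. State costs and
utilities attach to the setting occupied during the cycle; injury costs and
one-time QALY decrements attach to the event cycle. Setting `r = 0`
reproduces undiscounted sums exactly, and constant streams match the
geometric-series closed form to 1e-9 relative error (both tested).

`incremental_analysis()` implements the standard frontier algorithm: sort by
mean cost, drop strictly dominated arms, drop extended-dominated arms
(strictly non-monotone adjacent ICERs), then report adjacent ICERs and net
monetary benefit. Ties on both cost and effect are flagged and resolved
deterministically by arm id with an undefined ICER. Cross-arm comparisons
default to common random numbers: the population and all random streams are
shared across arms, so arms differ only through intervention effects and
costs.

The analytic perspective is deliberately unfixed: cost categories are a
flat, user-defined list in the scenario, so a payer or societal set can be
expressed without code changes.

## Known limitations

* At most one fall per cycle and one injury per fall; results do not apply
  to very frequent fallers.
* No probabilistic sensitivity analysis, CEACs or value-of-information
  machinery; the scenario layer is a single deterministic parameter set.
* Fear of falling is a static attribute, not a dynamic state (it reached
  consensus only as an attribute).
* All parameter magnitudes are synthetic; conclusions about real
  cost-effectiveness require replacing the scenario with estimated inputs.
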