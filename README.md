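# fallsim

Consensus analysis and individual-level state-transition (microsimulation)
modelling for the economics of fall prevention in older adults.

Falls are the leading cause of injury hospitalization among adults aged 65
and over, and a family of community-based prevention bundles (exercise,
vision assessment, environmental assessment, and their combinations) is
known to reduce fall rates. Comparing those bundles economically requires a
decision model, and building that model requires two things this package
implements as working, testable code:

1. **A modified-Delphi consensus engine.** An expert panel rates candidate
   health states/events and patient attributes on a 0–5 scale across survey
   rounds. An item is **included** when ≥ 80% of informative respondents
   (those not answering "Don't Know") rate it 4 or above, **excluded** when
   ≥ 80% rate it 2 or below, and **non-consensus** otherwise — non-consensus
   items carry forward and are re-rated. The package ships the full
   two-round rating tables of the fall-model survey as fixtures and
   reproduces every published classification and panel average exactly
   (9/20 health states/events and 18/38 attributes included in round 1,
   5 and 8 in round 2; 14 and 26 cumulatively).

2. **A six-state microsimulation engine.** States are care settings —
   community, residential aged care, hospital, rehabilitation hospital,
   death due to a fall, death from other causes — and clinical detail lives
   in tracked per-individual events (fall, the four named injuries plus
   moderate/minor categories, ED visit, admission, hip surgery). Each
   14-day cycle allows at most one fall and each fall at most one injury.
   Fall probability is `p = 1 − exp(−λ·m)` where `m` multiplies in attribute
   and history effects. Hospital admission from a living setting is gated on
   an ED visit; rehabilitation is entered only from hospital; hip surgery
   requires a hip fracture and admission. Each individual draws from named
   per-purpose random substreams of one master seed, making cohorts exactly
   reproducible and common random numbers across intervention arms exact.

A synthetic scenario generator supplies internally consistent parameter sets
(all labelled `"synthetic default"` — the conceptual model deliberately
publishes no empirical values), and a cost-effectiveness layer accumulates
discounted costs and QALYs and computes dominance frontiers, ICERs
(`ΔC/ΔE` between adjacent non-dominated arms) and net monetary benefit
(`λ·ΔE − ΔC`).

## Worked example

```r
library(fallsim)

# Consensus analysis on the packaged rating tables
hs <- delphi_analysis("health_state_event")
hs$rounds[[1]]
#> <round_summary> round 1: 20 items
#>   inclusion 9 | exclusion 0 | non-consensus 11

# Map the 14 consensus items onto the model structure
incorporation_report(hs$included)$counts
#>         state tracked_event        folded      excluded       unknown
#>             5             7             1             1             0
#>  incorporated
#>            12

# Simulate all eight arms over a 5-year horizon and compare
sc <- generate_default_scenario(seed = 1)
sc$plan$max_cycles <- 130L
run <- run_cea(sc, n = 200, seed = 1, lambda = 50000)
run
#> <cea_run> n = 200 per arm, seed = 1, digest = d6765ec4
#> <cea_result> lambda = 50000 per QALY
#>                          arm     cost   qaly             status      icer      nmb
#>                     exercise 26714.01 3.5338           frontier        NA 149973.7
#>           environment-vision 27129.68 3.5347           frontier  436895.8 149605.6
#>                   usual-care 27470.98 3.5142          dominated        NA 148241.0
#>              exercise-vision 27471.97 3.5347          dominated        NA 149263.3
#>         environment-exercise 27664.21 3.5349           frontier 2932303.0 149080.2
#>  exercise-environment-vision 28278.47 3.5350 extended_dominated        NA 148470.3
#>            multifactorial-qi 29197.20 3.5344          dominated        NA 147523.4
#>        exercise-emf-wbv-cavd 29467.71 3.5353           frontier 4204127.4 147298.2
```

Reading the table: arms are sorted by mean discounted cost per person;
`status` records strict dominance (dearer and no more effective than another
arm), extended dominance (an ICER strictly above that of the next frontier
arm), or frontier membership; `icer` is the incremental cost per QALY versus
the previous frontier arm; `nmb` is net monetary benefit at the given
willingness to pay. Under the synthetic defaults, usual care is dominated
because averted falls (hospitalization, surgery, aged-care admission) save
more than the cheaper programmes cost — a property of the synthetic inputs,
not an empirical finding.

Command-line front ends for the two workflows live in `inst/cli/`:
`delphi.R` (per-round classification tables, cumulative inclusion summary)
and `cea.R` (full scenario run writing CSV/JSON stamped with seed and
scenario digest).

## Package layout

- `R/delphi.R` — rating distributions, classification, round management
- `R/schema.R` — states, injury taxonomy, attribute registry, topology
- `R/engine.R` — the cycle engine, cohort simulation, structural audits
- `R/scenario.R` — synthetic scenarios, populations, YAML round trip
- `R/cea.R` — discounted accumulation, frontier/ICER/NMB analysis
- `inst/extdata/` — transcribed rating tables and published summaries
- `vignettes/fall-model-methods.Rmd` — modelling assumptions and choices
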