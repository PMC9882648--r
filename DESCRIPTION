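Package: fallsim
Title: Delphi Consensus Analysis and Microsimulation for a Fall
    Prevention Economic Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for conceptualizing and exercising an individual-level
    state-transition (microsimulation) model of falls in older adults.
    Includes a modified-Delphi consensus engine that classifies expert
    panel rating distributions into inclusion, exclusion and non-consensus
    categories and manages round-to-round carry-forward; a validated model
    schema encoding six care-setting states, a fall-injury taxonomy and the
    allowed transition topology; a discrete-time microsimulation engine
    with per-individual seeded random streams enforcing at most one fall
    per two-week cycle and one injury per fall; a synthetic scenario
    generator producing internally consistent hazards, pathway
    probabilities, costs, utilities and intervention arms; and a
    cost-effectiveness layer computing discounted costs, QALYs, dominance
    frontiers, ICERs and net monetary benefit.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    parallel,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
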