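Package: stgsim
Title: Stochastic Tree Grammar Simulation of Population Dynamics with
    Full Lineage Recording
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule-based stochastic simulation of population dynamics using
    environment-dependent stochastic tree grammars.  Programs declare
    per-species transition rules with probability-weighted outcome groups,
    per-individual internal states with pluggable updating functions, and
    conditional transformations triggered by internal-state thresholds.
    Execution uses the Gillespie direct method and records the complete
    lineage forest -- every individual ever alive, including extinct
    lineages -- with Newick export, tab-separated internal-state tables,
    and summary statistics over replicate seeded runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
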