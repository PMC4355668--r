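Package: stopgo
Title: Stop-Go Kinetics of Glucagon Fibril Growth Under a Monomer-Trimer Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models intermittent ("stop-go") elongation of glucagon amyloid
    fibrils. Glucagon partitions between monomers and trimers in solution;
    monomers build twisted fibrils and trimers build non-twisted fibrils, and
    each species blocks the growth of the opposite fibril class. The package
    solves the monomer-trimer equilibrium, derives closed-form stationary
    growth probabilities for a three-state fibril-tip chain, simulates the tip
    exactly (Gillespie), segments length-versus-time traces into stop and go
    dwells with a missed-event correction, fits exponential dwell
    distributions and switching rates, estimates fibril persistence length
    from worm-like-chain end-to-end statistics, and fits the model's rate
    ratios to measured growth probabilities. A synthetic-data module generates
    every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
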