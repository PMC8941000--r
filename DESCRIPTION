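Package: ommnet
Title: Interaction Network Inference for Defined Gut Bacterial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers signed, typed strain-strain interaction networks for
    defined (synthetic) gut bacterial communities from in vitro batch-culture
    readouts: spent-media growth curves summarised into normalized inhibition
    factors (d_AUC), untargeted-metabolomics feature tables turned into
    substrate-depletion profiles and asymmetric overlap matrices, qPCR
    absolute abundances converted into co-culture/monoculture ratios (r_bm)
    and classified into ecological interaction types (amensalism,
    competition, commensalism, predation, neutralism, mutualism), and
    serial-passage community compositions with dropout comparisons and
    ordination. A generalized Lotka-Volterra batch-dilution simulator with
    known ground truth makes every stage of the pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
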