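Package: retroplan
Title: Disconnection-Aware Multistep Retrosynthesis Planning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computer-aided synthesis planning with explicit disconnection
    control. Implements a tagged-SMILES dialect for marking candidate
    reactive atoms on a product, reaction-center identification from
    atom-mapped reactions, tagging-template mining and application,
    systematic and model-based disconnection-site enumeration, a
    forward-validated triple-predictor single-step loop behind pluggable
    model contracts, route scoring by a multiplicative route penalty
    score, and a memoized best-first multistep tree search down to a
    building-block set. Ships a deterministic rule-based toy chemistry
    with consistent mock predictors so every component runs end to end
    without trained models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    optparse,
    withr
Config/testthat/edition: 3
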