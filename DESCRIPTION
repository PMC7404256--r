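Package: sdtp
Title: Drug Treatment Patterns from Multilayer Tissue-Specific Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers candidate drug-target modules by mining recurrent
    heavy subgraphs from multilayer tissue-specific weighted gene networks
    and validating them against drug-activity and disease expression data.
    Provides network normalization and top-edge selection, a tensor-based
    heaviness-maximizing module miner, a module-selection cascade (overlap,
    differential-expression containment, local hypergeometric term
    enrichment, first-order neighbor scoring), permutation significance
    testing of module edge weights, case/control differential co-expression
    analysis, and synthetic-data generators with planted ground truth for
    end-to-end benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
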