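Package: nerpe
Title: Nonenzymatic RNA Primer Extension Sequencing and Kinetics Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing nonenzymatic RNA template copying with
    canonical (AUCG) and noncanonical (DUCG, with 2,6-diaminopurine
    replacing adenine) genetic alphabets. Implements a read-level analysis
    of self-priming hairpin deep-sequencing libraries: recovery of the
    randomized template and the copied product from each read,
    per-position classification of template:product pairs, mismatch
    frequency, product-base and inferred bridged-dinucleotide
    distributions, mismatch composition, and stalling statistics. A
    seeded stochastic read simulator with a ground-truth sidecar supports
    end-to-end validation. Companion kinetics functions fit
    pseudo-first-order primer-extension time courses and
    Michaelis-Menten saturation curves, and derive specificity ratios,
    rate-ratio stalling factors and binding free-energy differences from
    Km ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringi,
    ggplot2,
    generics,
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
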