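Package: bindnseq
Title: Thermodynamic Motif Inference from RNA Bind'n Seq Read Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers RNA-binding protein sequence specificity from in vitro
    affinity-selected oligonucleotide libraries (RNA Bind'n Seq and similar
    SELEX-style assays). Binding is modelled thermodynamically: a position
    weight matrix encodes site-specific Boltzmann weights and a scalar term
    captures sequence-unspecific binding. The position weight matrix and the
    unspecific-binding weight are estimated by expectation-maximization on
    the read-selection likelihood, with frequency priors from an order-d
    Markov model trained on the unselected input pool. Includes relative
    dissociation-constant estimation against a uniform reference motif,
    baseline k-mer enrichment analysis, and a synthetic Bind'n Seq simulator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
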