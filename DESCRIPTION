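Package: codonsel
Title: Codon Site-Model Selection Tests and Conservation Indices for
    Disease-Variant Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood inference of selective pressure on
    protein-coding genes from codon alignments and phylogenies, in the
    style of the codeml site and branch models: M0, the beta site-model
    pair M7/M8/M8a, the revised branch-site model A and the two-ratio
    branch model, with likelihood-ratio tests, family-structured
    Benjamini-Hochberg false-discovery-rate correction, and naive or
    Bayes empirical Bayes per-site posterior probabilities over omega
    classes.  Posterior-weighted mean omega values are turned into a
    per-site conservation index (1 - omega for purifying sites, zero
    otherwise) and a minimum-omega significance category, against which
    tables of disease-associated missense mutations are mapped to ask
    whether disease sites fall at evolutionarily conserved positions.
    Includes a codon-alignment simulator with ground truth for every
    model variant and an end-to-end study pipeline with a command-line
    entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
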