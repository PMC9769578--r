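Package: ecoassembly
Title: Phylogenetic Null Models for Community Assembly Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the deterministic and stochastic ecological processes
    (selection, dispersal, drift) structuring microbial communities from a
    rarefied amplicon count table and a rooted phylogeny. Implements the net
    relatedness index (NRI) and between-community phylogenetic turnover
    (beta mean pairwise distance and its z-score, betaNRI) under tip-label
    shuffling null models, the abundance-based Raup-Crick metric on
    Bray-Curtis dissimilarity (RC_bray), the five-process classification of
    sample pairs, Mantel correlograms for detecting phylogenetic signal in
    environmental niches, and a synthetic-community generator that assembles
    communities under each process so the whole pipeline can be validated
    against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    vegan,
    picante,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    biomformat
Config/testthat/edition: 3
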