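Package: trflptools
Title: In-Silico T-RFLP Fingerprinting and Water-Mass Community Analysis
Version: 0.1.0
Authors@R: person("RFZ", "Analysis Team", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for terminal restriction fragment length polymorphism
    (T-RFLP) community fingerprinting of marine prokaryotic communities:
    in-silico restriction digestion of primer-delimited 16S rRNA amplicons,
    peak-profile binning and standardization, OTU clustering of clone
    sequences, alpha-diversity estimation (Shannon, Margalef, bias-corrected
    Chao1, analytic rarefaction), Bray-Curtis resemblance with UPGMA
    clustering, Mantel-type matrix correlation between community and
    environmental resemblance matrices, and detection of successional change
    along a water-mass flow path via distance-decay regression with a
    bootstrap slope test and an ANCOVA comparison against a permutation
    null.  Includes a synthetic deep-ocean transect generator providing
    ground truth for every stage of the pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
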