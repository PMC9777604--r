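Package: pvltp
Title: Genome-Wide Identification and Characterization of Plant
    Non-Specific Lipid Transfer Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification, classification and characterization of plant
    non-specific lipid transfer protein (nsLTP) gene families from a
    proteome and genome annotation. Detects the eight-cysteine motif
    (C-Xn-C-Xn-CC-Xn-CXC-Xn-C-Xn-C) under inter-cysteine spacing
    constraints, classifies motifs into nsLTP types with a disjoint
    spacing grammar, runs the candidate filter cascade (motif presence,
    signal peptide, hybrid proline-rich exclusion, mature-length cutoff),
    computes mature-protein molecular weight and theoretical isoelectric
    point, maps family members onto chromosomes with tandem-duplicate
    cluster detection, builds a cysteine-anchored neighbor-joining
    phylogeny, and summarizes organ expression and qPCR 2^-ddCt fold
    changes. Ships the 58-gene common bean (Phaseolus vulgaris) family
    table as a worked reference data set and seeded synthetic-data
    generators with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
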