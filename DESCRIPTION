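Package: ighrep
Title: Immunoglobulin Heavy-Chain Repertoire Analysis for Mouse CLL/SLL Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of immunoglobulin heavy-chain (IGHV-D-J) rearrangements
    sequenced from B-cell clones of mouse chronic lymphocytic leukemia / small
    lymphocytic lymphoma models. Provides germline V/D/J assignment by pairwise
    alignment, discrimination of strain-specific germline polymorphisms from
    somatic hypermutation by cross-individual comparison of clones sharing an
    IGHV gene, mutated/unmutated classification, HCDR3 feature computation
    (length, Bjellqvist isoelectric point, composition), clonotype
    deduplication and stereotypy detection, gene-usage statistics (Pearson
    chi-square and likelihood-ratio tests with seeded Monte Carlo correction,
    proportion tests, t-tests), and a fully seeded synthetic-repertoire
    generator with ground truth for every stage.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
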