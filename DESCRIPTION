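Package: regensea
Title: Gene Set Enrichment and Conserved Regulator Gene Sets for
    Two-Condition Expression Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained re-implementation of the computational chain
    used to nominate candidate transcriptional and post-transcriptional
    regulators from a two-condition expression experiment: expression
    filtering, median probe collapse, fold-change plus Benjamini-Hochberg
    differential expression, a classic running-sum gene set enrichment
    engine with phenotype-permutation significance (ES, NES, nominal p,
    FDR q), construction of cross-species conserved transcription-factor
    motif gene sets by MATCH-style position-weight-matrix scanning of
    promoter alignments, microRNA 3'-UTR seed-match target sets, and the
    downstream validation arithmetic (2^-ddCt relative quantification with
    confidence intervals, unpaired t-tests from raw counts or printed
    summary statistics). Seeded synthetic-data generators with
    machine-readable planted truth make every stage testable without any
    external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite,
    optparse
Config/testthat/edition: 3
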