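Package: tradiskit
Title: Simulation and Insertion-Site Recovery for Transposon Insertion
    Sequencing (TraDIS) Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A self-contained toolkit for transposon directed insertion-site
    sequencing (TraDIS). Simulates Tn5 mutant libraries with the
    Nextera-TruSeq hybrid fragment layout (balancer, 20-bp PCR anchor,
    19-bp mosaic end, genomic junction sequence) and known clone
    abundances, then recovers unique insertion sites via two-round
    junction trimming with mismatch tolerance, dual-orientation
    seed-and-extend mapping (or external SAM ingest), de-duplication to
    putative junctions, and a counts-per-million support filter defining
    true junctions. Includes condition comparison reports, truth-based
    recovery metrics, transposome molar-ratio arithmetic, and a
    reproducible end-to-end pipeline driven by a YAML configuration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    data.table,
    Rcpp,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
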