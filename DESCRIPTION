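Package: mitofrag
Title: Digital PCR and Split-Read Analysis of Mitochondrial DNA Integrity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the integrity of circular mitochondrial
    genomes. Implements multiplex digital-PCR partition analysis (Poisson
    copy-number estimation, double/single-positive-partition linkage metrics
    and model-based linked-fraction inference), split/gapped-read junction
    detection on a circular reference with duplication-versus-deletion
    classification by heavy-strand-origin containment, junction microhomology
    search, breakpoint hotspot clustering, coverage and SNV gradients relative
    to the origin of replication, and a genotype-parameterised synthetic-data
    generator (molecule populations, truth-aligned SAM reads, dPCR plates,
    double-strand-break decay time-courses, Mendelian cross expectations) so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
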