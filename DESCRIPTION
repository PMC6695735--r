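Package: exontype
Title: Constitutive and Alternative Exon Annotation with Splicing Sequence Features
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies the exons of multi-isoform eukaryotic genes as
    constitutively or alternatively spliced under two complementary schemes
    (intact exon-coordinate units, or per-base constitutive/alternative exon
    regions), detects alternative-splicing events (exon skipping, alternative
    3'/5' splice sites, intron retention, exonic introns) against a reference
    isoform, computes diagnostic sequence features (position-weight-matrix
    splice-site strength, branch-point and polypyrimidine-tract detection,
    splicing-regulatory-element k-mer scanning, exon-intron architecture,
    GC content, reading-frame symmetry), and quantifies exon inclusion levels
    (PSI) from splice-junction read counts. Ships a deterministic simulator
    that generates annotated gene models, genome sequence with controllable
    splice-site strength, and junction counts with known inclusion levels,
    plus a command-line interface over all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
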