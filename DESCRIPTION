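Package: asunit
Title: Strand-Specific Antisense Transcription Unit Analysis for Yeast
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify and characterise antisense transcription from
    strand-specific paired-end RNA-seq in budding yeast. Fragment-center
    coverage is segmented into strand-specific transcribed units; units are
    assigned to UTR-extended gene models, antisense units are called and
    tiered by ORF coverage, fragmented calls are merged by a deterministic
    curation rule, and each antisense unit is classified by its plausible
    transcriptional origin (UTR extension, divergent promoter, 3' NFR, or
    unexplained). Companion routines normalise nCounter-style count tables
    in two steps (positive spike-ins, then control genes), compute
    strand-specific qPCR log-ratios, call induction/repression, count
    discordant sense-antisense pairs, and project antisense loci into other
    species through ortholog maps using ORF-relative coordinates. A
    synthetic-data generator plants gene models, antisense units, fragment
    sets and expression tables with known ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
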