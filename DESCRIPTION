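Package: fusionsurvey
Title: Gene-Fusion Discovery from Discordant Read Pairs with Breakpoint
    and Expression Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for discovering and validating gene
    fusions in paired-end RNA-seq. Candidate fusions are enumerated from
    discordant read pairs, scored with expression-normalized support
    statistics (SPER/DASPER/RESPER), and passed through a multi-rule
    exclusion ledger (amplicon association, annotation artifacts,
    reading-frame preservation, junction-read support). Retained
    candidates are validated with per-nucleotide coverage discontinuity,
    chimeric splice-junction reads, DNA-level fusion-point mapping with
    micro-homology resolution, and somatic status from matched
    tumor/normal exome reads. Expression consequences are assessed with
    RPKM quantification, outlier-expression detection, and
    nearest-template cosine pathway-activity scoring. A synthetic-data
    generator produces genomes, gene models, fusion events, sequencing
    reads, and cohort expression matrices with known ground truth so
    that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    data.table,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
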