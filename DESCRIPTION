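Package: mybfam
Title: Genome-Wide MYB Transcription Factor Family Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide identification and
    characterisation of plant MYB transcription factor families, modelled on
    the R2R3-MYB family of sugar beet (Beta vulgaris). Detects MYB repeats in
    predicted proteomes with a position-specific scoring profile anchored on
    the conserved tryptophan architecture of the MYB DNA-binding domain,
    classifies proteins into family classes (R2R3, MYB3R, MYB4R, CDC5-like)
    by repeat count, profiles per-position repeat conservation (sequence-logo
    data), annotates functional motifs (bHLH-interaction, SG7/SG7-2) and
    diagnostic residues, characterises chromosomal distribution, tandem
    sister-gene pairs and exon structure from gene models, assigns proteins
    to functional clades by landmark membership on Poisson-corrected
    neighbor-joining trees with bootstrap support, and summarises organ
    expression from RNA-seq count matrices via median-of-ratios
    normalisation, presence calls and centroid-linkage clustering. A
    synthetic-data module generates proteomes, gene models and count matrices
    with known ground truth so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
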