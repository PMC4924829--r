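Package: oakorigin
Title: Chloroplast Indel Markers for Continental Origin of White Oak Wood
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for developing and applying chloroplast DNA length-polymorphism
    markers that assign white oak (Quercus sect. Quercus) specimens -- including
    timber -- to their continent of origin (Asia, Europe, North America). Merges
    per-sample SNP/indel call tables into an annotated multi-individual variant
    matrix with summary statistics and primer-design flanking sequences, screens
    sample groups for continent-diagnostic fixed indels with repeat-context triage,
    simulates the five-locus PCR and PCR-RFLP genotyping assay in silico (primer
    location, amplification, HinfI digestion, dye-labeled fragment visibility),
    assigns continental origin from observed fragment-length profiles requiring
    concordant independent markers, and quantifies the residual risk that an
    apparently fixed marker segregates undetected, via exact binomial upper
    confidence bounds for zero observed events. A seeded synthetic-data generator
    produces reference sequences, continent haplotypes and pooled-sequencing
    variant tables so the full pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
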