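Package: rflpkit
Title: In Silico Multiplex PCR-RFLP Genotyping of CYP3A4 Star Alleles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a multiplex PCR-RFLP genotyping assay for the CYP3A4*4,
    CYP3A4*18B and CYP3A4*22 single-nucleotide polymorphisms. Provides
    nucleotide primitives (reverse complement, GC content, Wallace-rule
    melting temperature, primer quality control), a restriction-enzyme engine
    that maps recognition sites on both strands and digests linear templates
    (including type IIS offset cutters such as BsmAI), in silico multiplex
    PCR, per-genotype band-pattern prediction with an agarose gel visibility
    model, genotype calling from observed band sizes, multiplex assay
    validation, and a seeded generator of synthetic amplicon and locus
    sequences whose digests reproduce the assay's published fragment tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
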