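Package: grfhap
Title: Single-Gene Haplotype Diversity, In Silico Markers and
    Marker-Trait Association for Wheat GRF3-2A
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for allelic diversity of a single gene region
    (the bread wheat growth-regulating factor gene TaGRF3-2A and its
    flanks): pairwise alignment of accession sequences to a reference gene
    model, extraction and HGVS naming (g./c./p.) of sequence variants,
    5'UTR microsatellite measurement, collapsing of accessions into
    haplotypes, frequency-ranked protein-isoform grouping and allele
    designation, in silico prediction of PCR, CAPS and SSR molecular
    markers, SNP-only neighbor-joining phylogenies with bootstrap support
    and outgroup rooting, and per-year marker-trait association statistics
    (one-way F-tests, two-way least-squares means, Fisher's exact test).
    Includes a seeded synthetic-data generator that emulates the gene
    structure, a haplotype panel and phenotype panels with planted allele
    and year effects, so the full pipeline is testable without downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    emmeans,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
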