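Package: somascape
Title: Somatic Genome Interpretation for Synthetic Tumour Whole Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale somatic-genome interpretation stack for tumour
    whole-genome sequencing: tumour purity and ploidy estimation from
    B-allele frequency and read-depth segment summaries, whole-genome
    duplication calling, allele-specific copy-number assignment, variant
    ploidy and biallelic annotation, clonal/subclonal mixture modelling,
    microsatellite-instability and tumour-mutational-burden scoring,
    mutational-signature refitting, simplified dN/dS driver-gene testing,
    GISTIC-like copy-number peak peel-off, driver-catalogue construction
    with per-sample driver likelihoods, germline predisposition calling,
    fusion classification, and evidence-level clinical actionability.
    Includes a synthetic tumour-cohort generator so that every stage is
    testable without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    mclust,
    pracma,
    withr,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
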