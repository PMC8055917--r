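Package: psvkit
Title: Pseudogene-Aware Primer Design and Paralog-Specific Variant Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discriminates a gene from a highly homologous pseudogene for
    molecular diagnostics. Globally aligns the paralog pair, enumerates
    paralog-specific variants (PSVs) with HGVS-style 3'-normalized labels,
    annotates sites with population allele frequencies and Grantham
    physiochemical distances, designs gene-specific PCR and sequencing
    primers that place mismatches to the pseudogene at the primer 3' end
    while avoiding frequent SNPs (allele-dropout risk), verifies
    specificity by in-silico PCR, selects diagnostic SNP panels that
    confirm gene-specific amplification, and computes cohort screening
    statistics (allele frequencies, detection rates, pathogenic-allele
    spectra, fragment-analysis genotype calls). Includes a seeded
    synthetic-data generator for gene/pseudogene pairs, SNP tables,
    Hardy-Weinberg cohorts and fragment peaks with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
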