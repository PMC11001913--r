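Package: repairscan
Title: Genomic Scar Scores and DNA Repair Deficiency Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting homologous-recombination (HR) and
    nucleotide-excision-repair (NER) deficiency from tumor sequencing
    derivatives. Computes the three genomic scar scores (HRD-LOH, LST,
    TAI) and their sum from allele-specific copy-number segment profiles
    with the >=42 HR-deficiency call, the genomic LOH fraction with the
    >=16% rule, six-class biallelic genotype classification of HR genes
    from hard-filtered somatic variants plus gene-level LOH, non-negative
    least-squares refitting of mutational-signature exposures (SBS-96,
    ID-83, SV-32) with reconstruction cosine-similarity QC and an NER
    composite score (>=0.7 call), and cohort-level statistics (Fisher
    enrichment, Kaplan-Meier / log-rank / Cox survival stratification,
    ferroptosis signature scoring with Tukey fencing and extreme-quantile
    comparison). A synthetic-data module generates segment profiles with
    planted scar events, signature mixtures, filterable variant tables,
    hazard-ratio survival data and signature-shifted expression, each
    paired with oracle-computed ground truth, so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
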