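Package: ctclineage
Title: Clonal Lineage Inference from Circulating Tumor Cell Exomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative-genomics pipeline for cohorts combining bulk tumor
    specimens, whole-genome-amplified circulating tumor cell (CTC) pools and
    CTC-derived explant (CDX) models. Implements tumor-normal somatic variant
    post-filtering with low-VAF rescue and high-confidence CTC calling,
    estimation of whole-genome-amplification artifacts (allele drop-out and
    per-megabase false-positive rates), allele-specific copy-number calling
    from per-SNP coverage log-ratios and B-allele frequencies (circular binary
    segmentation, ploidy/purity lattice fitting, ploidy-relative aberration
    classes, LOH), allelic-imbalance based detection of known aberrations in
    noisy CTC samples, clonal set-accounting across sample groups, and
    maximum-parsimony phylogeny reconstruction from binary presence/absence
    matrices. Ships a synthetic-cohort generator with known clonal ground
    truth so the full pipeline is testable without controlled-access data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    ape,
    phangorn,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
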