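Package: editome
Title: Detection and Analysis of MicroRNA Mutation and Editing Sites from
    Small RNA Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for identifying mutation and editing (M/E)
    sites in microRNAs from small RNA sequencing reads. Reads are aligned to
    pre-miRNA hairpins with support for non-templated 3' tails, 5' additions
    and single-base indels; multi-mapped reads are down-weighted by an
    iterative cross-mapping correction; per-position editing levels are
    tested against a binomial sequencing-error model and classified into
    A-to-I, C-to-U, 3'-addition, 5'-editing and other categories. Per-sample
    calls are merged into a cohort matrix with prevalence, SNP, pseudo-site
    and cross-species conservation annotation; differential editing between
    groups is assessed with Mann-Whitney U tests and Benjamini-Hochberg
    correction; and the target repertoires of original versus edited mature
    miRNAs are compared using PAR-CLIP style T-to-C evidence and seed
    matching. A synthetic-data module generates all pipeline inputs with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
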