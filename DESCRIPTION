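Package: tmskit
Title: Analytics for Targeted Enzymatic Methylation Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational analytics for benchmarking targeted enzymatic
    methylation sequencing (TMS) against whole-genome, reduced-representation
    and array-based DNA methylation assays. Provides parsers for cytosine
    reports and BED intervals with strand collapsing to CpG dinucleotides;
    interval arithmetic for capture efficiency (target expansion and merging,
    on-target classification, probe coverage, expected-CpG counting, CpG
    island shore/shelf derivation); count-matrix assembly with
    coverage/missingness filtering and annotation summaries; run-level QC
    (CHH-based conversion estimates, assembly N50/N90, binomial read
    thinning and coverage curves); a coverage-conditioned power simulator
    over sample sizes, effect sizes and coverage multipliers; cross-technology
    concordance fits including microarray beta-value offset bias and
    matched-versus-permuted per-sample agreement; and per-site beta-binomial
    tissue-specificity tests with FDR control and overlap enrichment. A
    synthetic-data module generates every required input (reference, probes,
    methylomes, fragments, array betas, in-silico MspI digests) with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
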