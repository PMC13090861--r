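Package: clonith
Title: Subclonal Heterogeneity and Genomic Burden Statistics for Tumor
    Exome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sample-level genomic statistics for whole-exome tumor cohorts:
    multi-caller somatic variant retention filtering, tumor mutational burden
    (TMB) with pediatric classification, copy-number burden and gene-level
    amplification/deletion calls by fractional overlap, and an intratumoral
    heterogeneity (ITH) pipeline that maps variant allele frequencies to
    cellular prevalences, clusters mutations into subclones with a
    BIC-selected binomial-mixture model (or ingests clusters from an external
    clonal-inference tool), merges clusters in two stages (average-linkage
    with a fixed cutoff, then pairwise rank-sum refinement), and scores
    heterogeneity with the Shannon diversity index. Includes exact and
    normal-approximation two-sided rank-sum group comparisons and a synthetic
    tumor/cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
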