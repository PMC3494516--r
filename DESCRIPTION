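Package: bootrpkm
Title: Bootstrap Estimation of Gene Expression from Multi-Mapping
    RNA-Seq Alignments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates gene-model expression (RPKM) from short-read
    alignments in which many reads align to more than one location, as is
    common for transcriptomes containing families of highly similar gene
    models. Across bootstrap iterations each ambiguous read is uniformly
    re-assigned to one of its candidate alignment locations; the per-gene
    RPKM distribution is summarised as a mean and standard deviation, and a
    cumulative-normal-distribution p-value (Benjamini-Hochberg adjusted)
    tests for significant detected expression. Includes two non-bootstrap
    baselines (single random allocation, unique-reads-only), a parser for
    legacy Bowtie text alignment output, a synthetic-transcriptome read
    simulator with an internal exact-match aligner, evaluation metrics
    (accuracy, false-positive percentage, Spearman correlation, MA values),
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    parallel,
    stats,
    utils,
    optparse,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
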