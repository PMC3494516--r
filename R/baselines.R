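#' Single-random-allocation expression baseline
#'
#' Emulates the aligner-default treatment of ambiguous reads: each
#' multiply-aligning read is randomly assigned to one of its candidate
#' locations exactly once (a single bootstrap iteration), and per-gene RPKM is
#' computed with the total number of aligned reads as denominator.
#'
#' @param reads A `read_alignments` object.
#' @param genes The matching [gene_table].
#' @param seed Integer seed for the single random allocation.
#' @return Named numeric vector of per-gene RPKM, in gene-table order.
#' @export
random_assignment_expression <- function(reads, genes, seed = 1L) {
  stopifnot(inherits(genes, "gene_table"))
  if (reads$n_reads == 0L) {
    return(stats::setNames(numeric(nrow(genes)), genes$name))
  }
  set.seed(.derive_seed(seed, 0L))
  counts <- resample_iteration(reads, genes)
  stats::setNames(compute_rpkm(counts, genes$length_bp, reads$n_reads),
                  genes$name)
}

#' Unique-reads-only expression baseline
#'
#' Emulates the aligner setting that discards all ambiguously aligning reads:
#' only reads with exactly one alignment location are counted, and the RPKM
#' denominator is this baseline's own aligned total — the number of uniquely
#' aligning reads — as if the ambiguous reads had never been reported.
#'
#' @param reads A `read_alignments` object.
#' @param genes The matching [gene_table].
#' @return Named numeric vector of per-gene RPKM, in gene-table order. If no
#'   read aligns uniquely the vector is all zero and a warning is issued.
#' @export
unique_only_expression <- function(reads, genes) {
  stopifnot(inherits(genes, "gene_table"))
  nloc <- tabulate(reads$alignments$read, reads$n_reads)
  keep <- reads$alignments$read %in% which(nloc == 1L)
  n_unique <- sum(nloc == 1L)
  if (n_unique == 0L) {
    warning("no uniquely aligning reads; returning all-zero RPKM",
            call. = FALSE)
    return(stats::setNames(numeric(nrow(genes)), genes$name))
  }
  counts <- tabulate(reads$alignments$gene[keep], nrow(genes))
  stats::setNames(compute_rpkm(counts, genes$length_bp, n_unique), genes$name)
}

#' Presence/absence call for non-bootstrap baselines
#'
#' Baseline methods return no significance measure, so expression is called
#' as any RPKM strictly greater than zero.
#'
#' @param rpkm Numeric vector of per-gene RPKM.
#' @return Logical vector, `TRUE` where RPKM > 0.
#' @export
call_expressed_baseline <- function(rpkm) {
  rpkm > 0
}
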