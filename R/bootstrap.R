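#' Reads per kilobase of gene model per million aligned reads
#'
#' RPKM normalises a read count by gene model length (per kilobase) and
#' sequencing depth (per million aligned reads):
#' `count / (length_bp / 1000) / (total_aligned_reads / 1e6)`.
#'
#' @param count Read count(s) assigned to the gene model(s); non-negative,
#'   may be fractional (e.g. an expected count).
#' @param length_bp Gene model length(s) in base pairs, >= 1.
#' @param total_aligned_reads Total number of aligned reads in the dataset
#'   (the depth denominator), a single integer >= 1.
#' @return Numeric RPKM value(s).
#' @export
compute_rpkm <- function(count, length_bp, total_aligned_reads) {
  if (length(total_aligned_reads) != 1L || is.na(total_aligned_reads) ||
      total_aligned_reads < 1) {
    .stopf("total_aligned_reads must be a single integer >= 1 (no aligned reads, RPKM undefined)")
  }
  if (any(length_bp < 1)) .stopf("length_bp must be >= 1")
  if (any(count < 0)) .stopf("count must be non-negative")
  count / (length_bp / 1000) / (total_aligned_reads / 1e6)
}

#' One random assignment of every read to a single alignment location
#'
#' Performs a single bootstrap iteration: each read is assigned to one of its
#' candidate alignment locations, selected uniformly over its alignment
#' *records* (a gene hit at two positions by one read carries weight
#' 2/n_locations). Uses the current R random number stream; seed it with
#' [set.seed()] for reproducibility.
#'
#' @param reads A `read_alignments` object from [parse_bowtie_output()].
#' @param genes The matching [gene_table].
#' @return Integer vector of per-gene read counts, in gene-table order,
#'   summing to the number of reads.
#' @export
resample_iteration <- function(reads, genes) {
  idx <- .index_reads(reads, nrow(genes))
  counts <- idx$fixed_counts
  n_amb <- length(idx$amb_start)
  if (n_amb > 0L) {
    pick <- idx$amb_start +
      pmin(floor(stats::runif(n_amb) * idx$amb_nloc), idx$amb_nloc - 1L)
    counts <- counts + tabulate(idx$gene_sorted[pick], nrow(genes))
  }
  counts
}

#' Bootstrap expression estimation over random read re-assignments
#'
#' Runs the bootstrap core: across `iterations` independent iterations, every
#' multiply-aligning read is uniformly re-assigned to one of its candidate
#' alignment locations, per-gene RPKM is computed with the total number of
#' aligned reads as a constant denominator, and the per-gene RPKM values are
#' aggregated to a sample mean and sample standard deviation (n - 1
#' denominator) using streaming moments, so memory is O(genes) rather than
#' O(genes x iterations).
#'
#' Reads all of whose alignment locations lie on a single gene are that
#' gene's `unique_reads`; they are assigned identically in every iteration,
#' so a gene receiving only such reads has `sd_rpkm` exactly 0 and
#' `mean_rpkm` exactly equal to `unique_rpkm`.
#'
#' Each iteration draws from its own random stream derived from
#' `(seed, iteration index)`, and chunk results are combined in a fixed
#' order, so the output is bit-identical for any `workers` value.
#'
#' @param reads A `read_alignments` object.
#' @param genes The matching [gene_table].
#' @param iterations Number of bootstrap iterations, >= 2 (the standard
#'   deviation is undefined below that). Default 100.
#' @param seed Integer seed governing all random assignment.
#' @param workers Number of worker processes (>= 1) used to spread iterations;
#'   does not affect the result.
#' @return A `data.frame` with one row per gene (gene-table order) and
#'   columns `gene`, `length_bp`, `unique_reads`, `unique_rpkm`, `mean_rpkm`,
#'   `sd_rpkm`. Significance columns are added by [bootstrap_expression()].
#' @seealso [bootstrap_expression()] for the full estimate including
#'   CND and BH-adjusted p-values.
#' @export
run_bootstrap <- function(reads, genes, iterations = 100L, seed = 1L,
                          workers = 1L) {
  stopifnot(inherits(genes, "gene_table"))
  iterations <- as.integer(iterations)
  workers <- as.integer(workers)
  if (is.na(iterations) || iterations < 2L) {
    .stopf("iterations must be >= 2 (standard deviation undefined otherwise)")
  }
  if (is.na(workers) || workers < 1L) .stopf("workers must be >= 1")
  n_genes <- nrow(genes)
  n_reads <- reads$n_reads

  if (n_reads == 0L) {
    return(data.frame(gene = genes$name, length_bp = genes$length_bp,
                      unique_reads = 0L, unique_rpkm = 0, mean_rpkm = 0,
                      sd_rpkm = 0, stringsAsFactors = FALSE))
  }

  idx <- .index_reads(reads, n_genes)
  # constant per-gene scale: counts -> RPKM with the shared depth denominator
  scale <- 1 / (genes$length_bp / 1000) / (n_reads / 1e6)
  n_amb <- length(idx$amb_start)

  run_chunk <- function(iters) {
    n <- 0L
    mu <- numeric(n_genes)
    m2 <- numeric(n_genes)
    for (i in iters) {
      set.seed(.derive_seed(seed, i))
      counts <- idx$fixed_counts
      if (n_amb > 0L) {
        pick <- idx$amb_start +
          pmin(floor(stats::runif(n_amb) * idx$amb_nloc), idx$amb_nloc - 1L)
        counts <- counts + tabulate(idx$gene_sorted[pick], n_genes)
      }
      x <- counts * scale
      n <- n + 1L
      d <- x - mu
      mu <- mu + d / n
      m2 <- m2 + d * (x - mu)
    }
    list(n = n, mu = mu, m2 = m2)
  }

  # fixed chunking (independent of `workers`) + in-order pairwise combination
  # keeps the floating-point reduction tree identical for any worker count
  n_chunks <- min(iterations, 8L)
  chunk_of <- sort(rep_len(seq_len(n_chunks), iterations))
  chunks <- split(seq_len(iterations), chunk_of)
  parts <- if (workers > 1L) {
    parallel::mclapply(chunks, run_chunk, mc.cores = workers)
  } else {
    lapply(chunks, run_chunk)
  }
  agg <- parts[[1L]]
  for (p in parts[-1L]) {
    n_ab <- agg$n + p$n
    d <- p$mu - agg$mu
    agg <- list(n = n_ab,
                mu = agg$mu + d * (p$n / n_ab),
                m2 = agg$m2 + p$m2 + d * d * (agg$n * (p$n / n_ab)))
  }

  unique_reads <- idx$fixed_counts
  data.frame(
    gene = genes$name,
    length_bp = genes$length_bp,
    unique_reads = unique_reads,
    unique_rpkm = unique_reads * scale,
    mean_rpkm = agg$mu,
    sd_rpkm = sqrt(pmax(agg$m2, 0) / (agg$n - 1L)),
    stringsAsFactors = FALSE
  )
}

#' Full bootstrap expression estimate with significance
#'
#' Convenience wrapper: [run_bootstrap()] followed by the
#' cumulative-normal-distribution p-value ([cnd_pvalue()]), Benjamini-Hochberg
#' adjustment ([bh_adjust()]) and the presence/absence call
#' ([call_expressed()]).
#'
#' With zero aligned reads every gene receives an all-zero estimate with
#' `cnd_pvalue` 1 (no expression detectable).
#'
#' @inheritParams run_bootstrap
#' @param alpha Significance level for the expressed call on the BH-adjusted
#'   p-value (strict `<`). Default 0.05.
#' @return The [run_bootstrap()] data.frame with additional columns
#'   `cnd_pvalue`, `bh_pvalue` and logical `expressed`.
#' @export
bootstrap_expression <- function(reads, genes, iterations = 100L, seed = 1L,
                                 workers = 1L, alpha = 0.05) {
  est <- run_bootstrap(reads, genes, iterations = iterations, seed = seed,
                       workers = workers)
  est$cnd_pvalue <- cnd_pvalue(est$mean_rpkm, est$sd_rpkm)
  est$bh_pvalue <- bh_adjust(est$cnd_pvalue)
  est$expressed <- call_expressed(est$bh_pvalue, alpha = alpha)
  est
}
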