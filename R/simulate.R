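.BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Parameters of the synthetic validation harness: a transcriptome that mixes
#' independent gene models with families of highly similar duplicates (the
#' situation that produces multiply-aligning reads), a sparse known-expression
#' truth, and error-free fixed-length reads sampled in proportion to
#' expression.
#'
#' Defaults describe the harness's standard validation condition: 2000 gene
#' models of 500-3000 bp including 10 duplicate families of size 2 at 98%
#' within-family identity, half the genes expressed with log-normal weights
#' (meanlog 0, sdlog 1.5, spanning roughly four orders of magnitude), and
#' 300000 error-free 46-mer reads.
#'
#' @param n_genes Number of gene models.
#' @param length_range Integer `c(min_bp, max_bp)` for gene model lengths.
#' @param n_families Number of duplicate-gene families.
#' @param family_size Members per family (>= 2).
#' @param within_family_identity Expected per-base identity between family
#'   members, in (0, 1\]; 1 gives exact duplicates.
#' @param frac_expressed Fraction of genes given non-zero expression, in
#'   (0, 1\]; the expressed count is `round(frac_expressed * n_genes)`.
#' @param mu_log,sigma_log Log-normal parameters (meanlog, sdlog) of the
#'   expression weights of expressed genes.
#' @param n_reads Number of reads to simulate.
#' @param read_length_bp Read length in base pairs (default 46).
#' @param seed Integer seed; every simulation stage derives its own stream
#'   from it, so the transcriptome and truth are reproducible independently
#'   of `n_reads`.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, length_range = c(500L, 3000L),
                       n_families = 10L, family_size = 2L,
                       within_family_identity = 0.98, frac_expressed = 0.5,
                       mu_log = 0, sigma_log = 1.5, n_reads = 300000L,
                       read_length_bp = 46L, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              length_range = as.integer(length_range),
              n_families = as.integer(n_families),
              family_size = as.integer(family_size),
              within_family_identity = within_family_identity,
              frac_expressed = frac_expressed,
              mu_log = mu_log, sigma_log = sigma_log,
              n_reads = as.integer(n_reads),
              read_length_bp = as.integer(read_length_bp),
              seed = as.integer(seed))
  if (cfg$n_genes < 1L) .stopf("n_genes must be >= 1")
  if (length(cfg$length_range) != 2L ||
      cfg$length_range[1L] > cfg$length_range[2L] ||
      cfg$length_range[1L] < 1L) {
    .stopf("length_range must be c(min_bp, max_bp) with 1 <= min <= max")
  }
  if (cfg$read_length_bp < 1L ||
      cfg$read_length_bp > cfg$length_range[1L]) {
    .stopf("read_length_bp must be between 1 and the minimum gene length")
  }
  if (cfg$n_families < 0L) .stopf("n_families must be >= 0")
  if (cfg$n_families > 0L && cfg$family_size < 2L) {
    .stopf("family_size must be >= 2")
  }
  if (cfg$n_families * cfg$family_size > cfg$n_genes) {
    .stopf("n_families * family_size must not exceed n_genes")
  }
  if (cfg$within_family_identity <= 0 || cfg$within_family_identity > 1) {
    .stopf("within_family_identity must be in (0, 1]")
  }
  if (cfg$frac_expressed <= 0 || cfg$frac_expressed > 1) {
    .stopf("frac_expressed must be in (0, 1]")
  }
  if (cfg$sigma_log < 0) .stopf("sigma_log must be >= 0")
  if (cfg$n_reads < 1L) .stopf("n_reads must be >= 1")
  structure(cfg, class = "sim_config")
}

.random_sequence <- function(length_bp) {
  paste(sample(.BASES, length_bp, replace = TRUE), collapse = "")
}

# mutate a copy of `chars` at per-position rate, always to a different base
.mutate_chars <- function(chars, rate) {
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit) > 0L) {
    cur <- match(chars[hit], .BASES)
    chars[hit] <- .BASES[((cur - 1L + sample.int(3L, length(hit),
                                                 replace = TRUE)) %% 4L) + 1L]
  }
  chars
}

#' Simulate a transcriptome with duplicate-gene families
#'
#' Generates `n_genes` random nucleotide sequences. The first
#' `n_families * family_size` genes form families: within a family every
#' member is a copy of the family's seed sequence (hence equal length) with
#' positions mutated independently at rate `1 - within_family_identity`; at
#' identity 1 family members are exact duplicates. All remaining genes are
#' independent random sequences with lengths drawn uniformly from
#' `length_range`.
#'
#' @param config A [sim_config].
#' @return A list with `sequences` (named character vector of gene
#'   sequences), `genes` (the matching [gene_table]) and `family` (integer
#'   family id per gene, `NA` for singletons).
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.derive_seed(config$seed, 101L))
  n <- config$n_genes
  span <- config$length_range[2L] - config$length_range[1L] + 1L
  lens <- config$length_range[1L] + sample.int(span, n, replace = TRUE) - 1L
  family <- rep(NA_integer_, n)
  seqs <- character(n)
  mut_rate <- 1 - config$within_family_identity
  g <- 0L
  if (config$n_families > 0L) {
    for (f in seq_len(config$n_families)) {
      seed_chars <- sample(.BASES, lens[g + 1L], replace = TRUE)
      for (m in seq_len(config$family_size)) {
        g <- g + 1L
        family[g] <- f
        lens[g] <- length(seed_chars)
        seqs[g] <- if (m == 1L) {
          paste(seed_chars, collapse = "")
        } else {
          paste(.mutate_chars(seed_chars, mut_rate), collapse = "")
        }
      }
    }
  }
  for (i in seq.int(g + 1L, length.out = n - g)) {
    seqs[i] <- .random_sequence(lens[i])
  }
  names(seqs) <- sprintf("gene%05d", seq_len(n))
  list(sequences = seqs,
       genes = gene_table(names(seqs), lens),
       family = family)
}

#' Assign a sparse known-expression truth
#'
#' Selects `round(frac_expressed * n_genes)` genes without replacement and
#' gives them i.i.d. log-normal expression weights; all other genes get a
#' weight of exactly 0. Weights play the role of relative transcript
#' molarity.
#'
#' @param genes A [gene_table].
#' @param config A [sim_config].
#' @return A truth `data.frame` with columns `gene` and `weight` (columns
#'   `true_rpkm` and `origin_reads` are added by [simulate_reads()]).
#' @export
assign_expression <- function(genes, config) {
  stopifnot(inherits(genes, "gene_table"), inherits(config, "sim_config"))
  set.seed(.derive_seed(config$seed, 202L))
  n <- nrow(genes)
  n_expressed <- round(config$frac_expressed * n)
  idx <- sample.int(n, n_expressed)
  weight <- numeric(n)
  weight[idx] <- stats::rlnorm(n_expressed, meanlog = config$mu_log,
                               sdlog = config$sigma_log)
  data.frame(gene = genes$name, weight = weight, stringsAsFactors = FALSE)
}

#' Sample error-free reads from expressed gene models
#'
#' Each read is drawn by choosing a gene with probability proportional to
#' `weight x (length - read_length + 1)` (molarity times the number of valid
#' start positions), then a start position uniformly over the valid starts,
#' and emitting the exact forward-strand substring. The origin is encoded in
#' the read name as `read<i>|<gene>|<offset>` (0-based offset) and tallied
#' into `origin_reads`.
#'
#' The published truth `true_rpkm` is the RPKM of the *expected* origin count
#' (`compute_rpkm(n_reads * p_g, length_g, n_reads)`), i.e. the intended
#' expression level, independent of sampling noise; realised `origin_reads`
#' are retained for diagnostics.
#'
#' @param sequences Named character vector of gene sequences.
#' @param truth Truth table from [assign_expression()].
#' @param config A [sim_config].
#' @return A list with `reads` (named character vector of read sequences) and
#'   `truth` (the input truth with `true_rpkm` and `origin_reads` added).
#' @export
simulate_reads <- function(sequences, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$read_length_bp
  len <- nchar(sequences)
  if (any(truth$weight > 0 & len < k)) {
    .stopf("every expressed gene must be at least read_length_bp long")
  }
  if (all(truth$weight == 0)) .stopf("all expression weights are zero")
  set.seed(.derive_seed(config$seed, 303L))
  eff <- len - k + 1L
  pr <- truth$weight * eff
  n_reads <- config$n_reads
  g <- sample.int(length(sequences), n_reads, replace = TRUE, prob = pr)
  start <- 1L + pmin(as.integer(floor(stats::runif(n_reads) * eff[g])),
                     eff[g] - 1L)
  reads <- substr(sequences[g], start, start + k - 1L)
  names(reads) <- sprintf("read%d|%s|%d", seq_len(n_reads),
                          names(sequences)[g], start - 1L)
  expected <- n_reads * pr / sum(pr)
  truth$true_rpkm <- compute_rpkm(expected, len, n_reads)
  truth$origin_reads <- tabulate(g, length(sequences))
  list(reads = reads, truth = truth)
}

#' Build a k-mer index of a transcriptome
#'
#' Hash-style index of every k-mer position in every gene sequence (forward
#' strand), used by [align_exact()]. Building it once and passing it to
#' several [align_exact()] calls avoids re-indexing.
#'
#' @param sequences Named character vector of gene sequences.
#' @param k K-mer (read) length in base pairs.
#' @return A `data.table` keyed by k-mer with columns `kmer`, `gene`,
#'   `offset` (0-based).
#' @export
kmer_index <- function(sequences, k) {
  len <- nchar(sequences)
  if (any(len < k)) {
    use <- len >= k
    sequences <- sequences[use]
    len <- len[use]
  }
  eff <- len - k + 1L
  kmers <- unlist(lapply(seq_along(sequences), function(i) {
    substring(sequences[[i]], seq_len(eff[i]), seq_len(eff[i]) + k - 1L)
  }), use.names = FALSE)
  idx <- data.table::data.table(
    kmer = kmers,
    gene = rep(names(sequences), eff),
    offset = unlist(lapply(eff, seq_len), use.names = FALSE) - 1L
  )
  data.table::setkeyv(idx, "kmer")
  idx
}

#' Exact-match alignment of error-free reads, Bowtie-format output
#'
#' Reports every exact forward-strand occurrence of each read in the gene
#' sequences as one legacy Bowtie v1 text line (read name, `+`, gene, 0-based
#' offset, read sequence, constant `I` qualities, `0`), i.e. all-alignments
#' reporting. Error-free reads are guaranteed at least one hit (their
#' origin); a read with none is an input mismatch and raises an error.
#'
#' @param reads Named character vector of equal-length read sequences.
#' @param sequences Named character vector of gene sequences.
#' @param index Optional prebuilt [kmer_index()] of `sequences` at the read
#'   length; built on the fly when `NULL`.
#' @return Character vector of Bowtie-format alignment lines, grouped by read
#'   in input read order.
#' @export
align_exact <- function(reads, sequences, index = NULL) {
  if (length(reads) == 0L) return(character(0))
  k <- unique(nchar(reads))
  if (length(k) != 1L) .stopf("all reads must have equal length")
  if (is.null(index)) index <- kmer_index(sequences, k)
  query <- data.table::data.table(read = names(reads), kmer = unname(reads))
  hits <- index[query, on = "kmer", allow.cartesian = TRUE]
  if (anyNA(hits$gene)) {
    .stopf("read '%s' has no exact match in the transcriptome",
           hits$read[which(is.na(hits$gene))[1L]])
  }
  qual <- strrep("I", k)
  paste(hits$read, "+", hits$gene, hits$offset, hits$kmer, qual, "0",
        sep = "\t")
}

#' Run the full simulation harness
#'
#' [simulate_transcriptome()], [assign_expression()], [simulate_reads()] and
#' [align_exact()] chained under one configuration.
#'
#' @param config A [sim_config].
#' @return A list with `genes`, `sequences`, `family`, `truth`, `reads` and
#'   `alignments` (Bowtie-format lines).
#' @export
simulate_dataset <- function(config) {
  tx <- simulate_transcriptome(config)
  truth <- assign_expression(tx$genes, config)
  rd <- simulate_reads(tx$sequences, truth, config)
  aln <- align_exact(rd$reads, tx$sequences)
  list(genes = tx$genes, sequences = tx$sequences, family = tx$family,
       truth = rd$truth, reads = rd$reads, alignments = aln)
}

#' Write sequences as FASTA
#'
#' @param sequences Named character vector of nucleotide sequences (genes or
#'   reads).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Write the simulation truth table as TSV
#'
#' Columns: gene, weight, true_rpkm, origin_reads.
#'
#' @param truth Truth table from [simulate_reads()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a simulation truth table
#'
#' @param path Path to a TSV written by [write_truth_table()].
#' @return The truth `data.frame`.
#' @export
read_truth_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
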