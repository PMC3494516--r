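# Shared fixture builders and independent oracles. Everything is constructed
# in code; no stored data files.

# one legacy Bowtie text line
bt_line <- function(read, gene, offset = 0L, strand = "+",
                    seq = "ACGTACGTAC") {
  paste(read, strand, gene, offset, seq, strrep("I", nchar(seq)), "0",
        sep = "\t")
}

# Build a read_alignments object from a named list: read id -> character
# vector of gene names (one entry per alignment location; names may repeat
# for several locations on the same gene).
make_reads <- function(spec, genes) {
  lines <- unlist(lapply(names(spec), function(r) {
    vapply(seq_along(spec[[r]]),
           function(i) bt_line(r, spec[[r]][i], offset = i - 1L),
           character(1))
  }))
  suppressMessages(parse_bowtie_output(lines, genes))
}

# Exact assignment-distribution oracle by full enumeration: every combination
# of per-read location choices is equally likely. Returns the exact mean and
# population SD of per-gene RPKM under uniform location choice.
enum_bootstrap_oracle <- function(spec, genes) {
  n_reads <- length(spec)
  combos <- expand.grid(lapply(spec, seq_along))
  n_genes <- nrow(genes)
  rpkm <- matrix(0, nrow = nrow(combos), ncol = n_genes)
  for (ci in seq_len(nrow(combos))) {
    picked <- vapply(seq_len(n_reads),
                     function(r) spec[[r]][combos[ci, r]], character(1))
    counts <- tabulate(match(picked, genes$name), n_genes)
    rpkm[ci, ] <- compute_rpkm(counts, genes$length_bp, n_reads)
  }
  list(mean = colMeans(rpkm),
       sd = sqrt(colMeans(rpkm^2) - colMeans(rpkm)^2))
}

# Textbook Benjamini-Hochberg step-up, written independently of bh_adjust.
bh_textbook <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# small deterministic simulation for pipeline-level tests
small_sim_config <- function(seed = 7L, n_reads = 20000L, n_genes = 200L) {
  sim_config(n_genes = n_genes, length_range = c(200L, 800L),
             n_families = 4L, family_size = 2L,
             within_family_identity = 0.98, frac_expressed = 0.5,
             n_reads = n_reads, seed = seed)
}
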