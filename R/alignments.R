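#' Parse legacy Bowtie text alignment output
#'
#' Reads the default (pre-SAM) Bowtie v1 output: one alignment per line,
#' tab-separated, with fields read name, strand, reference name, 0-based
#' offset, read sequence, qualities, and optional trailing fields. Only the
#' first four fields are consumed. Lines are grouped by read name into one
#' record per read holding all of its candidate alignment locations; reads
#' were aligned with all-alignments reporting, so a multiply-aligning read
#' contributes several consecutive or scattered lines.
#'
#' Reference names must all be present in `genes`: an alignment against a
#' gene absent from the gene-size file would silently distort the RPKM
#' denominator, so this is a hard error.
#'
#' @param input Path to a Bowtie output file (or a connection), or a
#'   character vector of alignment lines (anything of length > 1, or a single
#'   string containing a tab, is treated as lines).
#' @param genes The [gene_table] the reads were aligned against.
#' @return An object of class `read_alignments`: a list with elements
#'   `alignments` (data.frame with integer `read` and `gene` indices,
#'   `offset`, `strand`), `read_ids` (distinct read names, in order of first
#'   appearance), `n_reads` and `n_alignments`.
#' @export
parse_bowtie_output <- function(input, genes) {
  stopifnot(inherits(genes, "gene_table"))
  lines <- if (inherits(input, "connection") ||
               (is.character(input) &&
                length(input) == 1L && !grepl("\t", input, fixed = TRUE))) {
    readLines(input)
  } else {
    as.character(input)
  }
  lines <- lines[nzchar(lines)]
  n_lines <- length(lines)
  if (n_lines == 0L) {
    message("parsed 0 alignment lines for 0 distinct reads")
    return(.new_read_alignments(character(0), integer(0), integer(0),
                                integer(0), character(0), genes))
  }
  parts <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  if (length(parts) < 4L) {
    .stopf("alignment line 1: fewer than 4 tab-separated fields")
  }
  short <- is.na(parts[[2L]]) | is.na(parts[[3L]]) | is.na(parts[[4L]])
  if (any(short)) {
    .stopf("alignment line %d: fewer than 4 tab-separated fields",
           which(short)[1L])
  }
  read_name <- parts[[1L]]
  strand <- parts[[2L]]
  ref <- parts[[3L]]
  offset <- suppressWarnings(as.integer(parts[[4L]]))
  if (any(is.na(offset) | offset < 0L)) {
    bad <- which(is.na(offset) | offset < 0L)[1L]
    .stopf("alignment line %d: offset '%s' is not a non-negative integer",
           bad, parts[[4L]][bad])
  }
  if (!all(strand %in% c("+", "-"))) {
    bad <- which(!(strand %in% c("+", "-")))[1L]
    .stopf("alignment line %d: strand '%s' is not '+' or '-'",
           bad, strand[bad])
  }
  gene <- match(ref, genes$name)
  if (anyNA(gene)) {
    bad <- which(is.na(gene))[1L]
    .stopf("alignment line %d: reference '%s' not found in the gene table",
           bad, ref[bad])
  }
  read_ids <- unique(read_name)
  read <- match(read_name, read_ids)
  message(sprintf("parsed %d alignment lines for %d distinct reads",
                  n_lines, length(read_ids)))
  .new_read_alignments(read_name, read, gene, offset, strand, genes,
                       read_ids = read_ids)
}

.new_read_alignments <- function(read_name, read, gene, offset, strand, genes,
                                 read_ids = unique(read_name)) {
  structure(
    list(
      alignments = data.frame(read = as.integer(read),
                              gene = as.integer(gene),
                              offset = as.integer(offset),
                              strand = as.character(strand),
                              stringsAsFactors = FALSE),
      read_ids = read_ids,
      n_reads = length(read_ids),
      n_alignments = length(read)
    ),
    class = "read_alignments"
  )
}

#' @export
print.read_alignments <- function(x, ...) {
  n_multi <- sum(tabulate(x$alignments$read, x$n_reads) > 1L)
  cat(sprintf(
    "read_alignments: %d reads, %d alignment lines (%d reads multiply aligned)\n",
    x$n_reads, x$n_alignments, n_multi))
  invisible(x)
}

# Index the alignment records by read for fast per-iteration resampling.
# Returns, over alignments sorted by read index:
#   gene_sorted   gene index of every alignment record
#   start, nloc   per-read block start and size in gene_sorted
#   fixed_counts  per-gene counts of reads all of whose locations lie on one
#                 gene (their assignment never varies)
#   amb_start, amb_nloc  block coordinates of the remaining (ambiguous) reads
.index_reads <- function(reads, n_genes) {
  aln <- reads$alignments
  n_reads <- reads$n_reads
  ord <- order(aln$read)
  read_sorted <- aln$read[ord]
  gene_sorted <- aln$gene[ord]
  nloc <- tabulate(read_sorted, n_reads)
  start <- c(1L, cumsum(nloc) + 1L)[seq_len(n_reads)]
  # a read is "fixed" iff every location gene equals the first one
  first_gene <- gene_sorted[start][read_sorted]
  differs <- gene_sorted != first_gene
  ambiguous <- tabulate(read_sorted[differs], n_reads) > 0L
  fixed <- !ambiguous
  fixed_counts <- tabulate(gene_sorted[start[fixed]], n_genes)
  list(gene_sorted = gene_sorted,
       start = start, nloc = nloc,
       fixed_counts = fixed_counts,
       amb_start = start[ambiguous], amb_nloc = nloc[ambiguous],
       n_reads = n_reads)
}
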