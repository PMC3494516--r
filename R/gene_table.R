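#' Construct a gene table
#'
#' A gene table is the universe over which RPKM is defined: one row per gene
#' model with its name and length in base pairs. Row order is preserved
#' throughout the pipeline and defines the row order of all result tables.
#'
#' @param name Character vector of unique, non-empty gene model names.
#' @param length_bp Integer vector of gene model lengths in base pairs
#'   (all >= 1).
#' @return A `data.frame` of class `gene_table` with columns `name` and
#'   `length_bp`.
#' @export
gene_table <- function(name, length_bp) {
  name <- as.character(name)
  length_bp <- as.integer(length_bp)
  if (length(name) != length(length_bp)) {
    .stopf("name and length_bp must have equal length")
  }
  if (any(is.na(name) | !nzchar(name))) .stopf("gene names must be non-empty")
  dup <- duplicated(name)
  if (any(dup)) .stopf("duplicate gene name: '%s'", name[which(dup)[1L]])
  if (any(is.na(length_bp) | length_bp < 1L)) {
    .stopf("gene lengths must be positive integers")
  }
  structure(
    data.frame(name = name, length_bp = length_bp, stringsAsFactors = FALSE),
    class = c("gene_table", "data.frame")
  )
}

#' Read a tab-separated gene-size file
#'
#' Parses the two-column `name<TAB>length_bp` file (no header) that defines
#' the gene models reads were aligned against. A mismatch between this file
#' and the alignment index silently corrupts the RPKM denominator, so unknown
#' or malformed entries are hard errors, never warnings.
#'
#' @param path Path to the gene-size file.
#' @return A [gene_table] with one row per input line, in input order.
#' @export
parse_gene_size_file <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) .stopf("gene-size file is empty: %s", path)
  parts <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  if (length(parts) < 2L || anyNA(parts[[2L]])) {
    bad <- if (length(parts) < 2L) 1L else which(is.na(parts[[2L]]))[1L]
    .stopf("line %d of %s: expected 'name<TAB>length'", lineno[bad], path)
  }
  name <- parts[[1L]]
  raw_len <- parts[[2L]]
  ok <- grepl("^[0-9]+$", raw_len)
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    .stopf("line %d of %s: gene length '%s' is not a positive integer",
           lineno[bad], path, raw_len[bad])
  }
  len <- as.integer(raw_len)
  if (any(len < 1L)) {
    bad <- which(len < 1L)[1L]
    .stopf("line %d of %s: gene length must be >= 1 (got %d)",
           lineno[bad], path, len[bad])
  }
  dup <- duplicated(name)
  if (any(dup)) {
    bad <- which(dup)[1L]
    .stopf("line %d of %s: duplicate gene name '%s'",
           lineno[bad], path, name[bad])
  }
  gene_table(name, len)
}

#' Write a gene table as a gene-size file
#'
#' @param genes A [gene_table].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_size_file <- function(genes, path) {
  writeLines(paste(genes$name, genes$length_bp, sep = "\t"), path)
  invisible(path)
}
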