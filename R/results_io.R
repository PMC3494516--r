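.EXPRESSION_COLUMNS <- c("gene", "length_bp", "unique_reads", "unique_rpkm",
                         "mean_rpkm", "sd_rpkm", "cnd_pvalue", "bh_pvalue")

#' Write a bootstrap expression estimate table as TSV
#'
#' One row per gene in gene-table order, with header `gene`, `length_bp`,
#' `unique_reads`, `unique_rpkm`, `mean_rpkm`, `sd_rpkm`, `cnd_pvalue`,
#' `bh_pvalue`. Floating values carry at least 6 significant digits so the
#' file round-trips through [read_expression_table()] to printed precision.
#'
#' @param estimates Estimate `data.frame` from [bootstrap_expression()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_table <- function(estimates, path) {
  missing_cols <- setdiff(.EXPRESSION_COLUMNS, names(estimates))
  if (length(missing_cols) > 0L) {
    .stopf("estimates lack column(s): %s", paste(missing_cols, collapse = ", "))
  }
  out <- estimates[, .EXPRESSION_COLUMNS]
  for (col in c("unique_rpkm", "mean_rpkm", "sd_rpkm", "cnd_pvalue",
                "bh_pvalue")) {
    out[[col]] <- formatC(out[[col]], digits = 8, format = "g")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(.EXPRESSION_COLUMNS, collapse = "\t"), con)
  if (nrow(out) > 0L) {
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  }
  invisible(path)
}

#' Read a bootstrap expression estimate table
#'
#' @param path Path to a TSV written by [write_expression_table()].
#' @return The estimate `data.frame`.
#' @export
read_expression_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(gene = "character"))
}

#' Write a baseline RPKM table as TSV
#'
#' Columns: gene, rpkm, expressed.
#'
#' @param rpkm Named per-gene RPKM vector from a baseline method.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_baseline_table <- function(rpkm, path) {
  out <- data.frame(gene = names(rpkm),
                    rpkm = formatC(as.numeric(rpkm), digits = 8, format = "g"),
                    expressed = call_expressed_baseline(as.numeric(rpkm)),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a baseline RPKM table
#'
#' @param path Path to a TSV written by [write_baseline_table()].
#' @return `data.frame` with columns `gene`, `rpkm`, `expressed`.
#' @export
read_baseline_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(gene = "character"))
}
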