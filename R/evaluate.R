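#' Presence/absence accuracy against the simulation truth
#'
#' `(TP + TN) / n` over all genes, where a gene is truth-positive when its
#' expression weight is greater than zero.
#'
#' @param calls Logical vector of per-gene expressed calls, aligned to
#'   `truth`.
#' @param truth Truth table with a `weight` column (see
#'   [assign_expression()]).
#' @return Accuracy in \[0, 1\].
#' @export
classification_accuracy <- function(calls, truth) {
  truth_pos <- .truth_positive(calls, truth)
  mean(calls == truth_pos)
}

#' False positives as a percentage of called genes
#'
#' `100 x FP / n_called`: of the genes called expressed, the percentage that
#' are truth-unexpressed (a precision complement). Returns 0 when no gene is
#' called. The companion rate over truth-negatives is
#' [false_positive_rate_pct()].
#'
#' @inheritParams classification_accuracy
#' @return Percentage in \[0, 100\].
#' @export
false_positive_pct <- function(calls, truth) {
  truth_pos <- .truth_positive(calls, truth)
  n_called <- sum(calls)
  if (n_called == 0L) return(0)
  100 * sum(calls & !truth_pos) / n_called
}

#' False positives as a percentage of truth-negative genes
#'
#' `100 x FP / n_truth_negative`; the classical false-positive rate, exposed
#' alongside [false_positive_pct()]. Returns 0 when there are no
#' truth-negative genes.
#'
#' @inheritParams classification_accuracy
#' @return Percentage in \[0, 100\].
#' @export
false_positive_rate_pct <- function(calls, truth) {
  truth_pos <- .truth_positive(calls, truth)
  n_neg <- sum(!truth_pos)
  if (n_neg == 0L) return(0)
  100 * sum(calls & !truth_pos) / n_neg
}

.truth_positive <- function(calls, truth) {
  if (length(calls) != nrow(truth)) {
    .stopf("calls (%d) and truth (%d rows) must have equal length",
           length(calls), nrow(truth))
  }
  truth$weight > 0
}

#' Spearman rank correlation of calculated vs known expression
#'
#' Pearson correlation of mid-ranks (average ranks for ties, including the
#' tied zeros), computed over all genes in the table.
#'
#' @param calculated Per-gene calculated expression values.
#' @param known Per-gene known expression values, same length >= 2.
#' @return Correlation in \[-1, 1\].
#' @export
expression_spearman <- function(calculated, known) {
  if (length(calculated) != length(known) || length(calculated) < 2L) {
    .stopf("calculated and known must have equal length >= 2")
  }
  if (stats::sd(calculated) == 0 || stats::sd(known) == 0) {
    .stopf("Spearman correlation undefined for a constant vector")
  }
  stats::cor(calculated, known, method = "spearman")
}

#' MA values of calculated vs known expression
#'
#' For each gene with both values strictly positive,
#' `M = log2(calculated / known)` and `A = log2((calculated + known) / 2)`.
#' A perfect estimator places every gene on M = 0; M > 0 is over-reporting.
#' Pairs with a zero (or negative) value on either side are dropped and the
#' dropped count reported via a message.
#'
#' @param calculated,known Per-gene expression values of equal length.
#' @param gene Optional gene names carried into the output.
#' @return `data.frame` with columns `gene` (if given), `M` and `A`.
#' @export
ma_values <- function(calculated, known, gene = NULL) {
  if (length(calculated) != length(known)) {
    .stopf("calculated and known must have equal length")
  }
  keep <- calculated > 0 & known > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(sprintf("ma_values: dropped %d gene(s) with non-positive expression",
                    n_dropped))
  }
  out <- data.frame(M = log2(calculated[keep] / known[keep]),
                    A = log2((calculated[keep] + known[keep]) / 2))
  if (!is.null(gene)) out <- cbind(gene = gene[keep], out)
  out
}

#' Summarise one method's performance on one dataset
#'
#' Bundles the comparison metrics — accuracy, false-positive percentages,
#' Spearman correlation and the number of genes called — into a one-row
#' summary.
#'
#' @param method Method label (e.g. `"bootstrap"`, `"random"`, `"unique"`).
#' @param calculated Per-gene calculated expression values.
#' @param calls Logical per-gene expressed calls.
#' @param truth Truth table with `weight` and `true_rpkm` columns.
#' @return One-row `data.frame`: `method`, `n_called`, `accuracy`,
#'   `false_positive_pct`, `false_positive_rate_pct`, `spearman`.
#' @export
evaluate_method <- function(method, calculated, calls, truth) {
  data.frame(
    method = method,
    n_called = sum(calls),
    accuracy = classification_accuracy(calls, truth),
    false_positive_pct = false_positive_pct(calls, truth),
    false_positive_rate_pct = false_positive_rate_pct(calls, truth),
    spearman = expression_spearman(calculated, truth$true_rpkm),
    stringsAsFactors = FALSE
  )
}
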