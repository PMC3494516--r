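#' Cumulative-normal-distribution p-value for detected expression
#'
#' Models a gene's bootstrap RPKM distribution as Normal(mean, sd) and
#' returns the probability that the distribution includes zero,
#' `P(X <= 0) = pnorm(-mean / sd)`. A value close to zero indicates
#' statistically significant detected expression. Two degenerate rules apply,
#' checked in this order on the exact floating values (no tolerance):
#' a mean of exactly 0 (the gene received no reads in any iteration) gives
#' p = 1; a positive mean with sd exactly 0 (identical counts in every
#' iteration, e.g. only uniquely-aligning reads) gives p = 0.
#'
#' @param mean Bootstrap mean RPKM (vectorised, >= 0).
#' @param sd Bootstrap standard deviation of RPKM (vectorised, >= 0).
#' @return P-value(s) in \[0, 1\].
#' @export
cnd_pvalue <- function(mean, sd) {
  if (length(mean) != length(sd)) {
    if (length(mean) == 1L) mean <- rep_len(mean, length(sd))
    else if (length(sd) == 1L) sd <- rep_len(sd, length(mean))
    else .stopf("mean and sd must have compatible lengths")
  }
  if (any(is.na(mean) | is.na(sd))) .stopf("mean and sd must be non-missing")
  if (any(mean < 0) || any(sd < 0)) .stopf("mean and sd must be non-negative")
  p <- stats::pnorm(0, mean = mean, sd = sd)
  p[sd == 0] <- 0
  p[mean == 0] <- 1
  p
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment: p-values are ranked ascending, each multiplied
#' by m/rank, a cumulative minimum is taken from the largest rank down, values
#' are capped at 1 and returned in the input order.
#'
#' @param pvalues Numeric vector of raw p-values, all in \[0, 1\].
#' @return Adjusted p-values in the input order, each in \[0, 1\].
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) .stopf("pvalues must be non-empty")
  if (any(is.na(pvalues) | pvalues < 0 | pvalues > 1)) {
    .stopf("all p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Call significant detected expression
#'
#' A gene is called expressed when its BH-adjusted p-value is strictly below
#' `alpha`.
#'
#' @param bh_pvalue Vector of BH-adjusted p-values.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return Logical vector, `TRUE` where expression is called.
#' @export
call_expressed <- function(bh_pvalue, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    .stopf("alpha must be a single value in (0, 1)")
  }
  bh_pvalue < alpha
}
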