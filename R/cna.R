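# Discretization of DNA copy-number log2 ratios at a single locus and the
# association between copy gains and expression. Fold-change thresholds:
# 1.5x for gains and losses, 2x for amplifications and homozygous deletions,
# applied symmetrically to log2 ratios with boundary values assigned to the
# altered state.

#' Call a copy-number state from a log2 ratio
#'
#' States: `amplification` (ratio >= 1 = log2 2), `gain`
#' (log2 1.5 <= ratio < 1), `neutral`, `loss` (-1 < ratio <= -log2 1.5),
#' `homozygous_deletion` (ratio <= -1). Vectorized.
#'
#' @param log2_ratio numeric vector of DNA copy log2 ratios.
#' @return character vector of states.
#' @export
call_cna <- function(log2_ratio) {
  if (any(!is.finite(log2_ratio)))
    stop("call_cna: log2 ratios must be finite")
  g <- log2(1.5)
  ifelse(log2_ratio >= 1, "amplification",
  ifelse(log2_ratio >= g, "gain",
  ifelse(log2_ratio <= -1, "homozygous_deletion",
  ifelse(log2_ratio <= -g, "loss", "neutral"))))
}

#' Association between copy-number gains and expression
#'
#' Two-sided two-sample t-test comparing the expression of samples with a
#' gain or amplification against all others (pooled-variance Student t by
#' default; Welch available).
#'
#' @param states character vector of [call_cna()] states.
#' @param expression numeric vector of matching expression values.
#' @param pooled use the pooled-variance Student t (default TRUE).
#' @return list with `t`, `df`, `p`, and per-group means `mean_gain`,
#'   `mean_other`.
#' @export
cna_expression_association <- function(states, expression, pooled = TRUE) {
  stopifnot(length(states) == length(expression))
  gain <- states %in% c("gain", "amplification")
  if (sum(gain) < 2L || sum(!gain) < 2L)
    stop("cna_expression_association: need at least 2 samples per group")
  tt <- stats::t.test(expression[gain], expression[!gain],
                      var.equal = pooled)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       mean_gain = mean(expression[gain]),
       mean_other = mean(expression[!gain]))
}
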