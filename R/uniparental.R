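# Haplotype diversity for uniparental marker sets and the Y/mtDNA ratio.

#' Nei's haplotype diversity
#'
#' `H = n/(n-1) * (1 - sum_i p_i^2)` over haplotype class frequencies
#' `p_i = count_i / n`: the bias-corrected probability that two sampled
#' haplotypes differ.
#'
#' @param counts positive integer counts per haplotype class (a named or
#'   unnamed vector; a `table` works).
#' @return H in \[0, 1\].
#' @export
haplotype_diversity <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts <= 0)) stop("haplotype counts must be positive")
  n <- sum(counts)
  if (n < 2) stop("need at least 2 haplotypes")
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Ratio of two haplotype diversities (e.g. Y over mtDNA)
#'
#' A Y/mt diversity ratio well below 1 is a classic signature of sex-biased
#' demography (e.g. patrilocality with female exogamy). Reported both at
#' full precision and truncated (not rounded) to two decimals, the printing
#' convention used for such ratios.
#'
#' @param H_y numerator diversity (Y chromosome).
#' @param H_mt denominator diversity (mitochondrial), must be > 0.
#' @return list with `ratio` (full precision) and `ratio_2dp` (truncated to
#'   two decimals).
#' @export
diversity_ratio <- function(H_y, H_mt) {
  if (H_mt <= 0) stop("denominator diversity must be > 0")
  r <- H_y / H_mt
  list(ratio = r, ratio_2dp = trunc(r * 100) / 100)
}
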