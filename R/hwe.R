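# Exact test of Hardy-Weinberg equilibrium (classic formulation, no mid-p).

#' Exact Hardy-Weinberg equilibrium p-value
#'
#' Exact conditional test: given the allele counts, the p-value is the sum
#' of the probabilities of all heterozygote counts (of the same parity as
#' the rare-allele count) whose conditional probability does not exceed
#' that of the observed configuration. Probabilities are evaluated in
#' closed form through log-gamma.
#'
#' @param n_hom1 Count of homozygotes for the first allele.
#' @param n_het Heterozygote count.
#' @param n_hom2 Count of homozygotes for the second allele.
#' @return Exact two-sided p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_hom1, n_het, n_hom2) {
  counts <- c(n_hom1, n_het, n_hom2)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_config("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stop_config("all genotype counts are zero")
  n1 <- 2 * n_hom1 + n_het            # allele-1 count
  n2 <- 2 * n_hom2 + n_het
  rare <- min(n1, n2)
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(het = h | allele counts): n! 2^h / (h! ((n1-h)/2)! ((n2-h)/2)!)
  #                                 * n1! n2! / (2n)!
  logp <- lgamma(n + 1) + hets * log(2) - lgamma(hets + 1) -
    lgamma((n1 - hets) / 2 + 1) - lgamma((n2 - hets) / 2 + 1)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_het, hets)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-10)]))
}
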