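# Variant- and sample-level genotype quality control.

#' Quality-control thresholds
#'
#' Defaults follow the conventional candidate-gene pipeline: minor allele
#' frequency >= 1%, per-SNP call rate >= 95%, Hardy-Weinberg exact p >=
#' 5e-7, per-individual missingness <= 3%.
#'
#' @param maf Minimum minor allele frequency.
#' @param call_rate Minimum per-SNP call rate.
#' @param hwe_p Minimum HWE exact p-value.
#' @param ind_missing Maximum per-individual missingness.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf = 0.01, call_rate = 0.95, hwe_p = 5e-7,
                          ind_missing = 0.03) {
  vals <- c(maf = maf, call_rate = call_rate, hwe_p = hwe_p,
            ind_missing = ind_missing)
  if (any(vals < 0 | vals > 1))
    stop_config("QC thresholds must lie in [0, 1]")
  structure(as.list(vals), class = "qc_thresholds")
}

#' Apply genotype quality control
#'
#' Individuals with missingness above the threshold are dropped first; SNP
#' statistics (MAF, call rate, HWE) are then computed on the retained
#' individuals, and failing SNPs removed. A SNP failing several criteria is
#' counted under each.
#'
#' @param dataset A `genotype_dataset`.
#' @param thresholds A [qc_thresholds()] object.
#' @return list(dataset = filtered `genotype_dataset`, report = list of
#'   removal counts and identifiers per criterion).
#' @export
qc_filter <- function(dataset, thresholds = qc_thresholds()) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            inherits(thresholds, "qc_thresholds"))
  g <- dataset$dosage
  ind_miss <- rowMeans(is.na(g))
  drop_ind <- ind_miss > thresholds$ind_missing
  g2 <- g[!drop_ind, , drop = FALSE]

  call_rate <- colMeans(!is.na(g2))
  freq <- colMeans(g2, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  maf[is.nan(maf)] <- 0
  hwe <- vapply(seq_len(ncol(g2)), function(j) {
    tab <- tabulate(g2[, j] + 1L, 3L)        # counts of dosage 0,1,2
    if (sum(tab) == 0) return(1)
    hwe_exact_p(tab[3], tab[2], tab[1])      # hom-effect, het, hom-other
  }, numeric(1))

  fail_maf <- maf < thresholds$maf
  fail_call <- call_rate < thresholds$call_rate
  fail_hwe <- hwe < thresholds$hwe_p
  drop_snp <- fail_maf | fail_call | fail_hwe

  filtered <- genotype_dataset(
    g2[, !drop_snp, drop = FALSE],
    dataset$variants[!drop_snp, , drop = FALSE],
    dataset$samples[!drop_ind, , drop = FALSE])
  report <- list(
    n_individuals_in = nrow(g), n_snps_in = ncol(g),
    n_individuals_removed = sum(drop_ind),
    individuals_removed = dataset$samples$iid[drop_ind],
    n_snps_removed = sum(drop_snp),
    n_snps_removed_maf = sum(fail_maf),
    n_snps_removed_call_rate = sum(fail_call),
    n_snps_removed_hwe = sum(fail_hwe),
    snps_removed_maf = dataset$variants$snp[fail_maf],
    snps_removed_call_rate = dataset$variants$snp[fail_call],
    snps_removed_hwe = dataset$variants$snp[fail_hwe],
    n_individuals_out = nrow(filtered$dosage),
    n_snps_out = ncol(filtered$dosage),
    thresholds = unclass(thresholds))
  list(dataset = filtered, report = report)
}
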