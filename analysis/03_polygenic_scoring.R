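#!/usr/bin/env Rscript
# Stage 3 — LD clumping and best-fit polygenic profile scans.
#
# For each of the eight language base traits: clump the discovery
# association results (r2 > 0.1 within 250 kb, p-ordered), build weighted
# profile scores over the .01-.50 threshold grid, and fit the same trait in
# the replication half (consistency family). Then take the
# expressive-language weights and scan them against DLD status and the five
# SDQ subscales (cross-trait family). Writes scan tables, both family
# tables, and the best-fit SNP sets under results/polygenic/.
#
# Usage: Rscript analysis/03_polygenic_scoring.R

library(polyprofile)

ds <- read_plink("results/cohort/cohort")
phen <- read.table("results/cohort/cohort_phenotypes.tsv", header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
qcr <- jsonlite::read_json("results/association/qc_report.json")
keep_iid <- setdiff(ds$samples$iid, unlist(qcr$individuals_removed))
keep_snp <- setdiff(ds$variants$snp,
                    unlist(qcr[c("snps_removed_maf", "snps_removed_call_rate",
                                 "snps_removed_hwe")]))
ds <- genotype_dataset(ds$dosage[keep_iid, keep_snp],
                       ds$variants[match(keep_snp, ds$variants$snp), ],
                       ds$samples[match(keep_iid, ds$samples$iid), ])
phen <- phen[match(ds$samples$iid, phen$iid), ]
halves <- lapply(jsonlite::read_json("results/association/split.json"),
                 function(x) unlist(x))
assoc <- read.table("results/association/association.tsv", header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)

disc <- genotype_dataset(ds$dosage[halves$discovery, ], ds$variants,
                         ds$samples[halves$discovery, ])
repl <- genotype_dataset(ds$dosage[halves$replication, ], ds$variants,
                         ds$samples[halves$replication, ])
phen_repl <- phen[halves$replication, ]

dir.create("results/polygenic", recursive = TRUE, showWarnings = FALSE)
ld <- ld_r2_matrix(disc)
lang <- unique(assoc$trait)
best_snps <- list()
consistency <- NULL
cat("Consistency family (base trait = target trait, replication fits):\n")
for (tr in lang) {
  atr <- assoc[assoc$trait == tr, ]
  cl <- clump(atr, disc, ld = ld)
  write.table(cl$index, sprintf("results/polygenic/clump_%s.tsv", tr),
              sep = "\t", quote = FALSE, row.names = FALSE)
  w <- atr[atr$snp %in% cl$retained, c("snp", "a1", "beta", "p")]
  scan <- best_fit_scan(repl, w, phen_repl[[tr]])
  write.table(scan$scan, sprintf("results/polygenic/scan_%s.tsv", tr),
              sep = "\t", quote = FALSE, row.names = FALSE)
  best_snps[[tr]] <- scan$best_snps
  b <- scan$best
  consistency <- rbind(consistency, data.frame(
    base = tr, target = tr, threshold = b$threshold, n_snps = b$n_snps,
    r2 = b$r2, beta = b$beta, p = b$p))
  cat(sprintf("  %-14s T*=%.2f  %3d SNPs  R2=%.3f%%  p=%.3f\n",
              tr, b$threshold, b$n_snps, 100 * b$r2, b$p))
  if (tr == "expressive_8y") w_cross <- w
}

cat("Cross-trait family (expressive-language weights):\n")
phen_repl$dld_status_num <- ifelse(phen_repl$dld_status == "affected", 1,
                                   ifelse(phen_repl$dld_status == "unaffected",
                                          0, NA))
cross_targets <- c("dld_status", "emotional_11y", "peer_problems_11y",
                   "conduct_11y", "hyperactivity_11y", "prosociality_11y")
cross <- NULL
cross_best_snps <- list()
for (tg in cross_targets) {
  y <- if (tg == "dld_status") phen_repl$dld_status_num else phen_repl[[tg]]
  scan <- best_fit_scan(repl, w_cross, y)
  write.table(scan$scan, sprintf("results/polygenic/scan_cross_%s.tsv", tg),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cross_best_snps[[tg]] <- scan$best_snps
  b <- scan$best
  cross <- rbind(cross, data.frame(
    base = "expressive_8y", target = tg, threshold = b$threshold,
    n_snps = b$n_snps, r2 = b$r2, beta = b$beta, p = b$p))
  cat(sprintf("  %-18s T*=%.2f  %3d SNPs  R2=%.3f%%  p=%.3f\n",
              tg, b$threshold, b$n_snps, 100 * b$r2, b$p))
}

write.table(consistency, "results/polygenic/consistency.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cross, "results/polygenic/cross_trait.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(consistency = best_snps,
                          cross_trait = cross_best_snps),
                     "results/polygenic/best_fit_snps.json",
                     digits = NA, pretty = TRUE)
cat("Wrote results/polygenic/ (clump, scan, family and SNP-set files)\n")
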