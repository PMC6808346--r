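#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Generates the default synthetic cohort: 5,435 children genotyped at 1,229
# SNPs across the six language/reading candidate genes, thirteen bounded
# instruments, therapy/ASD-like/hearing-like flags, and derived DLD
# caseness. Writes PLINK BED/BIM/FAM, phenotype and flag TSVs, and the
# generating truth under results/cohort/.
#
# Usage: Rscript analysis/01_simulate_cohort.R [seed]

library(polyprofile)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

cfg <- sim_config(seed = derive_seed(seed, "cohort"))
cohort <- simulate_cohort(cfg)
paths <- write_cohort(cohort, "results/cohort", "cohort")

n <- nrow(cohort$phenotypes)
prev <- mean(cohort$caseness == "affected", na.rm = TRUE)
cat(sprintf("Simulated %d individuals x %d SNPs over %d gene blocks\n",
            n, ncol(cohort$genotypes$dosage), nrow(cfg$gene_blocks)))
cat(sprintf("DLD caseness: %d affected (%.1f%%), %d excluded\n",
            sum(cohort$caseness == "affected"), 100 * prev,
            sum(cohort$caseness %in% c("excluded", "excluded_missing"))))
cat("Wrote:\n")
for (p in paths) cat(" -", p, "\n")
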