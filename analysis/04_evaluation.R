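#!/usr/bin/env Rscript
# Stage 4 — multiple-testing control, SNP-set overlap, phenotype
# correlations.
#
# Applies Benjamini-Hochberg adjustment within the consistency (m = 8) and
# cross-trait (m = 6) families, reports which fits survive FDR .05,
# quantifies the overlap between the SNPs behind the expressive-language
# consistency fit and those behind the peer-problems cross-trait fit, and
# tabulates the pairwise phenotype correlation matrix for all thirteen
# measures. Writes under results/evaluation/.
#
# Usage: Rscript analysis/04_evaluation.R

library(polyprofile)

consistency <- read.table("results/polygenic/consistency.tsv", header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
cross <- read.table("results/polygenic/cross_trait.tsv", header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
fam <- run_test_families(consistency, cross)

cat("Consistency family after BH adjustment (m = 8):\n")
print(fam$consistency[, c("base", "threshold", "n_snps", "r2", "p",
                          "p_adjusted", "significant")], row.names = FALSE)
cat("Cross-trait family after BH adjustment (m = 6):\n")
print(fam$cross_trait[, c("target", "threshold", "n_snps", "r2", "p",
                          "p_adjusted", "significant")], row.names = FALSE)

sets <- jsonlite::read_json("results/polygenic/best_fit_snps.json")
ov <- subset_overlap(unlist(sets$consistency$expressive_8y),
                     unlist(sets$cross_trait$peer_problems_11y),
                     label_a = "expressive_8y (consistency)",
                     label_b = "peer_problems_11y (cross-trait)")
cat(sprintf("\nBest-fit SNP overlap: %d of %d (%d%%) of the expressive-language\n",
            ov$n_shared, ov$n_a, ov$pct_of_a_rounded))
cat(sprintf("SNPs also contribute to peer problems; subset: %s\n",
            ov$subset))

phen <- read.table("results/cohort/cohort_phenotypes.tsv", header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
traits <- setdiff(names(phen), c("iid", "dld_status"))
corrs <- phenotype_correlations(phen[, traits])

dir.create("results/evaluation", recursive = TRUE, showWarnings = FALSE)
write.table(fam$consistency, "results/evaluation/family_consistency.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(fam$cross_trait, "results/evaluation/family_cross_trait.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(ov[c("label_a", "label_b", "n_a", "n_b", "n_shared",
                          "pct_of_a", "pct_of_a_rounded", "subset")],
                     "results/evaluation/overlap.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
write.table(format_correlations(corrs),
            "results/evaluation/correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Wrote results/evaluation/\n")
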