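#!/usr/bin/env Rscript
# Stage 2 — quality control, half-split, discovery association scan.
#
# Reads the cohort written by stage 1, applies the variant/sample QC
# filters, splits the cohort into discovery and replication halves, and
# scans every SNP against the eight language measures in the discovery
# half. Writes the QC report, split indices, association table, and the
# gene x trait minimum-p summary under results/association/.
#
# Usage: Rscript analysis/02_qc_association.R [seed]

library(polyprofile)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

ds <- assign_genes(read_plink("results/cohort/cohort"))
phen <- read.table("results/cohort/cohort_phenotypes.tsv", header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)

qc <- qc_filter(ds, qc_thresholds())
ds <- qc$dataset
phen <- phen[match(ds$samples$iid, phen$iid), ]
cat(sprintf("QC: %d individuals and %d SNPs retained (removed: %d ind, %d SNPs)\n",
            qc$report$n_individuals_out, qc$report$n_snps_out,
            qc$report$n_individuals_removed, qc$report$n_snps_removed))

halves <- split_cohort(nrow(ds$dosage), seed = derive_seed(seed, "split"))
cat(sprintf("Split: discovery n = %d, replication n = %d\n",
            length(halves$discovery), length(halves$replication)))

disc <- genotype_dataset(ds$dosage[halves$discovery, ], ds$variants,
                         ds$samples[halves$discovery, ])
lang <- c("vocab_15m", "vocab_24m", "receptive_15m", "grammar_24m",
          "receptive_8y", "expressive_8y", "nonword_8y", "pragmatic_9y")
assoc <- assoc_scan(disc, phen[halves$discovery, ], lang)
cat(sprintf("Association: %d tests (%d traits x %d SNPs); min p = %.3g (%s / %s)\n",
            nrow(assoc), length(lang), ncol(disc$dosage),
            min(assoc$p), assoc$gene[which.min(assoc$p)],
            assoc$trait[which.min(assoc$p)]))

minp <- gene_min_p(assoc)

dir.create("results/association", recursive = TRUE, showWarnings = FALSE)
jsonlite::write_json(qc$report, "results/association/qc_report.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
jsonlite::write_json(halves, "results/association/split.json",
                     digits = NA, pretty = TRUE)
write.table(assoc, "results/association/association.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cbind(gene = rownames(minp$matrix),
                  as.data.frame(minp$matrix)),
            "results/association/gene_min_p.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Wrote results/association/{qc_report.json,split.json,association.tsv,gene_min_p.tsv}\n")
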