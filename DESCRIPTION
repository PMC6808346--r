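Package: polyprofile
Title: Candidate-Gene Polygenic Profile Scores for Language and
    Psychosocial Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A discovery-replication polygenic profile (PRS) pipeline for
    candidate-gene studies of child language and psychosocial development.
    Simulates genotype-phenotype cohorts with block LD structure, bounded
    ordinal instruments, and a weak pleiotropic polygenic architecture;
    reads and writes PLINK binary genotypes with variant- and sample-level
    quality control; runs per-SNP additive linear association scans;
    performs greedy LD clumping; builds p-value-thresholded weighted
    profile scores with a best-fit threshold scan; and evaluates base and
    cross-trait prediction in a replication half-cohort with
    Benjamini-Hochberg control over each test family.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
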