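# Synthetic cohort generator

test_that("genotype simulation honours allele frequencies and determinism", {
  blocks <- data.frame(gene = "G1", chr = 1L, start = 1e6, end = 2e6,
                       n_snps = 20L, ld_rho = 0)
  cfg <- sim_config(n_individuals = 10000, gene_blocks = blocks,
                    allele_freq_range = c(0.3, 0.3), missing_rate = 0,
                    architectures = list(), seed = 11)
  g <- simulate_genotypes(cfg)
  emp <- colMeans(g$dosage) / 2
  expect_true(all(abs(emp - 0.3) < 0.02))
  expect_true(all(g$dosage %in% 0:2))
  g2 <- simulate_genotypes(cfg)
  expect_identical(g$dosage, g2$dosage)
  expect_identical(g$variants, g2$variants)
})

test_that("latent AR(1) autocorrelation induces adjacent-pair LD", {
  adj_r2 <- function(rho, seed) {
    blocks <- data.frame(gene = "G1", chr = 1L, start = 1e6, end = 2e6,
                         n_snps = 6L, ld_rho = rho)
    cfg <- sim_config(n_individuals = 300, gene_blocks = blocks,
                      allele_freq_range = c(0.2, 0.5), missing_rate = 0,
                      architectures = list(), seed = seed)
    g <- simulate_genotypes(cfg)$dosage
    mean(sapply(seq_len(ncol(g) - 1),
                function(j) dosage_r2(g[, j], g[, j + 1])), na.rm = TRUE)
  }
  with_ld <- sapply(1:50, function(s) adj_r2(0.9, s))
  without <- sapply(1:50, function(s) adj_r2(0, s))
  expect_gt(mean(with_ld), mean(without))
})

test_that("default gene blocks total 1229 SNPs over six loci", {
  b <- default_gene_blocks()
  expect_equal(nrow(b), 6)
  expect_equal(sum(b$n_snps), 1229)
  expect_setequal(b$gene, c("ATP2C2", "CMIP", "CNTNAP2", "DCDC2", "FOXP2",
                            "KIAA0319"))
})

test_that("phenotype simulation controls the genetic variance fraction", {
  blocks <- data.frame(gene = "G1", chr = 1L, start = 1e6, end = 2e6,
                       n_snps = 30L, ld_rho = 0)
  cfg <- sim_config(n_individuals = 5000, gene_blocks = blocks,
                    allele_freq_range = c(0.2, 0.5), missing_rate = 0,
                    architectures = list(), seed = 3)
  g <- simulate_genotypes(cfg)

  null_arch <- trait_architecture("t", 1:10, rnorm(10), 0, c(0, 100))
  s0 <- simulate_phenotypes(g, null_arch, seed = 7)
  expect_lt(cor(s0$values, s0$genetic_raw)^2, 0.01)

  arch <- trait_architecture("t", 1:10, s0$architecture$beta, 0.2,
                             c(0, 100))
  s <- simulate_phenotypes(g, arch, seed = 7)
  ratio <- var(s$genetic) / var(s$latent)
  expect_lt(abs(ratio - 0.2), 0.05)

  # identical causal sets and effect sizes -> identical genetic components
  a1 <- trait_architecture("a", 1:10, arch$beta, 0.5, c(0, 100))
  a2 <- trait_architecture("b", 1:10, arch$beta, 0.5, c(0, 100))
  g1 <- simulate_phenotypes(g, a1, seed = 21)$genetic
  g2 <- simulate_phenotypes(g, a2, seed = 22)$genetic
  expect_equal(cor(g1, g2), 1)
})

test_that("genetic-component correlation rises with the shared fraction", {
  blocks <- data.frame(gene = "G1", chr = 1L, start = 1e6, end = 2e6,
                       n_snps = 40L, ld_rho = 0)
  cors <- sapply(1:20, function(rep) {
    cfg <- sim_config(n_individuals = 400, gene_blocks = blocks,
                      allele_freq_range = c(0.2, 0.5), missing_rate = 0,
                      architectures = list(), seed = rep)
    g <- simulate_genotypes(cfg)
    set.seed(1000 + rep)
    beta <- rnorm(10)
    base <- trait_architecture("base", 1:10, beta, 0.5, c(0, 100))
    gb <- simulate_phenotypes(g, base, seed = rep)$genetic_raw
    sapply(c(0, 0.5, 1), function(f) {
      k <- round(10 * f)
      causal <- c(seq_len(k), 10 + seq_len(10 - k))   # swap in fresh SNPs
      b2 <- beta
      if (k < 10) b2[(k + 1):10] <- rnorm(10 - k)
      other <- trait_architecture("other", causal, b2, 0.5, c(0, 100))
      cor(gb, simulate_phenotypes(g, other, seed = rep + 500)$genetic_raw)
    })
  })
  avg <- rowMeans(cors)
  expect_lt(avg[1], avg[2])
  expect_lt(avg[2], avg[3])
})

test_that("instrument scores respect their configured bounds", {
  cohort <- simulate_cohort(small_sim_config(n = 300, seed = 9))
  for (tr in setdiff(names(cohort$phenotypes), "iid")) {
    b <- INSTRUMENT_BOUNDS_OF(tr)
    expect_true(all(cohort$phenotypes[[tr]] >= b[1] &
                      cohort$phenotypes[[tr]] <= b[2]),
                info = tr)
    expect_true(all(cohort$phenotypes[[tr]] ==
                      round(cohort$phenotypes[[tr]])), info = tr)
  }
})

test_that("DLD caseness follows the two-of-four criterion rule", {
  n_bg <- 2000
  set.seed(4)
  base <- as.vector(scale(rnorm(n_bg)))      # mean 0, sd 1 exactly
  prag <- c(base, -1.5, 0, -1.5)
  nonw <- c(base, -1.2, 0, -1.3)
  rece <- c(base, 0.2, 0, -1.4)
  ther <- c(rep(FALSE, n_bg), FALSE, FALSE, FALSE)
  asd <- c(rep(FALSE, n_bg), FALSE, FALSE, TRUE)
  idx <- n_bg + 1:3
  st <- derive_dld_status(prag, nonw, rece, ther, asd = asd)
  expect_equal(as.character(st[idx]),
               c("affected",        # two z < -1 criteria
                 "unaffected",      # at the sample mean, no therapy
                 "excluded"))       # three criteria but ASD flag set

  # missing criterion input -> excluded for missingness
  prag[idx[1]] <- NA
  st2 <- derive_dld_status(prag, nonw, rece, ther)
  expect_equal(as.character(st2[idx[1]]), "excluded_missing")

  # prevalence is monotone non-increasing in cutoff severity; no criteria,
  # no cases
  prev <- sapply(c(-0.5, -1, -1.5), function(z)
    mean(derive_dld_status(prag, nonw, rece, ther, z_cutoff = z) ==
           "affected", na.rm = TRUE))
  expect_true(all(diff(prev) <= 0))
  st3 <- derive_dld_status(prag, nonw, rece, ther, criteria = character(0))
  expect_true(!any(st3 == "affected"))
})

test_that("cohort split is a random equal partition", {
  s <- split_cohort(5435, seed = 2)
  expect_equal(length(s$discovery), 2718)
  expect_equal(length(s$replication), 2717)
  expect_equal(sort(c(s$discovery, s$replication)), 1:5435)

  expect_equal(lengths(split_cohort(2, seed = 1)), c(discovery = 1L,
                                                     replication = 1L))
  for (n in c(7, 100)) for (seed in 1:3) {
    sp <- split_cohort(n, seed)
    expect_length(intersect(sp$discovery, sp$replication), 0)
    expect_setequal(c(sp$discovery, sp$replication), seq_len(n))
  }
  expect_error(split_cohort(1), "n >= 2")
})

test_that("configuration errors are caught", {
  expect_error(sim_config(n_individuals = 0), "positive")
  blocks <- default_gene_blocks(ld_rho = 1)
  expect_error(sim_config(gene_blocks = blocks), "ld_rho")
  expect_error(sim_config(allele_freq_range = c(0, 0.5)), "frequencies")
  expect_error(trait_architecture("t", 1:3, rnorm(3), 1, c(0, 10)), "h2")
})
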