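# Per-SNP linear association

test_that("assoc_linear matches lm on the five-point example", {
  g <- c(0, 1, 2, 1, 0)
  y <- c(1.0, 1.5, 2.1, 1.4, 0.9)
  row <- assoc_linear(g, y)
  fit <- summary(lm(y ~ g))
  expect_equal(row$beta, fit$coefficients[2, 1], tolerance = 1e-10)
  expect_equal(row$se, fit$coefficients[2, 2], tolerance = 1e-10)
  expect_equal(row$p, fit$coefficients[2, 4], tolerance = 1e-10)
  expect_equal(row$n, 5)
})

test_that("exact linear and degenerate cases behave as specified", {
  g <- c(0, 1, 2, 0, 2, 1)
  exact <- assoc_linear(g, g)
  expect_equal(exact$beta, 1)
  expect_lt(exact$p, 1e-100)

  mono <- assoc_linear(rep(2, 10), rnorm(10))
  expect_true(mono$degenerate)
  expect_equal(mono$p, 1)
  expect_true(is.na(mono$beta))
  expect_error(assoc_linear(c(0, 1), c(1, 2)), "3 complete")
})

test_that("beta and p transform correctly under phenotype and allele maps", {
  set.seed(6)
  g <- rbinom(40, 2, 0.4)
  y <- rnorm(40) + 0.3 * g
  base <- assoc_linear(g, y)
  shifted <- assoc_linear(g, y + 100)
  expect_equal(shifted$beta, base$beta, tolerance = 1e-12)
  expect_equal(shifted$p, base$p, tolerance = 1e-12)
  scaled <- assoc_linear(g, 3 * y)
  expect_equal(scaled$beta, 3 * base$beta, tolerance = 1e-12)
  expect_equal(scaled$p, base$p, tolerance = 1e-12)
  flipped <- assoc_linear(2 - g, y)
  expect_equal(flipped$beta, -base$beta, tolerance = 1e-12)
  expect_equal(flipped$p, base$p, tolerance = 1e-12)
})

test_that("assoc_scan agrees with assoc_linear row by row", {
  ds <- make_dataset(n = 80, m = 12, seed = 7, miss = 0.05)
  phen <- data.frame(iid = ds$samples$iid,
                     t1 = rnorm(80) + 0.4 * ifelse(is.na(ds$dosage[, 1]), 0,
                                                   ds$dosage[, 1]),
                     t2 = rnorm(80))
  scan <- assoc_scan(ds, phen)
  expect_equal(nrow(scan), 2 * 12)
  for (j in c(1, 5, 12)) for (tr in c("t1", "t2")) {
    row <- scan[scan$snp == ds$variants$snp[j] & scan$trait == tr, ]
    ref <- assoc_linear(ds$dosage[, j], phen[[tr]])
    expect_equal(row$beta, ref$beta, tolerance = 1e-12)
    expect_equal(row$p, ref$p, tolerance = 1e-12)
    expect_equal(row$n, ref$n)
  }
  expect_error(assoc_scan(ds, phen, "absent_trait"), "absent_trait")
})

test_that("null p-values are uniform across independent SNPs", {
  ds <- make_dataset(n = 300, m = 400, seed = 9, miss = 0)
  set.seed(10)
  phen <- data.frame(iid = ds$samples$iid, y = rnorm(300))
  scan <- assoc_scan(ds, phen)
  expect_gt(ks.test(scan$p, "punif")$p.value, 0.01)
  expect_lt(abs(mean(scan$p < 0.05) - 0.05), 0.03)
})

test_that("gene_min_p reproduces a brute-force minimum scan", {
  set.seed(11)
  tab <- expand.grid(gene = c("GA", "GB", "GC"), trait = c("x", "y"),
                     idx = 1:5, stringsAsFactors = FALSE)
  tab$snp <- sprintf("s%02d", seq_len(nrow(tab)))
  tab$p <- runif(nrow(tab))
  res <- gene_min_p(tab)
  for (g in c("GA", "GB", "GC")) for (tr in c("x", "y")) {
    expect_equal(res$matrix[g, tr],
                 min(tab$p[tab$gene == g & tab$trait == tr]))
  }
  expect_equal(res$overall$min_p, min(tab$p))
  expect_equal(min(res$gene_min$min_p), min(tab$p))
  expect_equal(min(res$trait_min$min_p), min(tab$p))
  # single gene/trait cell minimum
  small <- data.frame(gene = "G1", trait = "t", snp = c("a", "b", "c"),
                      p = c(.3, .02, .5))
  expect_equal(gene_min_p(small)$matrix["G1", "t"], 0.02)
})
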