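# LD clumping

test_that("dosage_r2 basics and formula oracle", {
  a <- c(0, 0, 1, 1, 2, 2)
  expect_equal(dosage_r2(a, a), 1)
  expect_equal(dosage_r2(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)  # sign-invariant
  expect_true(is.na(dosage_r2(rep(1, 5), c(0, 1, 2, 0, 1))))
  set.seed(2)
  for (i in 1:20) {
    x <- rbinom(30, 2, 0.4)
    y <- rbinom(30, 2, 0.3)
    if (sd(x) == 0 || sd(y) == 0) next
    num <- sum((x - mean(x)) * (y - mean(y)))
    oracle <- num^2 / (sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(dosage_r2(x, y), oracle, tolerance = 1e-12)
  }
})

test_that("uncorrelated SNPs all become index SNPs", {
  ds <- make_dataset(n = 200, m = 3, seed = 3, miss = 0)
  a <- data.frame(snp = ds$variants$snp, chr = 1L, bp = ds$variants$bp,
                  p = c(.01, .02, .03))
  res <- clump(a, ds, r2_threshold = 0.5)
  expect_equal(length(res$retained), 3)
  expect_true(all(res$index$n_members == 0))
})

test_that("perfect LD collapses to the best-p index SNP", {
  g <- rbinom(100, 2, 0.4)
  ds <- genotype_dataset(
    cbind(s1 = g, s2 = g, s3 = 2L - g),
    data.frame(snp = c("s1", "s2", "s3"), chr = 1L,
               bp = c(1000L, 2000L, 3000L), a1 = "A", a2 = "G"),
    data.frame(fid = paste0("f", 1:100), iid = paste0("i", 1:100)))
  a <- data.frame(snp = c("s1", "s2", "s3"), chr = 1L,
                  bp = c(1000, 2000, 3000), p = c(.01, .001, .02))
  res <- clump(a, ds, r2_threshold = 0.8, window_kb = 250)
  expect_equal(res$retained, "s2")
  expect_equal(res$index$n_members, 2)
})

test_that("greedy clumping matches the brute-force oracle on seeded instances", {
  for (seed in 1:25) {
    set.seed(seed)
    m <- 15
    ds <- make_dataset(n = 60, m = m, seed = seed, miss = 0.05,
                       chr = sample(1:2, m, TRUE),
                       bp = as.integer(sample.int(500, m) * 1000))
    # duplicate some columns to create strong LD
    dup <- sample(m, 4)
    ds$dosage[, dup[1:2]] <- ds$dosage[, dup[3:4]]
    a <- data.frame(snp = ds$variants$snp, chr = ds$variants$chr,
                    bp = ds$variants$bp, p = runif(m))
    res <- clump(a, ds, r2_threshold = 0.2, window_kb = 100, p_ceiling = 0.9)
    oracle <- clump_oracle(a, ds, r2_threshold = 0.2, window_kb = 100,
                           p_ceiling = 0.9)
    expect_identical(res$retained, oracle)
  }
})

test_that("clump output is invariant to input row order", {
  ds <- make_dataset(n = 100, m = 12, seed = 5, miss = 0)
  a <- data.frame(snp = ds$variants$snp, chr = 1L, bp = ds$variants$bp,
                  p = runif(12))
  r1 <- clump(a, ds, r2_threshold = 0.1, window_kb = 5)
  r2 <- clump(a[sample(12), ], ds, r2_threshold = 0.1, window_kb = 5)
  expect_identical(r1$retained, r2$retained)
})

test_that("index SNPs are mutually clump-free and monotone in r2 threshold", {
  ds <- make_dataset(n = 150, m = 20, seed = 6, miss = 0)
  ds$dosage[, 2] <- ds$dosage[, 1]
  ds$dosage[, 10] <- pmin(ds$dosage[, 9] + rbinom(150, 1, 0.1), 2L)
  a <- data.frame(snp = ds$variants$snp, chr = 1L, bp = ds$variants$bp,
                  p = runif(20))
  sizes <- sapply(c(0.05, 0.2, 0.5, 0.9), function(r2t) {
    res <- clump(a, ds, r2_threshold = r2t, window_kb = 250)
    idx <- match(res$retained, ds$variants$snp)
    for (i in idx) for (j in idx) {
      if (i >= j) next
      if (abs(ds$variants$bp[i] - ds$variants$bp[j]) > 250000) next
      r2 <- dosage_r2(ds$dosage[, i], ds$dosage[, j])
      expect_true(is.na(r2) || r2 <= r2t)
    }
    length(res$retained)
  })
  expect_true(all(diff(sizes) >= 0))
})

test_that("precomputed LD lookup reproduces on-the-fly clumping", {
  ds <- make_dataset(n = 120, m = 18, seed = 8, miss = 0.05,
                     chr = rep(1:2, each = 9))
  a <- data.frame(snp = ds$variants$snp, chr = ds$variants$chr,
                  bp = ds$variants$bp, p = runif(18))
  ld <- ld_r2_matrix(ds)
  expect_identical(clump(a, ds, ld = ld)$retained, clump(a, ds)$retained)
})

test_that("empty input yields an empty result", {
  ds <- make_dataset(n = 50, m = 2, seed = 9)
  a <- data.frame(snp = character(0), chr = integer(0), bp = integer(0),
                  p = numeric(0))
  expect_length(clump(a, ds)$retained, 0)
})
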