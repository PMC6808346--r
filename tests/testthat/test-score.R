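# Profile scoring and the threshold scan

test_that("threshold grid is .01 to .50 in 50 equal steps", {
  g <- threshold_grid()
  expect_length(g, 50)
  expect_equal(g[1], 0.01)
  expect_equal(g[50], 0.50)
  expect_true(all(abs(diff(g) - 0.01) < 1e-12))
})

two_snp_dataset <- function(dosages) {
  genotype_dataset(
    matrix(dosages, nrow = 1,
           dimnames = list("i1", c("s1", "s2"))),
    data.frame(snp = c("s1", "s2"), chr = 1L, bp = c(100L, 200L),
               a1 = "A", a2 = "G"),
    data.frame(fid = "f1", iid = "i1"))
}

test_that("score is the beta-weighted dosage average", {
  ds <- two_snp_dataset(c(2L, 1L))
  w <- data.frame(snp = c("s1", "s2"), a1 = "A", beta = c(0.5, -0.2),
                  p = c(0.01, 0.01))
  sc <- compute_score(ds, w, threshold = 0.5)
  expect_equal(unname(sc$values), 0.4)     # (0.5*2 + (-0.2)*1)/2
  expect_equal(sc$n_snps, 2)

  dbl <- w; dbl$beta <- 2 * dbl$beta
  expect_equal(unname(compute_score(ds, dbl, 0.5)$values), 0.8)

  empty <- compute_score(ds, w, threshold = 0.001)
  expect_true(empty$empty)
  expect_true(all(is.na(empty$values)))
})

test_that("allele flips with negated beta leave scores unchanged", {
  ds <- make_dataset(n = 40, m = 6, seed = 3, miss = 0.05)
  set.seed(4)
  w <- data.frame(snp = ds$variants$snp, a1 = "A", beta = rnorm(6),
                  p = runif(6, 0, 0.4))
  flipped <- w
  flipped$a1 <- "G"
  flipped$beta <- -flipped$beta
  s1 <- compute_score(ds, w, 0.5)
  s2 <- compute_score(ds, flipped, 0.5)
  expect_equal(s1$values, s2$values, tolerance = 1e-12)

  bad <- w; bad$a1[2] <- "T"
  expect_error(compute_score(ds, bad, 0.5), "irreconcilable.*s002")
})

test_that("missing dosages are imputed at twice the allele frequency", {
  g <- matrix(c(0L, 2L, NA, 2L), 4, 1, dimnames = list(NULL, "s1"))
  ds <- genotype_dataset(
    g, data.frame(snp = "s1", chr = 1L, bp = 1L, a1 = "A", a2 = "G"),
    data.frame(fid = paste0("f", 1:4), iid = paste0("i", 1:4)))
  w <- data.frame(snp = "s1", a1 = "A", beta = 1, p = 0.01)
  sc <- compute_score(ds, w, 0.5)
  expect_equal(unname(sc$values[3]), mean(c(0, 2, 2)))
})

test_that("fit_score_model matches lm and handles degenerate scores", {
  set.seed(5)
  x <- rnorm(50)
  y <- 2 - 0.7 * x + rnorm(50, sd = 0.5)
  fit <- fit_score_model(x, y)
  ref <- summary(lm(y ~ x))
  expect_equal(fit$r2, ref$r.squared, tolerance = 1e-10)
  expect_equal(fit$beta, ref$coefficients[2, 1], tolerance = 1e-10)
  expect_equal(fit$p, ref$coefficients[2, 4], tolerance = 1e-10)

  affine <- fit_score_model(x, 3 * x - 1)
  expect_equal(affine$r2, 1)

  degen <- fit_score_model(rep(1, 20), rnorm(20))
  expect_true(degen$degenerate)
  expect_equal(degen$r2, 0)
  expect_equal(degen$p, 1)
})

test_that("null scores explain almost nothing at replication scale", {
  set.seed(6)
  r2s <- replicate(200, {
    n <- 2717
    fit_score_model(rnorm(n), rnorm(n))$r2
  })
  expect_gt(mean(r2s < 0.005), 0.95)
})

test_that("best_fit_scan matches an exhaustive per-threshold re-fit", {
  ds <- make_dataset(n = 150, m = 20, seed = 7, miss = 0.05)
  set.seed(8)
  w <- data.frame(snp = ds$variants$snp, a1 = "A", beta = rnorm(20),
                  p = runif(20, 0, 0.6))
  y <- rnorm(150) + 0.5 * scale(ds$dosage[, 3], scale = FALSE)[, 1]
  y[is.na(y)] <- 0
  grid <- threshold_grid()
  res <- best_fit_scan(ds, w, y, grid)
  for (i in seq_along(grid)) {
    sc <- compute_score(ds, w, grid[i])
    if (sc$empty) {
      expect_equal(res$scan$n_snps[i], 0)
      next
    }
    ref <- fit_score_model(sc, y)
    expect_equal(res$scan$r2[i], ref$r2, tolerance = 1e-12)
    expect_equal(res$scan$p[i], ref$p, tolerance = 1e-12)
    expect_equal(res$scan$n_snps[i], ref$n_snps)
  }
  expect_true(all(diff(res$scan$n_snps) >= 0))        # nested S(T)
  best_ref <- which.max(res$scan$r2)
  expect_equal(res$best$threshold, grid[best_ref])
  expect_length(res$best_snps, res$best$n_snps)
})

test_that("a dominant SNP is picked up at the first grid point that admits it", {
  ds <- make_dataset(n = 300, m = 10, seed = 9, miss = 0)
  y <- as.numeric(ds$dosage[, 4]) * 2 + rnorm(300, sd = 0.1)
  p <- rep(0.45, 10)
  p[4] <- 1e-8
  w <- data.frame(snp = ds$variants$snp, a1 = "A",
                  beta = c(rep(0.01, 3), 2, rep(0.01, 6)), p = p)
  res <- best_fit_scan(ds, w, y, threshold_grid())
  expect_equal(res$best$threshold, 0.01)
  expect_equal(res$best$n_snps, 1)
  expect_equal(res$best_snps, ds$variants$snp[4])
})

test_that("all-empty grids are an error", {
  ds <- make_dataset(n = 50, m = 3, seed = 10)
  w <- data.frame(snp = ds$variants$snp, a1 = "A", beta = 1:3, p = rep(0.9, 3))
  expect_error(best_fit_scan(ds, w, rnorm(50), grid = c(0.01, 0.1)), "empty")
})
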