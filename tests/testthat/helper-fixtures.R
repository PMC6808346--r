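# Shared fixtures and independent oracles, all built in code.

# small genotype dataset with optional missingness; one or two chromosomes
make_dataset <- function(n = 60, m = 10, seed = 1, miss = 0,
                         chr = rep(1L, m), bp = NULL,
                         freq = runif(m, 0.2, 0.5)) {
  set.seed(seed)
  freq <- rep_len(freq, m)
  g <- sapply(freq, function(f) stats::rbinom(n, 2, f))
  if (miss > 0) g[stats::runif(length(g)) < miss] <- NA
  v <- data.frame(snp = sprintf("s%03d", seq_len(m)), chr = chr,
                  bp = bp %||% as.integer(seq_len(m) * 1000L),
                  a1 = "A", a2 = "G",
                  gene = paste0("G", chr), stringsAsFactors = FALSE)
  s <- data.frame(fid = sprintf("f%03d", seq_len(n)),
                  iid = sprintf("i%03d", seq_len(n)),
                  sex = 1L, stringsAsFactors = FALSE)
  genotype_dataset(matrix(as.integer(g), n, m), v, s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent HWE oracle: Wigginton-style recurrence over heterozygote
# counts (the package uses a log-gamma closed form instead).
hwe_oracle <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  n1 <- 2 * n_hom1 + n_het
  n2 <- 2 * n_hom2 + n_het
  rare <- min(n1, n2)
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hets))
  mid <- which.min(abs(hets - rare * (n1 + n2 - rare) / (n1 + n2)))
  probs[mid] <- 1
  # P(h-2)/P(h) = h(h-1) / ((n1-h+2)(n2-h+2))  [allele-1/allele-2 halves]
  if (mid > 1) for (k in seq(mid - 1, 1)) {
    h <- hets[k + 1]
    probs[k] <- probs[k + 1] * h * (h - 1) /
      ((n1 - h + 2) * (n2 - h + 2))
  }
  if (mid < length(hets)) for (k in seq(mid + 1, length(hets))) {
    h <- hets[k - 1]
    probs[k] <- probs[k - 1] * (n1 - h) * (n2 - h) / ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

# Brute-force greedy clumping oracle: sorts by (p, bp, snp) and applies the
# rule with exhaustive per-pair dosage_r2 checks.
clump_oracle <- function(assoc, dataset, r2_threshold = 0.1,
                         window_kb = 250, p_ceiling = 1) {
  a <- assoc[!is.na(assoc$p) & assoc$p <= p_ceiling, , drop = FALSE]
  a <- a[order(a$p, a$bp, a$snp), , drop = FALSE]
  g <- dataset$dosage[, match(a$snp, colnames(dataset$dosage)), drop = FALSE]
  assigned <- rep(FALSE, nrow(a))
  retained <- character(0)
  for (i in seq_len(nrow(a))) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    retained <- c(retained, a$snp[i])
    for (j in seq_len(nrow(a))) {
      if (assigned[j]) next
      if (a$chr[j] != a$chr[i]) next
      if (abs(a$bp[j] - a$bp[i]) > window_kb * 1000) next
      r2 <- dosage_r2(g[, i], g[, j])
      if (!is.na(r2) && r2 > r2_threshold) assigned[j] <- TRUE
    }
  }
  retained
}

# tiny 3-block simulation config for pipeline-level tests
small_sim_config <- function(n = 400, snps_per_block = 15, seed = 5,
                             h2_expr = 0.2) {
  blocks <- data.frame(
    gene = c("GENE1", "GENE2", "GENE3"), chr = c(1L, 2L, 2L),
    start = c(1e6, 1e6, 2e6), end = c(1.1e6, 1.1e6, 2.1e6),
    n_snps = snps_per_block, ld_rho = 0.5)
  m <- 3 * snps_per_block
  set.seed(seed + 1)
  expr_causal <- sort(sample.int(m, 6))
  expr_beta <- rnorm(6)
  shared <- expr_causal[1:3]
  arch <- list()
  for (tr in polyprofile:::LANGUAGE_TRAITS) {
    if (tr == "expressive_8y")
      arch[[tr]] <- trait_architecture(tr, expr_causal, expr_beta, h2_expr,
                                       INSTRUMENT_BOUNDS_OF(tr))
    else
      arch[[tr]] <- trait_architecture(tr, sort(sample.int(m, 4)), rnorm(4),
                                       0.05, INSTRUMENT_BOUNDS_OF(tr))
  }
  for (tr in polyprofile:::SDQ_TRAITS) {
    if (tr == "peer_problems_11y") {
      causal <- sort(c(shared, sample(setdiff(seq_len(m), expr_causal), 3)))
      beta <- rnorm(6)
      beta[match(shared, causal)] <- expr_beta[match(shared, expr_causal)]
      arch[[tr]] <- trait_architecture(
        tr, causal, beta, h2_expr, INSTRUMENT_BOUNDS_OF(tr),
        shared_with = list(trait = "expressive_8y", indices = shared))
    } else {
      arch[[tr]] <- trait_architecture(tr, sort(sample.int(m, 4)), rnorm(4),
                                       0.02, INSTRUMENT_BOUNDS_OF(tr))
    }
  }
  sim_config(n_individuals = n, gene_blocks = blocks,
             allele_freq_range = c(0.2, 0.5), missing_rate = 0.01,
             architectures = arch, seed = seed)
}

INSTRUMENT_BOUNDS_OF <- function(tr) polyprofile:::INSTRUMENT_BOUNDS[[tr]]
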