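# Synthetic cohort generator
#
# Emulates a candidate-gene study cohort: six gene loci carrying 1,229 SNPs
# in total, ~5,435 children, eight bounded language instruments, five SDQ
# subscales (0-10), derived DLD caseness, and a weak additive polygenic
# architecture in which an expressive-language-like trait and a
# peer-problems-like trait share part of their causal variants.

LANGUAGE_TRAITS <- c("vocab_15m", "vocab_24m", "receptive_15m", "grammar_24m",
                     "receptive_8y", "expressive_8y", "nonword_8y",
                     "pragmatic_9y")
SDQ_TRAITS <- c("emotional_11y", "peer_problems_11y", "conduct_11y",
                "hyperactivity_11y", "prosociality_11y")

# instrument bounds: (min, max); all instruments are integer sum scores
INSTRUMENT_BOUNDS <- list(
  vocab_15m         = c(0, 268),
  vocab_24m         = c(0, 246),
  receptive_15m     = c(0, 12),
  grammar_24m       = c(0, 8),
  receptive_8y      = c(0, 16),
  expressive_8y     = c(0, 10),
  nonword_8y        = c(0, 12),
  pragmatic_9y      = c(86, 162),
  emotional_11y     = c(0, 10),
  peer_problems_11y = c(0, 10),
  conduct_11y       = c(0, 10),
  hyperactivity_11y = c(0, 10),
  prosociality_11y  = c(0, 10)
)

#' Default candidate-gene block layout
#'
#' Six language/reading candidate loci (ATP2C2, CMIP, CNTNAP2, DCDC2, FOXP2,
#' KIAA0319 at their hg38 coordinates) with SNP counts allocated in
#' proportion to genomic span (largest-remainder rounding) so that the total
#' equals \code{total_snps}.
#'
#' @param total_snps Total SNPs across the six blocks (default 1229).
#' @param ld_rho Latent AR(1) autocorrelation within each block, in [0, 1).
#' @return data.frame with columns gene, chr, start, end, n_snps, ld_rho.
#' @export
default_gene_blocks <- function(total_snps = 1229, ld_rho = 0.8) {
  genes <- data.frame(
    gene  = c("ATP2C2", "CMIP", "CNTNAP2", "DCDC2", "FOXP2", "KIAA0319"),
    chr   = c(16L, 16L, 7L, 6L, 7L, 6L),
    start = c(84368615, 81445241, 146116876, 24174729, 114426511, 24541241),
    end   = c(84463732, 81709799, 148415616, 24357750, 114693772, 24645764),
    stringsAsFactors = FALSE
  )
  span <- genes$end - genes$start
  raw <- total_snps * span / sum(span)
  n <- floor(raw)
  rem <- total_snps - sum(n)
  if (rem > 0) {
    add <- order(raw - n, decreasing = TRUE)[seq_len(rem)]
    n[add] <- n[add] + 1L
  }
  genes$n_snps <- as.integer(n)
  genes$ld_rho <- ld_rho
  genes
}

#' Simulation configuration
#'
#' Study-scale defaults: 5,435 individuals and 1,229 SNPs over six gene
#' blocks, allele frequencies uniform on (0.05, 0.5), 1% missing genotype
#' calls at random.
#'
#' @param n_individuals Cohort size.
#' @param gene_blocks data.frame as produced by [default_gene_blocks()].
#' @param allele_freq_range Length-2 numeric in (0, 0.5]; per-SNP effect
#'   allele frequencies are drawn uniformly from this interval.
#' @param missing_rate Probability that a genotype call is missing (MCAR).
#' @param architectures List of [trait_architecture()] objects.
#' @param seed Master seed; all child streams derive from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 5435,
                       gene_blocks = default_gene_blocks(),
                       allele_freq_range = c(0.05, 0.5),
                       missing_rate = 0.01,
                       architectures = NULL,
                       seed = 1L) {
  if (!is.numeric(n_individuals) || n_individuals < 1)
    stop_config("n_individuals must be a positive count, got %s",
                format(n_individuals))
  if (any(gene_blocks$n_snps < 1))
    stop_config("every gene block needs n_snps >= 1")
  if (any(gene_blocks$ld_rho < 0 | gene_blocks$ld_rho >= 1))
    stop_config("ld_rho must lie in [0, 1)")
  f <- sort(allele_freq_range)
  if (f[1] <= 0 || f[2] > 0.5)
    stop_config("allele frequencies must lie in (0, 0.5]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop_config("missing_rate must lie in [0, 1)")
  if (is.null(architectures))
    architectures <- default_architectures(sum(gene_blocks$n_snps),
                                           seed = derive_seed(seed, "arch"))
  structure(list(n_individuals = as.integer(n_individuals),
                 gene_blocks = gene_blocks,
                 allele_freq_range = f,
                 missing_rate = missing_rate,
                 architectures = architectures,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Trait architecture: the simulation truth for one trait
#'
#' @param name Trait name.
#' @param causal Integer indices of causal SNPs (columns of the dosage
#'   matrix).
#' @param beta Per-causal-SNP effect sizes on the latent scale.
#' @param h2 Proportion of latent-trait variance explained by the additive
#'   genetic component, in [0, 1).
#' @param instrument Length-2 numeric bounds (min, max); scores are rounded
#'   to integers when `round = TRUE`.
#' @param round Should instrument scores be rounded to integers?
#' @param shared_with Optional list(trait =, indices =) recording that
#'   `indices` (a subset of `causal`) reuse another trait's effect sizes.
#' @return An object of class `trait_architecture`.
#' @export
trait_architecture <- function(name, causal, beta, h2,
                               instrument = c(0, 10), round = TRUE,
                               shared_with = NULL) {
  causal <- as.integer(causal)
  if (length(beta) != length(causal))
    stop_config("beta must align with causal indices for trait %s", name)
  if (anyDuplicated(causal))
    stop_config("duplicate causal indices for trait %s", name)
  if (!is.numeric(h2) || h2 < 0 || h2 >= 1)
    stop_config("h2 must lie in [0, 1), got %s for %s", format(h2), name)
  if (!is.null(shared_with) && !all(shared_with$indices %in% causal))
    stop_config("shared indices must be a subset of causal indices (%s)", name)
  structure(list(name = name, causal = causal, beta = as.numeric(beta),
                 h2 = h2, instrument = as.numeric(instrument[1:2]),
                 round = isTRUE(round), shared_with = shared_with),
            class = "trait_architecture")
}

#' Default weak pleiotropic architecture
#'
#' Expressive language at 8 years carries 65 causal SNPs whose additive
#' component explains 1% of latent variance; peer problems at 11 years
#' carries 65 causal SNPs of which 27 are shared with expressive language
#' (same effect sizes, so the two genetic components are positively
#' correlated). The remaining language traits get small own architectures
#' (40 causal SNPs, h2 = 0.005), the remaining problem subscales weaker
#' ones (h2 = 0.002), and prosociality no genetic component at all.
#'
#' @param n_snps Total SNP count in the genotype panel.
#' @param seed Seed for drawing causal indices and effect sizes.
#' @return Named list of [trait_architecture()] objects (13 traits).
#' @export
default_architectures <- function(n_snps = 1229, seed = 42L) {
  with_seed(seed, {
    draw <- function(k) sort(sample.int(n_snps, k))
    expr_causal <- draw(65)
    expr_beta <- stats::rnorm(65)
    shared_idx <- sort(sample(expr_causal, 27))
    own_pool <- setdiff(seq_len(n_snps), expr_causal)
    peer_causal <- sort(c(shared_idx, sample(own_pool, 38)))
    peer_beta <- stats::rnorm(65)
    keep <- match(shared_idx, peer_causal)
    peer_beta[keep] <- expr_beta[match(shared_idx, expr_causal)]

    arch <- list()
    for (tr in LANGUAGE_TRAITS) {
      if (tr == "expressive_8y") {
        arch[[tr]] <- trait_architecture(tr, expr_causal, expr_beta, 0.01,
                                         INSTRUMENT_BOUNDS[[tr]])
      } else {
        arch[[tr]] <- trait_architecture(tr, draw(40), stats::rnorm(40), 0.005,
                                         INSTRUMENT_BOUNDS[[tr]])
      }
    }
    for (tr in SDQ_TRAITS) {
      if (tr == "peer_problems_11y") {
        arch[[tr]] <- trait_architecture(
          tr, peer_causal, peer_beta, 0.01, INSTRUMENT_BOUNDS[[tr]],
          shared_with = list(trait = "expressive_8y", indices = shared_idx))
      } else if (tr == "prosociality_11y") {
        arch[[tr]] <- trait_architecture(tr, integer(0), numeric(0), 0,
                                         INSTRUMENT_BOUNDS[[tr]])
      } else {
        arch[[tr]] <- trait_architecture(tr, draw(40), stats::rnorm(40), 0.002,
                                         INSTRUMENT_BOUNDS[[tr]])
      }
    }
    arch
  })
}

# latent n x m matrix whose columns follow a stationary AR(1) with
# autocorrelation rho across columns (rows independent)
ar1_latent <- function(n, m, rho) {
  z <- matrix(stats::rnorm(n * m), n, m)
  if (rho > 0 && m > 1) {
    s <- sqrt(1 - rho^2)
    for (j in 2:m) z[, j] <- rho * z[, j - 1] + s * z[, j]
  }
  z
}

#' Simulate genotypes with block-diagonal LD
#'
#' Each gene block uses a latent-Gaussian threshold model: two independent
#' haplotype indicator sets per individual, each thresholded from a latent
#' AR(1) Gaussian so adjacent SNPs within a block are in LD while blocks are
#' mutually independent. Dosages count the effect allele (0/1/2), with
#' missing calls introduced completely at random.
#'
#' @param config A [sim_config()] object.
#' @return A `genotype_dataset`: list(dosage, variants, samples). `dosage`
#'   is an n x m integer matrix (NA = missing); `variants` has columns snp,
#'   chr, bp, a1, a2, gene, freq; `samples` has columns fid, iid, sex.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  blocks <- config$gene_blocks
  with_seed(derive_seed(config$seed, "genotypes"), {
    dos_list <- vector("list", nrow(blocks))
    var_list <- vector("list", nrow(blocks))
    for (b in seq_len(nrow(blocks))) {
      m <- blocks$n_snps[b]
      f <- stats::runif(m, config$allele_freq_range[1],
                        config$allele_freq_range[2])
      thr <- stats::qnorm(f)
      h1 <- sweep(ar1_latent(n, m, blocks$ld_rho[b]), 2, thr, `<`)
      h2 <- sweep(ar1_latent(n, m, blocks$ld_rho[b]), 2, thr, `<`)
      g <- matrix(as.integer(h1) + as.integer(h2), n, m)
      dos_list[[b]] <- g
      bp <- round(seq(blocks$start[b], blocks$end[b], length.out = m))
      var_list[[b]] <- data.frame(
        snp = sprintf("snp_%s_%04d", blocks$gene[b], seq_len(m)),
        chr = blocks$chr[b], bp = as.integer(bp),
        a1 = "A", a2 = "G", gene = blocks$gene[b], freq = f,
        stringsAsFactors = FALSE)
    }
    dosage <- do.call(cbind, dos_list)
    variants <- do.call(rbind, var_list)
    if (config$missing_rate > 0) {
      miss <- stats::runif(length(dosage)) < config$missing_rate
      dosage[miss] <- NA_integer_
    }
    colnames(dosage) <- variants$snp
    samples <- data.frame(
      fid = sprintf("F%05d", seq_len(n)),
      iid = sprintf("I%05d", seq_len(n)),
      sex = sample(1:2, n, replace = TRUE),
      stringsAsFactors = FALSE)
    rownames(dosage) <- samples$iid
    genotype_dataset(dosage, variants, samples)
  })
}

#' Construct a genotype dataset container
#'
#' @param dosage n x m integer matrix of effect-allele counts (NA missing).
#' @param variants data.frame with at least snp, chr, bp, a1, a2 (gene
#'   optional).
#' @param samples data.frame with at least fid, iid.
#' @return list of class `genotype_dataset`.
#' @export
genotype_dataset <- function(dosage, variants, samples) {
  if (nrow(dosage) != nrow(samples) || ncol(dosage) != nrow(variants))
    stop_config("dosage dimensions (%d x %d) do not match metadata (%d x %d)",
                nrow(dosage), ncol(dosage), nrow(samples), nrow(variants))
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% 0:2))
    stop_config("dosage values must be 0, 1, 2 or NA")
  if (anyDuplicated(variants$snp))
    stop_config("variant identifiers must be unique")
  dimnames(dosage) <- list(samples$iid, variants$snp)
  structure(list(dosage = dosage, variants = variants, samples = samples),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d individuals x %d SNPs (%s)\n",
              nrow(x$dosage), ncol(x$dosage),
              paste(unique(x$variants$gene %||% "-"), collapse = ", ")))
  invisible(x)
}

#' Simulate one trait from an additive architecture
#'
#' The latent trait is `sqrt(h2) * scale(g) + sqrt(1 - h2) * e`, where
#' `g = sum_j beta_j * standardized dosage_j` over the causal SNPs (missing
#' dosages mean-imputed) and `e` is standard normal noise, so the genetic
#' component explains h2 of latent variance. The latent score is then
#' standardized and mapped affinely onto the instrument (midpoint +
#' z * span/6), rounded when the instrument is integer, and clipped to its
#' bounds.
#'
#' @param genotypes A `genotype_dataset`.
#' @param architecture A [trait_architecture()].
#' @param seed Seed for the environmental noise.
#' @return list of class `trait_sim`: values (bounded instrument scores),
#'   latent (pre-instrument scale), genetic (the additive term actually
#'   added), genetic_raw (unscaled weighted sum of standardized dosages).
#' @export
simulate_phenotypes <- function(genotypes, architecture, seed = 1L) {
  stopifnot(inherits(genotypes, "genotype_dataset"),
            inherits(architecture, "trait_architecture"))
  n <- nrow(genotypes$dosage)
  a <- architecture
  if (length(a$causal) && max(a$causal) > ncol(genotypes$dosage))
    stop_config("causal index %d outside panel of %d SNPs",
                max(a$causal), ncol(genotypes$dosage))
  g_raw <- rep(0, n)
  if (length(a$causal)) {
    G <- genotypes$dosage[, a$causal, drop = FALSE]
    mu <- colMeans(G, na.rm = TRUE)
    for (j in seq_along(a$causal)) {
      col <- G[, j]
      col[is.na(col)] <- mu[j]
      s <- stats::sd(col)
      if (s > 0) g_raw <- g_raw + a$beta[j] * (col - mu[j]) / s
    }
  }
  with_seed(seed, {
    e <- stats::rnorm(n)
    if (a$h2 > 0 && stats::sd(g_raw) > 0) {
      gen <- sqrt(a$h2) * as.vector(scale(g_raw))
      latent <- gen + sqrt(1 - a$h2) * e
    } else {
      gen <- rep(0, n)
      latent <- e
    }
    z <- as.vector(scale(latent))
    mid <- mean(a$instrument)
    span <- diff(a$instrument)
    raw <- mid + z * span / 6
    if (a$round) raw <- round(raw)
    vals <- pmin(pmax(raw, a$instrument[1]), a$instrument[2])
    structure(list(values = vals, latent = latent, genetic = gen,
                   genetic_raw = g_raw, architecture = a),
              class = "trait_sim")
  })
}

#' Derive DLD caseness from the four deficit criteria
#'
#' A child is classed as affected when at least two of four criteria hold:
#' pragmatic language, nonword repetition, or receptive language more than
#' 1 SD below the standardized sample mean, or a positive
#' speech/language-therapy report. Children flagged for an ASD-like or
#' hearing-like condition are excluded from both groups; children with any
#' criterion input missing are reported as excluded for missingness.
#'
#' @param pragmatic,nonword,receptive Numeric instrument scores.
#' @param therapy Logical/0-1 therapy indicator.
#' @param asd,hearing Logical exclusion flags (default all FALSE).
#' @param z_cutoff Severity cutoff on the z scale (default -1; a criterion
#'   holds when the standardized score falls strictly below it).
#' @param criteria Which of the four criteria to apply (subset of
#'   "pragmatic", "nonword", "receptive", "therapy"); with none enabled no
#'   child is affected.
#' @return factor with levels affected, unaffected, excluded,
#'   excluded_missing.
#' @export
derive_dld_status <- function(pragmatic, nonword, receptive, therapy,
                              asd = FALSE, hearing = FALSE, z_cutoff = -1,
                              criteria = c("pragmatic", "nonword",
                                           "receptive", "therapy")) {
  n <- length(pragmatic)
  stopifnot(length(nonword) == n, length(receptive) == n,
            length(therapy) == n)
  if (length(criteria))
    criteria <- match.arg(criteria, several.ok = TRUE)
  asd <- rep_len(as.logical(asd), n)
  hearing <- rep_len(as.logical(hearing), n)
  zs <- function(x) (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
  crit <- cbind(pragmatic = zs(pragmatic) < z_cutoff,
                nonword = zs(nonword) < z_cutoff,
                receptive = zs(receptive) < z_cutoff,
                therapy = as.logical(therapy))
  crit <- crit[, criteria, drop = FALSE]
  n_crit <- rowSums(crit)                       # NA if any criterion missing
  status <- ifelse(is.na(n_crit), "excluded_missing",
                   ifelse(n_crit >= 2, "affected", "unaffected"))
  status[asd | hearing] <- "excluded"
  factor(status, levels = c("affected", "unaffected", "excluded",
                            "excluded_missing"))
}

#' Randomly split a cohort into discovery and replication halves
#'
#' @param n Cohort size (>= 2).
#' @param seed Seed for the permutation.
#' @return list(discovery =, replication =) of disjoint, exhaustive sorted
#'   index vectors of sizes ceiling(n/2) and floor(n/2).
#' @export
split_cohort <- function(n, seed = 1L) {
  if (!is.numeric(n) || n < 2) stop_config("need n >= 2 to split, got %s",
                                           format(n))
  n <- as.integer(n)
  with_seed(seed, {
    perm <- sample.int(n)
    k <- ceiling(n / 2)
    list(discovery = sort(perm[seq_len(k)]),
         replication = sort(perm[(k + 1):n]))
  })
}

#' Simulate a full genotype-phenotype cohort
#'
#' Genotypes, all thirteen instruments, therapy/ASD-like/hearing-like flags,
#' and derived DLD caseness, plus the generating truth. The therapy flag is
#' a noisy logistic indicator of low latent language (mean of the three
#' criterion traits' latents); ASD-like and hearing-like flags are rare
#' independent Bernoulli draws (1.2% and 2%).
#'
#' @param config A [sim_config()].
#' @return list of class `cohort_tables`: genotypes, phenotypes (data.frame
#'   iid + 13 trait columns), caseness, flags, truth.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  genotypes <- simulate_genotypes(config)
  n <- config$n_individuals
  sims <- list()
  for (tr in names(config$architectures)) {
    sims[[tr]] <- simulate_phenotypes(genotypes, config$architectures[[tr]],
                                      seed = derive_seed(config$seed,
                                                         paste0("trait_", tr)))
  }
  phen <- data.frame(iid = genotypes$samples$iid, stringsAsFactors = FALSE)
  for (tr in names(sims)) phen[[tr]] <- sims[[tr]]$values

  with_seed(derive_seed(config$seed, "flags"), {
    lang_z <- rowMeans(scale(cbind(sims$pragmatic_9y$latent,
                                   sims$nonword_8y$latent,
                                   sims$receptive_8y$latent)))
    therapy <- stats::rbinom(n, 1, stats::plogis(-3 - 1.5 * lang_z)) == 1
    asd <- stats::runif(n) < 0.012
    hearing <- stats::runif(n) < 0.02
  })
  caseness <- derive_dld_status(phen$pragmatic_9y, phen$nonword_8y,
                                phen$receptive_8y, therapy, asd, hearing)
  flags <- data.frame(iid = phen$iid, therapy = therapy, asd = asd,
                      hearing = hearing, stringsAsFactors = FALSE)
  truth <- list(architectures = config$architectures,
                genetic = vapply(sims, function(s) s$genetic_raw, numeric(n)),
                seed = config$seed)
  structure(list(genotypes = genotypes, phenotypes = phen,
                 caseness = caseness, flags = flags, truth = truth,
                 config = config),
            class = "cohort_tables")
}

#' Write a simulated cohort to disk
#'
#' PLINK BED/BIM/FAM for the genotypes, tab-separated phenotype and flag
#' tables keyed by `iid`, and the truth record as JSON.
#'
#' @param cohort A `cohort_tables` object.
#' @param dir Output directory (created if absent).
#' @param prefix File name stem.
#' @return Invisibly, the named vector of paths written.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  stopifnot(inherits(cohort, "cohort_tables"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, prefix)
  write_plink(cohort$genotypes, stem)
  phen <- cohort$phenotypes
  phen$dld_status <- as.character(cohort$caseness)
  phen_path <- paste0(stem, "_phenotypes.tsv")
  utils::write.table(phen, phen_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  flag_path <- paste0(stem, "_flags.tsv")
  utils::write.table(cohort$flags, flag_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_path <- paste0(stem, "_truth.json")
  truth <- lapply(cohort$truth$architectures, function(a)
    list(name = a$name, causal = a$causal, beta = a$beta, h2 = a$h2,
         instrument = a$instrument,
         shared_with = if (is.null(a$shared_with)) NULL else
           list(trait = a$shared_with$trait,
                indices = a$shared_with$indices)))
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(bed = paste0(stem, ".bed"), bim = paste0(stem, ".bim"),
              fam = paste0(stem, ".fam"), phenotypes = phen_path,
              flags = flag_path, truth = truth_path))
}
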