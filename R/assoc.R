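# Per-SNP additive linear association.

#' Single-SNP linear association
#'
#' Ordinary least squares of phenotype on effect-allele dosage with an
#' intercept, complete cases only; the two-sided p-value comes from the t
#' distribution with n - 2 degrees of freedom. A monomorphic SNP (or
#' zero-variance phenotype) yields a degenerate row with undefined beta and
#' p = 1.
#'
#' @param dosage Numeric dosage vector (0/1/2, NA missing).
#' @param phenotype Numeric phenotype vector.
#' @return One-row data.frame: beta, se, t, p, n, degenerate.
#' @export
assoc_linear <- function(dosage, phenotype) {
  ok <- !is.na(dosage) & !is.na(phenotype)
  x <- as.numeric(dosage[ok])
  y <- as.numeric(phenotype[ok])
  n <- length(x)
  if (n < 3) stop_config("need at least 3 complete pairs, got %d", n)
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  if (sxx <= 0 || syy <= 0) {
    return(data.frame(beta = NA_real_, se = NA_real_, t = NA_real_, p = 1,
                      n = n, degenerate = TRUE))
  }
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  beta <- sxy / sxx
  rss <- syy - beta * sxy
  se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
  tval <- if (se > 0) beta / se else sign(beta) * Inf
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  data.frame(beta = beta, se = se, t = tval, p = max(p, .Machine$double.xmin),
             n = n, degenerate = FALSE)
}

#' Association scan over all SNPs and traits
#'
#' Vectorized per-trait OLS (complete cases per SNP, matching PLINK's
#' --linear convention). One row per (SNP, trait).
#'
#' @param dataset A `genotype_dataset`.
#' @param phenotypes data.frame with an `iid` column (aligned to the
#'   dataset's samples) and one column per trait.
#' @param traits Character vector of trait columns to scan (default: all
#'   non-iid columns).
#' @return data.frame: snp, chr, bp, a1, gene, trait, beta, se, t, p, n,
#'   degenerate.
#' @export
assoc_scan <- function(dataset, phenotypes, traits = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  traits <- traits %||% setdiff(names(phenotypes), "iid")
  missing_tr <- setdiff(traits, names(phenotypes))
  if (length(missing_tr))
    stop_config("trait(s) absent from phenotype table: %s",
                paste(missing_tr, collapse = ", "))
  if (!is.null(phenotypes$iid)) {
    idx <- match(dataset$samples$iid, phenotypes$iid)
    if (anyNA(idx))
      stop_config("phenotype table lacks %d of the dataset's individuals",
                  sum(is.na(idx)))
    phenotypes <- phenotypes[idx, , drop = FALSE]
  }
  g_all <- dataset$dosage
  v <- dataset$variants
  out <- vector("list", length(traits))
  for (k in seq_along(traits)) {
    y_full <- as.numeric(phenotypes[[traits[k]]])
    ok <- !is.na(y_full)
    g <- g_all[ok, , drop = FALSE]
    y <- y_full[ok]
    M <- !is.na(g)
    g0 <- g
    g0[!M] <- 0
    n_j <- colSums(M)
    sx <- colSums(g0)
    sxx <- colSums(g0^2)
    sxy <- as.vector(crossprod(g0, y))
    sy <- as.vector(crossprod(M, y))
    syy <- as.vector(crossprod(M, y^2))
    sxx_c <- sxx - sx^2 / n_j
    syy_c <- syy - sy^2 / n_j
    sxy_c <- sxy - sx * sy / n_j
    eps <- 1e-12
    degen <- sxx_c <= eps * pmax(sxx, 1) | syy_c <= eps * pmax(syy, 1) |
      n_j < 3
    beta <- ifelse(degen, NA_real_, sxy_c / sxx_c)
    rss <- pmax(syy_c - beta * sxy_c, 0)
    se <- ifelse(degen, NA_real_, sqrt(rss / (n_j - 2) / sxx_c))
    tval <- ifelse(degen | se == 0, NA_real_, beta / se)
    p <- ifelse(degen, 1, 2 * stats::pt(-abs(tval), df = n_j - 2))
    p <- pmax(p, .Machine$double.xmin)
    out[[k]] <- data.frame(
      snp = v$snp, chr = v$chr, bp = v$bp, a1 = v$a1,
      gene = v$gene %||% NA_character_, trait = traits[k],
      beta = beta, se = se, t = tval, p = p, n = n_j, degenerate = degen,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gene-by-trait minimum-p summary
#'
#' Each cell is the minimum association p-value over the gene's SNPs for
#' that trait; margins report the per-gene and per-trait minima with their
#' argmin labels.
#'
#' @param assoc Output of [assoc_scan()] (must carry a `gene` column).
#' @return list: matrix (gene x trait), gene_min (data.frame gene, min_p,
#'   trait), trait_min (data.frame trait, min_p, gene), overall (list).
#' @export
gene_min_p <- function(assoc) {
  if (is.null(assoc$gene) || anyNA(assoc$gene))
    stop_config("every SNP must carry a gene label")
  genes <- unique(assoc$gene)
  traits <- unique(assoc$trait)
  mat <- matrix(NA_real_, length(genes), length(traits),
                dimnames = list(genes, traits))
  for (g in genes) for (tr in traits) {
    p <- assoc$p[assoc$gene == g & assoc$trait == tr]
    if (length(p)) mat[g, tr] <- min(p)
  }
  gene_min <- data.frame(
    gene = genes,
    min_p = apply(mat, 1, min, na.rm = TRUE),
    trait = traits[apply(mat, 1, which.min)],
    stringsAsFactors = FALSE)
  trait_min <- data.frame(
    trait = traits,
    min_p = apply(mat, 2, min, na.rm = TRUE),
    gene = genes[apply(mat, 2, which.min)],
    stringsAsFactors = FALSE)
  cell <- arrayInd(which.min(mat), dim(mat))
  list(matrix = mat, gene_min = gene_min, trait_min = trait_min,
       overall = list(min_p = min(mat, na.rm = TRUE),
                      gene = genes[cell[1]], trait = traits[cell[2]]))
}
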