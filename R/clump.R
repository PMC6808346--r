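# Greedy LD clumping: thin SNPs by linkage disequilibrium and p-value so
# each retained index SNP represents its correlated neighbourhood.

#' Composite (genotype) r-squared between two dosage columns
#'
#' Squared Pearson correlation of dosages over complete pairs — the
#' unphased surrogate for haplotype r2.
#'
#' @param a,b Numeric dosage vectors.
#' @return r2 in [0, 1]; NA when either column is monomorphic over the
#'   complete pairs (treated as 0 by [clump()]).
#' @export
dosage_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(NA_real_)
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) return(NA_real_)
  stats::cor(a[ok], b[ok])^2
}

#' Pairwise-complete dosage r2 matrices, one per chromosome
#'
#' Computes the full within-chromosome matrix of squared dosage
#' correlations (complete pairs per SNP pair, the same quantity as
#' [dosage_r2()]) through four cross-products, so [clump()] can be run for
#' many traits against one precomputed LD set. Monomorphic pairs yield 0.
#'
#' @param dataset A `genotype_dataset`.
#' @return Named list (one element per chromosome) of symmetric r2
#'   matrices with SNP identifiers as dimnames.
#' @export
ld_r2_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  out <- list()
  for (ch in unique(dataset$variants$chr)) {
    cols <- which(dataset$variants$chr == ch)
    g <- dataset$dosage[, cols, drop = FALSE]
    M <- !is.na(g); storage.mode(M) <- "double"
    X0 <- g; X0[is.na(X0)] <- 0; storage.mode(X0) <- "double"
    A <- crossprod(M)              # complete-pair counts
    B <- crossprod(X0)             # sum x_i x_j over complete pairs
    C <- crossprod(X0, M)          # C[i,j] = sum of x_i over pairs (i,j)
    D <- crossprod(X0^2, M)        # D[i,j] = sum of x_i^2 over pairs (i,j)
    num <- A * B - C * t(C)
    den <- (A * D - C^2) * (A * t(D) - t(C)^2)
    r2 <- num^2 / den
    r2[!is.finite(r2)] <- 0
    diag(r2) <- 1
    dimnames(r2) <- list(dataset$variants$snp[cols],
                         dataset$variants$snp[cols])
    out[[as.character(ch)]] <- r2
  }
  out
}

#' Greedy p-value-ordered LD clumping
#'
#' SNPs with p <= `p_ceiling` are considered in order of ascending p (ties
#' broken by position, then identifier). Each round takes the best
#' remaining SNP as an index and assigns to it every unassigned SNP on the
#' same chromosome within `window_kb` whose dosage r2 with the index
#' exceeds `r2_threshold`. Defaults follow the PRSice v1.25 conventions.
#'
#' @param assoc One trait's association rows (columns snp, chr, bp, p).
#' @param dataset The `genotype_dataset` supplying LD (normally the
#'   discovery cohort, i.e. the cohort that produced the p-values).
#' @param r2_threshold LD threshold above which a SNP joins a clump.
#' @param window_kb Window half-width in kilobases.
#' @param p_ceiling Ignore SNPs with p above this ceiling.
#' @param ld Optional precomputed [ld_r2_matrix()] result; when supplied,
#'   r2 values are looked up instead of recomputed (useful when clumping
#'   several traits against the same cohort).
#' @return list of class `clump_result`: `index` (data.frame snp, chr, bp,
#'   p, n_members, members, member_r2), `retained` (index SNP ids in
#'   p order), `params`.
#' @export
clump <- function(assoc, dataset, r2_threshold = 0.1, window_kb = 250,
                  p_ceiling = 1, ld = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (length(unique(assoc$trait %||% "x")) > 1)
    stop_config("clump() expects association rows for a single trait")
  a <- assoc[!is.na(assoc$p) & assoc$p <= p_ceiling, , drop = FALSE]
  params <- list(r2_threshold = r2_threshold, window_kb = window_kb,
                 p_ceiling = p_ceiling)
  if (nrow(a) == 0)
    return(structure(list(index = data.frame(), retained = character(0),
                          params = params), class = "clump_result"))
  a <- a[order(a$p, a$bp, a$snp), , drop = FALSE]
  col <- match(a$snp, colnames(dataset$dosage))
  if (anyNA(col))
    stop_config("association rows name SNPs absent from the dataset: %s",
                paste(utils::head(a$snp[is.na(col)], 5), collapse = ", "))
  g <- dataset$dosage[, col, drop = FALSE]
  nsnp <- nrow(a)
  assigned <- rep(FALSE, nsnp)
  rows <- list()
  for (i in seq_len(nsnp)) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    cand <- which(!assigned & a$chr == a$chr[i] &
                    abs(a$bp - a$bp[i]) <= window_kb * 1000)
    members <- character(0)
    member_r2 <- numeric(0)
    if (length(cand)) {
      if (!is.null(ld)) {
        r2 <- ld[[as.character(a$chr[i])]][a$snp[i], a$snp[cand]]
      } else {
        r2 <- suppressWarnings(
          as.vector(stats::cor(g[, i], g[, cand, drop = FALSE],
                               use = "pairwise.complete.obs"))^2)
      }
      r2[is.na(r2)] <- 0
      take <- r2 > r2_threshold
      if (any(take)) {
        members <- a$snp[cand[take]]
        member_r2 <- r2[take]
        assigned[cand[take]] <- TRUE
      }
    }
    rows[[length(rows) + 1]] <- data.frame(
      snp = a$snp[i], chr = a$chr[i], bp = a$bp[i], p = a$p[i],
      n_members = length(members),
      members = paste(members, collapse = ","),
      member_r2 = paste(sprintf("%.6g", member_r2), collapse = ","),
      stringsAsFactors = FALSE)
  }
  index <- do.call(rbind, rows)
  structure(list(index = index, retained = index$snp, params = params),
            class = "clump_result")
}

#' @export
print.clump_result <- function(x, ...) {
  cat(sprintf("clump_result: %d index SNPs (r2 > %g within %g kb, p <= %g)\n",
              length(x$retained), x$params$r2_threshold, x$params$window_kb,
              x$params$p_ceiling))
  invisible(x)
}
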