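# Test-family assembly, multiple-testing adjustment, SNP-set overlap, and
# the phenotype correlation matrix.

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Step-up adjustment: sort ascending, adj(i) = min over j >= i of
#' (m/j) p(j), capped at 1, returned in input order. Delegates to
#' \code{stats::p.adjust(method = "BH")} after validating the input.
#'
#' @param p Numeric vector of nominal p-values in (0, 1].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || length(p) == 0)
    stop_config("p must be a non-empty numeric vector")
  if (anyNA(p) || any(p <= 0 | p > 1))
    stop_config("all p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' SNP-set overlap between two best-fit models
#'
#' @param set_a,set_b Character vectors of SNP identifiers (set A is the
#'   reference whose size forms the denominator).
#' @param label_a,label_b Optional labels for reporting.
#' @return list of class `overlap_report`: n_a, n_b, n_shared, shared
#'   (ids), pct_of_a (exact), pct_of_a_rounded (nearest whole percent),
#'   subset (is B a subset of A), undefined (empty A flag).
#' @export
subset_overlap <- function(set_a, set_b, label_a = "A", label_b = "B") {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  shared <- intersect(set_a, set_b)
  undefined <- length(set_a) == 0
  pct <- if (undefined) NA_real_ else 100 * length(shared) / length(set_a)
  structure(list(label_a = label_a, label_b = label_b,
                 n_a = length(set_a), n_b = length(set_b),
                 n_shared = length(shared), shared = shared,
                 pct_of_a = pct,
                 pct_of_a_rounded = if (undefined) NA_real_ else round(pct),
                 subset = all(set_b %in% set_a),
                 undefined = undefined),
            class = "overlap_report")
}

#' Pairwise phenotype correlation matrix
#'
#' Pearson correlations with pairwise deletion; per-cell two-sided p-values
#' from \code{stats::cor.test} and significance tiers at .05 / .01 / .001.
#'
#' @param phenotypes data.frame of trait columns (an `iid` column, if
#'   present, is dropped).
#' @return list of class `phenotype_correlations`: r, p, n matrices, and
#'   `stars` (character matrix: "", "*", "**", "***"; "c" marks undefined
#'   cells from constant columns).
#' @export
phenotype_correlations <- function(phenotypes) {
  df <- phenotypes[, setdiff(names(phenotypes), "iid"), drop = FALSE]
  df <- as.data.frame(lapply(df, as.numeric))
  k <- ncol(df)
  r <- diag(1, k); p <- matrix(NA_real_, k, k); n <- matrix(NA_integer_, k, k)
  dimnames(r) <- dimnames(p) <- dimnames(n) <- list(names(df), names(df))
  stars <- matrix("", k, k, dimnames = dimnames(r))
  for (i in seq_len(k)) for (j in seq_len(i)) {
    ok <- !is.na(df[[i]]) & !is.na(df[[j]])
    n[i, j] <- n[j, i] <- sum(ok)
    if (i == j) next
    if (sum(ok) < 3 || stats::sd(df[[i]][ok]) == 0 ||
        stats::sd(df[[j]][ok]) == 0) {
      r[i, j] <- r[j, i] <- NA_real_
      stars[i, j] <- stars[j, i] <- "c"
      next
    }
    ct <- stats::cor.test(df[[i]][ok], df[[j]][ok])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
    s <- if (ct$p.value < .001) "***" else if (ct$p.value < .01) "**"
         else if (ct$p.value < .05) "*" else ""
    stars[i, j] <- stars[j, i] <- s
  }
  structure(list(r = r, p = p, n = n, stars = stars),
            class = "phenotype_correlations")
}

#' Format a correlation matrix as a lower-triangular table
#'
#' @param x A `phenotype_correlations` object.
#' @param digits Decimals for r.
#' @return data.frame in lower-triangular layout with significance stars.
#' @export
format_correlations <- function(x, digits = 2) {
  stopifnot(inherits(x, "phenotype_correlations"))
  k <- ncol(x$r)
  out <- matrix("", k, k, dimnames = dimnames(x$r))
  for (i in seq_len(k)) for (j in seq_len(i)) {
    out[i, j] <- if (i == j) "1" else if (is.na(x$r[i, j])) "-" else
      paste0(formatC(x$r[i, j], digits = digits, format = "f"),
             x$stars[i, j])
  }
  data.frame(measure = rownames(out), out, check.names = FALSE,
             row.names = NULL)
}

#' Assemble the two replication test families and adjust within each
#'
#' The consistency family holds one base-equals-target fit per base trait;
#' the cross-trait family holds the fits of one base trait's weights
#' against alternative targets. Benjamini-Hochberg adjustment is applied
#' within each family separately, and rows at adjusted p <= fdr are
#' flagged.
#'
#' @param consistency data.frame of fits with columns base, target,
#'   threshold, n_snps, r2, p (one row per base trait).
#' @param cross_trait data.frame of the same shape for the cross-trait
#'   fits.
#' @param fdr False-discovery-rate level for flagging (default .05).
#' @return list of class `test_families` with elements `consistency` and
#'   `cross_trait`, each gaining `p_adjusted` and `significant` columns.
#' @export
run_test_families <- function(consistency, cross_trait, fdr = 0.05) {
  check <- function(df, fam) {
    need <- c("base", "target", "p")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop_config("%s family lacks column(s): %s", fam,
                  paste(miss, collapse = ", "))
    if (nrow(df) == 0 || anyNA(df$p))
      stop_config("%s family has missing fits: %s", fam,
                  paste(df$target[is.na(df$p)], collapse = ", "))
    df$p_adjusted <- bh_adjust(df$p)
    df$significant <- df$p_adjusted <= fdr
    df
  }
  structure(list(consistency = check(consistency, "consistency"),
                 cross_trait = check(cross_trait, "cross_trait"),
                 fdr = fdr),
            class = "test_families")
}
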