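# Weighted polygenic profile scores over a p-value threshold grid.

#' The p-value threshold grid
#'
#' Thresholds at increments of .01 between 0 and .5; 0 itself is excluded
#' (an empty score is undefined) and .50 included.
#'
#' @param from,to,step Grid limits and increment.
#' @return Strictly increasing numeric vector (default {.01, .02, ..., .50},
#'   50 values).
#' @export
threshold_grid <- function(from = 0.01, to = 0.5, step = 0.01) {
  if (step <= 0 || to < from) stop_config("invalid threshold grid")
  round(seq(from, to, by = step), 10)
}

# Reconcile external weights to the scored dataset: match by SNP id and
# flip the sign of beta when the weight's effect allele is the dataset's
# other allele. Irreconcilable alleles are an error.
reconcile_weights <- function(weights, variants) {
  idx <- match(weights$snp, variants$snp)
  if (anyNA(idx))
    stop_config("weights name SNPs absent from the dataset: %s",
                paste(utils::head(weights$snp[is.na(idx)], 5), collapse = ", "))
  same <- weights$a1 == variants$a1[idx]
  flip <- weights$a1 == variants$a2[idx]
  bad <- !(same | flip)
  if (any(bad))
    stop_config("irreconcilable alleles for SNP(s): %s",
                paste(utils::head(weights$snp[bad], 5), collapse = ", "))
  w <- weights
  w$beta[flip] <- -w$beta[flip]
  w$col <- idx
  w
}

#' Compute a weighted profile score at one threshold
#'
#' score_i = mean over S(T) of beta_j * g_ij, where S(T) is the set of
#' weight SNPs with p <= T, and missing dosages are imputed by twice the
#' effect-allele frequency in the scored cohort (the column mean dosage).
#' Weights whose effect allele is the dataset's other allele have their
#' beta sign flipped before scoring.
#'
#' @param dataset The `genotype_dataset` to score.
#' @param weights data.frame with columns snp, a1, beta, p (normally the
#'   discovery association table restricted to clumped index SNPs).
#' @param threshold p-value ceiling T.
#' @return list of class `score_profile`: threshold, snps (S(T)), values
#'   (per individual, named by iid), n_snps, empty (flag).
#' @export
compute_score <- function(dataset, weights, threshold) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  w <- reconcile_weights(weights, dataset$variants)
  keep <- !is.na(w$p) & w$p <= threshold + 1e-12
  w <- w[keep, , drop = FALSE]
  if (nrow(w) == 0) {
    vals <- rep(NA_real_, nrow(dataset$dosage))
    names(vals) <- dataset$samples$iid
    return(structure(list(threshold = threshold, snps = character(0),
                          values = vals, n_snps = 0L, empty = TRUE),
                     class = "score_profile"))
  }
  g <- dataset$dosage[, w$col, drop = FALSE]
  mu <- colMeans(g, na.rm = TRUE)
  for (j in seq_len(ncol(g))) {
    nas <- is.na(g[, j])
    if (any(nas)) g[nas, j] <- mu[j]
  }
  vals <- as.vector(g %*% w$beta) / nrow(w)
  names(vals) <- dataset$samples$iid
  structure(list(threshold = threshold, snps = w$snp, values = vals,
                 n_snps = nrow(w), empty = FALSE),
            class = "score_profile")
}

# shared closed-form simple regression with intercept
simple_ols <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop_config("need at least 3 complete (score, trait) pairs")
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  if (sxx <= 0 || syy <= 0)
    return(list(beta = NA_real_, se = NA_real_, t = NA_real_, p = 1,
                r2 = 0, n = n, degenerate = TRUE))
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  beta <- sxy / sxx
  r2 <- sxy^2 / (sxx * syy)
  rss <- syy - beta * sxy
  se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
  tval <- if (se > 0) beta / se else sign(beta) * Inf
  p <- max(2 * stats::pt(-abs(tval), df = n - 2), .Machine$double.xmin)
  list(beta = beta, se = se, t = tval, p = p, r2 = min(r2, 1), n = n,
       degenerate = FALSE)
}

#' Fit a score -> phenotype regression
#'
#' OLS of trait on score with intercept (so R2 is the squared Pearson
#' correlation). For a binary target, `link = "logistic"` fits a logistic
#' regression instead and reports McFadden's pseudo-R2.
#'
#' @param score A `score_profile` (or bare numeric vector).
#' @param trait Numeric target vector aligned to the score.
#' @param threshold,n_snps Reporting fields when `score` is a bare vector.
#' @param link "linear" (default) or "logistic".
#' @return One-row data.frame of class `fit_result`: threshold, n_snps, r2,
#'   beta, p, n, degenerate.
#' @export
fit_score_model <- function(score, trait, threshold = NA_real_,
                            n_snps = NA_integer_,
                            link = c("linear", "logistic")) {
  link <- match.arg(link)
  if (inherits(score, "score_profile")) {
    threshold <- score$threshold
    n_snps <- score$n_snps
    score <- score$values
  }
  if (link == "logistic") {
    ok <- !is.na(score) & !is.na(trait)
    fit <- stats::glm(trait[ok] ~ score[ok], family = stats::binomial())
    null_dev <- fit$null.deviance
    r2 <- if (null_dev > 0) 1 - fit$deviance / null_dev else 0
    cf <- summary(fit)$coefficients
    res <- list(beta = cf[2, 1], p = cf[2, 4], r2 = r2, n = sum(ok),
                degenerate = FALSE)
  } else {
    res <- simple_ols(score, trait)
  }
  out <- data.frame(threshold = threshold, n_snps = n_snps, r2 = res$r2,
                    beta = res$beta, p = res$p, n = res$n,
                    degenerate = res$degenerate)
  class(out) <- c("fit_result", class(out))
  out
}

#' Best-fit threshold scan
#'
#' Computes the profile score at every grid threshold (sets S(T) are nested
#' as T grows, so scores are accumulated incrementally) and fits the target
#' trait at each; the best fit maximizes R2, ties broken towards the
#' smaller threshold (parsimony).
#'
#' @param dataset The evaluation `genotype_dataset`.
#' @param weights Clumped discovery weights (snp, a1, beta, p).
#' @param trait Target vector aligned to the dataset's samples.
#' @param grid Threshold grid (default [threshold_grid()]).
#' @param link Passed to [fit_score_model()].
#' @return list of class `scan_result`: scan (data.frame over the grid),
#'   best (one-row data.frame), best_snps (S(T*) identifiers), snps_in_p_order.
#' @export
best_fit_scan <- function(dataset, weights, trait, grid = threshold_grid(),
                          link = "linear") {
  stopifnot(length(grid) >= 1)
  w <- reconcile_weights(weights, dataset$variants)
  w <- w[!is.na(w$p), , drop = FALSE]
  w <- w[order(w$p, w$snp), , drop = FALSE]
  ks <- vapply(grid, function(T) sum(w$p <= T + 1e-12), integer(1))
  if (all(ks == 0))
    stop_config("every grid threshold yields an empty SNP set")
  kmax <- max(ks)
  g <- dataset$dosage[, w$col[seq_len(kmax)], drop = FALSE]
  mu <- colMeans(g, na.rm = TRUE)
  for (j in seq_len(ncol(g))) {
    nas <- is.na(g[, j])
    if (any(nas)) g[nas, j] <- mu[j]
  }
  contrib <- sweep(g, 2, w$beta[seq_len(kmax)], `*`)
  fits_by_k <- list()
  acc <- rep(0, nrow(g))
  for (k in seq_len(kmax)) {
    acc <- acc + contrib[, k]
    if (k %in% ks)
      fits_by_k[[as.character(k)]] <-
        fit_score_model(acc / k, trait, n_snps = k, link = link)
  }
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    if (ks[i] == 0) {
      rows[[i]] <- data.frame(threshold = grid[i], n_snps = 0L, r2 = NA_real_,
                              beta = NA_real_, p = NA_real_, n = NA_integer_,
                              degenerate = NA)
    } else {
      r <- fits_by_k[[as.character(ks[i])]]
      r$threshold <- grid[i]
      rows[[i]] <- r
    }
  }
  scan <- do.call(rbind, rows)
  rownames(scan) <- NULL
  usable <- which(!is.na(scan$r2))
  best_i <- usable[which.max(scan$r2[usable])]   # first max = smallest T
  best <- scan[best_i, , drop = FALSE]
  structure(list(scan = scan, best = best,
                 best_snps = w$snp[seq_len(scan$n_snps[best_i])],
                 snps_in_p_order = w$snp[seq_len(kmax)]),
            class = "scan_result")
}
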