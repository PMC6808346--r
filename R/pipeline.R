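# Config-driven end-to-end pipeline: simulate or load a cohort, QC, split,
# associate in the discovery half, clump, scan profile scores, fit the
# replication families, adjust, and report.

#' Pipeline configuration
#'
#' Defaults mirror the study design: a simulated cohort of 5,435 children
#' with 1,229 SNPs over six candidate genes; QC at MAF 1% / call rate 95% /
#' HWE 5e-7 / individual missingness 3%; clumping at r2 0.1 within 250 kb;
#' a threshold grid of .01-.50 in steps of .01; eight language base traits;
#' cross-trait prediction of DLD status and the five SDQ subscales from the
#' expressive-language weights.
#'
#' @param mode "simulate" or "load".
#' @param sim A [sim_config()] (simulate mode).
#' @param paths list(bed =, bim =, fam =, phenotypes =) for load mode; the
#'   phenotype TSV needs an `iid` column, the trait columns, and (for the
#'   DLD target) a `dld_status` column.
#' @param qc A [qc_thresholds()].
#' @param clump_params list(r2_threshold =, window_kb =, p_ceiling =).
#' @param grid Threshold grid.
#' @param fit_mode "scan_in_target" (scan thresholds in the replication
#'   cohort, the table-style report) or "fixed_from_discovery" (fix the
#'   threshold maximized in the discovery cohort, then fit it once in
#'   replication).
#' @param base_traits Base traits for the consistency family.
#' @param cross_base Base trait supplying cross-trait weights.
#' @param cross_targets Targets for the cross-trait family.
#' @param dld_link "linear" (linear probability model, default) or
#'   "logistic" for the DLD status target.
#' @param seed Master seed.
#' @param out_dir Optional output directory for the report bundle.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "load"),
                            sim = NULL, paths = NULL,
                            qc = qc_thresholds(),
                            clump_params = list(r2_threshold = 0.1,
                                                window_kb = 250,
                                                p_ceiling = 1),
                            grid = threshold_grid(),
                            fit_mode = c("scan_in_target",
                                         "fixed_from_discovery"),
                            base_traits = LANGUAGE_TRAITS,
                            cross_base = "expressive_8y",
                            cross_targets = c("dld_status", SDQ_TRAITS),
                            dld_link = c("linear", "logistic"),
                            seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  fit_mode <- match.arg(fit_mode)
  dld_link <- match.arg(dld_link)
  if (mode == "simulate") {
    if (is.null(seed)) stop_config("simulate mode requires a seed")
    sim <- sim %||% sim_config(seed = derive_seed(seed, "cohort"))
  } else if (is.null(paths)) {
    stop_config("load mode requires paths = list(bed, bim, fam, phenotypes)")
  }
  if (!cross_base %in% base_traits)
    stop_config("cross_base '%s' must be one of the base traits", cross_base)
  structure(list(mode = mode, sim = sim, paths = paths, qc = qc,
                 clump_params = clump_params, grid = grid,
                 fit_mode = fit_mode, base_traits = base_traits,
                 cross_base = cross_base, cross_targets = cross_targets,
                 dld_link = dld_link, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

stage_log <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

# numeric DLD target: affected = 1, unaffected = 0, excluded = NA
dld_numeric <- function(status) {
  s <- as.character(status)
  ifelse(s == "affected", 1, ifelse(s == "unaffected", 0, NA_real_))
}

#' Run the full discovery-replication polygenic profile pipeline
#'
#' Stages, in order: simulate or load the cohort; QC; random half-split;
#' discovery association scan over the base traits; per-base-trait LD
#' clumping in the discovery cohort; threshold-scanned profile scores and
#' replication fits for the consistency family; cross-trait fits of the
#' `cross_base` weights against the cross targets; Benjamini-Hochberg
#' adjustment within each family; SNP-set overlap between the consistency
#' best fit of `cross_base` and the best cross-trait fit; the phenotype
#' correlation matrix. Fully deterministic given the config seed.
#'
#' @param config A [pipeline_config()].
#' @param verbose Emit per-stage log lines?
#' @return list of class `report_bundle`; see the elements written by
#'   [write_report_bundle()].
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))

  if (config$mode == "simulate") {
    cohort <- simulate_cohort(config$sim)
    genotypes <- cohort$genotypes
    phen <- cohort$phenotypes
    phen$dld_status <- dld_numeric(cohort$caseness)
    stage_log(verbose, "simulate", "cohort of %d individuals x %d SNPs",
              nrow(genotypes$dosage), ncol(genotypes$dosage))
  } else {
    genotypes <- read_plink(bed = config$paths$bed, bim = config$paths$bim,
                            fam = config$paths$fam)
    regions <- config$paths$gene_regions %||%
      (if (!is.null(config$sim)) config$sim$gene_blocks else
        default_gene_blocks())
    if (is.character(regions))
      regions <- utils::read.table(regions, header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE)
    genotypes <- assign_genes(genotypes, regions)
    phen <- utils::read.table(config$paths$phenotypes, header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
    if (!is.numeric(phen$dld_status %||% numeric(0)) &&
        !is.null(phen$dld_status))
      phen$dld_status <- dld_numeric(phen$dld_status)
    cohort <- NULL
    stage_log(verbose, "load", "read %d individuals x %d SNPs",
              nrow(genotypes$dosage), ncol(genotypes$dosage))
  }
  missing_tr <- setdiff(c(config$base_traits,
                          setdiff(config$cross_targets, "dld_status")),
                        names(phen))
  if (length(missing_tr))
    stop_config("unknown trait(s) in config: %s",
                paste(missing_tr, collapse = ", "))

  qc_res <- qc_filter(genotypes, config$qc)
  genotypes <- qc_res$dataset
  phen <- phen[match(genotypes$samples$iid, phen$iid), , drop = FALSE]
  stage_log(verbose, "qc", "%d individuals, %d SNPs retained",
            qc_res$report$n_individuals_out, qc_res$report$n_snps_out)

  n <- nrow(genotypes$dosage)
  halves <- split_cohort(n, seed = derive_seed(config$seed, "split"))
  subset_ds <- function(idx) genotype_dataset(
    genotypes$dosage[idx, , drop = FALSE], genotypes$variants,
    genotypes$samples[idx, , drop = FALSE])
  disc <- subset_ds(halves$discovery)
  repl <- subset_ds(halves$replication)
  phen_disc <- phen[halves$discovery, , drop = FALSE]
  phen_repl <- phen[halves$replication, , drop = FALSE]
  stage_log(verbose, "split", "discovery n = %d, replication n = %d",
            nrow(disc$dosage), nrow(repl$dosage))

  assoc <- assoc_scan(disc, phen_disc, config$base_traits)
  stage_log(verbose, "assoc", "%d tests (%d traits x %d SNPs)",
            nrow(assoc), length(config$base_traits), ncol(disc$dosage))
  min_p <- gene_min_p(assoc)

  ld <- ld_r2_matrix(disc)       # discovery LD, shared across base traits
  clumps <- list()
  scans <- list()
  consistency <- list()
  for (tr in config$base_traits) {
    a_tr <- assoc[assoc$trait == tr, , drop = FALSE]
    cl <- clump(a_tr, disc,
                r2_threshold = config$clump_params$r2_threshold,
                window_kb = config$clump_params$window_kb,
                p_ceiling = config$clump_params$p_ceiling, ld = ld)
    clumps[[tr]] <- cl
    w <- a_tr[a_tr$snp %in% cl$retained, c("snp", "a1", "beta", "p")]
    if (config$fit_mode == "fixed_from_discovery") {
      disc_scan <- best_fit_scan(disc, w, phen_disc[[tr]], config$grid)
      t_star <- disc_scan$best$threshold
      sc <- compute_score(repl, w, t_star)
      fit <- fit_score_model(sc, phen_repl[[tr]])
      scans[[tr]] <- list(scan = disc_scan$scan, best = fit,
                          best_snps = sc$snps,
                          discovery_best = disc_scan$best)
    } else {
      scans[[tr]] <- best_fit_scan(repl, w, phen_repl[[tr]], config$grid)
    }
    b <- scans[[tr]]$best
    consistency[[tr]] <- data.frame(
      base = tr, target = tr, threshold = b$threshold, n_snps = b$n_snps,
      r2 = b$r2, beta = b$beta, p = b$p, stringsAsFactors = FALSE)
  }
  consistency <- do.call(rbind, consistency)
  rownames(consistency) <- NULL
  stage_log(verbose, "consistency", "%d base-trait fits", nrow(consistency))

  cb <- config$cross_base
  w_cross <- assoc[assoc$trait == cb &
                     assoc$snp %in% clumps[[cb]]$retained,
                   c("snp", "a1", "beta", "p")]
  cross_scans <- list()
  cross <- list()
  for (tg in config$cross_targets) {
    y <- if (tg == "dld_status") phen_repl$dld_status else phen_repl[[tg]]
    link <- if (tg == "dld_status" && config$dld_link == "logistic")
      "logistic" else "linear"
    if (config$fit_mode == "fixed_from_discovery") {
      t_star <- scans[[cb]]$discovery_best$threshold
      sc <- compute_score(repl, w_cross, t_star)
      fit <- fit_score_model(sc, y, link = link)
      cross_scans[[tg]] <- list(best = fit, best_snps = sc$snps)
    } else {
      cross_scans[[tg]] <- best_fit_scan(repl, w_cross, y, config$grid,
                                         link = link)
    }
    b <- cross_scans[[tg]]$best
    cross[[tg]] <- data.frame(
      base = cb, target = tg, threshold = b$threshold, n_snps = b$n_snps,
      r2 = b$r2, beta = b$beta, p = b$p, stringsAsFactors = FALSE)
  }
  cross <- do.call(rbind, cross)
  rownames(cross) <- NULL
  stage_log(verbose, "cross_trait", "%d cross-trait fits", nrow(cross))

  families <- run_test_families(consistency, cross)

  peer_target <- if ("peer_problems_11y" %in% config$cross_targets)
    "peer_problems_11y" else config$cross_targets[1]
  overlap <- subset_overlap(scans[[cb]]$best_snps,
                            cross_scans[[peer_target]]$best_snps,
                            label_a = paste0(cb, " (consistency)"),
                            label_b = paste0(peer_target, " (cross-trait)"))
  stage_log(verbose, "overlap", "%d/%d shared (%s%%)", overlap$n_shared,
            overlap$n_a, format(overlap$pct_of_a_rounded))

  corr_traits <- intersect(c(LANGUAGE_TRAITS, SDQ_TRAITS), names(phen))
  correlations <- phenotype_correlations(phen[, corr_traits, drop = FALSE])

  bundle <- structure(list(
    config = config, cohort = cohort, qc_report = qc_res$report,
    split = halves, association = assoc, gene_min_p = min_p,
    clumps = clumps, scans = scans, cross_scans = cross_scans,
    families = families, overlap = overlap, correlations = correlations,
    provenance = list(seed = config$seed, fit_mode = config$fit_mode,
                      version = as.character(utils::packageVersion("polyprofile")),
                      timestamp = format(Sys.time(), tz = "UTC"))),
    class = "report_bundle")
  if (!is.null(config$out_dir)) write_report_bundle(bundle, config$out_dir)
  bundle
}

#' Write a report bundle as TSV/JSON files with a manifest
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the manifest path.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put_tsv <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, name)
  }
  put_json <- function(x, name) {
    path <- file.path(dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    files <<- c(files, name)
  }
  put_json(bundle$qc_report, "qc_report.json")
  put_tsv(bundle$association, "association.tsv")
  put_tsv(as.data.frame(bundle$gene_min_p$matrix), "gene_min_p.tsv")
  for (tr in names(bundle$clumps)) {
    cl <- bundle$clumps[[tr]]
    if (nrow(cl$index)) put_tsv(cl$index, sprintf("clump_%s.tsv", tr))
  }
  for (tr in names(bundle$scans))
    put_tsv(bundle$scans[[tr]]$scan, sprintf("scan_%s.tsv", tr))
  put_tsv(bundle$families$consistency, "family_consistency.tsv")
  put_tsv(bundle$families$cross_trait, "family_cross_trait.tsv")
  put_json(bundle$families[c("consistency", "cross_trait", "fdr")],
           "families.json")
  put_json(bundle$overlap[c("label_a", "label_b", "n_a", "n_b", "n_shared",
                            "pct_of_a", "pct_of_a_rounded", "subset")],
           "overlap.json")
  put_tsv(format_correlations(bundle$correlations), "correlations.tsv")
  manifest <- list(files = files, provenance = bundle$provenance,
                   seed = bundle$config$seed)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
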