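#' Run the full gene-centered rare-variant association pipeline
#'
#' Executes, in order: post-imputation QC, rare-variant accounting,
#' principal-component computation on common variants, per-gene LD pruning
#' to an independent marker set, per-gene burden and SKAT tests with
#' genomic-control correction, pooled-marker permutation correction,
#' intersection-based candidate selection and, when a gene-disease table
#' is supplied, the annotation-enrichment test.  Per-stage artifacts are
#' written under `config$out_dir`, each with a provenance header, together
#' with a machine-readable `manifest.yaml`.
#'
#' @param config A [run_config()] (paths and thresholds), or a list with
#'   in-memory inputs `geno` ([genotype_matrix()]), `pheno` and `regions`
#'   `data.frame`s in place of paths.
#' @return Invisibly, a list with the per-stage results: `qc_report`,
#'   `tally`, `functional`, `pcs`, `pruned_idx`, `results`, `candidates`,
#'   `enrichment`, `manifest`.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  # --- inputs ---------------------------------------------------------
  geno <- stage("read_genotypes", {
    if (inherits(cfg$geno, "genotype_matrix")) cfg$geno
    else read_genotypes(cfg$geno)
  })
  pheno <- stage("read_phenotypes", {
    if (is.data.frame(cfg$pheno)) cfg$pheno else read_phenotypes(cfg$pheno)
  })
  regions <- stage("read_regions", {
    if (is.data.frame(cfg$regions)) cfg$regions
    else read_gene_regions(cfg$regions)
  })
  idx <- match(geno$samples$sample_id, pheno$sample_id)
  if (any(is.na(idx))) stop("samples missing from the phenotype table")
  geno$samples$status <- pheno$status[idx]
  if ("subpop" %in% names(pheno)) geno$samples$subpop <- pheno$subpop[idx]
  ann <- if (!is.null(cfg$annotations)) {
    if (is.data.frame(cfg$annotations)) cfg$annotations
    else read_annotations(cfg$annotations)
  }
  gdt <- if (!is.null(cfg$gene_disease)) {
    if (is.data.frame(cfg$gene_disease)) cfg$gene_disease
    else read_gene_disease(cfg$gene_disease)
  }
  out_dir <- cfg$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  prov <- list(package = as.character(utils::packageVersion("rarescan")),
               seed = cfg$seed,
               thresholds = unclass(cfg$thresholds),
               r2_threshold = cfg$r2_threshold, maf_max = cfg$maf_max,
               n_perm = cfg$n_perm, alpha = cfg$alpha)
  hdr <- list(rarescan = prov$package, seed = prov$seed,
              r2_threshold = cfg$r2_threshold, maf_max = cfg$maf_max)
  # --- QC -------------------------------------------------------------
  qc <- stage("imputation_qc", apply_imputation_qc(geno, cfg$thresholds))
  geno <- qc$geno
  write_results_tsv(qc$report, file.path(out_dir, "qc_report.tsv"), hdr)
  # --- annotation merge ----------------------------------------------
  if (!is.null(ann)) {
    geno$variants$annotation <-
      ann$category[match(geno$variants$id, ann$variant_id)]
  }
  # --- stratification covariates -------------------------------------
  st <- variant_stats_table(geno)
  pcs <- NULL
  if (cfg$n_pcs > 0L) {
    common <- which(st$category == "common")
    pcs <- stage("pca", {
      if (length(common) <= cfg$n_pcs) {
        stop("not enough common variants (", length(common),
             ") to compute ", cfg$n_pcs, " PCs")
      }
      pca_genotypes(geno, variant_idx = common, k = cfg$n_pcs)
    })
    utils::write.table(
      data.frame(sample_id = geno$samples$sample_id, pcs$scores),
      file.path(out_dir, "pcs.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  # --- LD pruning -----------------------------------------------------
  pruned_idx <- stage("prune", {
    prune_by_gene(geno, regions, threshold = cfg$r2_threshold,
                  window = cfg$prune_window, step = cfg$prune_step)
  })
  pruned <- subset_geno(geno, variants = pruned_idx)
  # --- variant accounting (independent set) ---------------------------
  tally <- stage("tally", tally_categories(pruned))
  write_results_tsv(tally, file.path(out_dir, "category_tally.tsv"), hdr)
  functional <- NULL
  if (!is.null(ann)) {
    rare_ids <- st$id[st$category %in% rare_categories]
    functional <- functional_tally(
      geno$variants[geno$variants$id %in% rare_ids, , drop = FALSE],
      pruned_ids = pruned$variants$id)
    write_results_tsv(functional,
                      file.path(out_dir, "functional_tally.tsv"), hdr)
  }
  # --- association tests ---------------------------------------------
  results <- stage("gene_tests", {
    run_all_genes(pruned, regions,
                  pcs = if (is.null(pcs)) NULL else pcs$scores,
                  maf_max = cfg$maf_max, weights_beta = cfg$weights_beta)
  })
  if (nrow(results) == 0L) {
    manifest <- c(prov, list(n_genes_tested = 0L))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
    return(invisible(list(qc_report = qc$report, tally = tally,
                          functional = functional, pcs = pcs,
                          pruned_idx = pruned_idx, results = results,
                          candidates = results, enrichment = NULL,
                          manifest = manifest)))
  }
  # --- empirical multiple-testing correction --------------------------
  pooled <- build_pooled_table(pruned, regions, maf_max = cfg$maf_max)
  results <- stage("empirical_correction", {
    empirical_correct(results, pooled, geno$samples$status,
                      pcs = if (is.null(pcs)) NULL else pcs$scores,
                      n_perm = cfg$n_perm, seed = cfg$seed,
                      weights_beta = cfg$weights_beta)
  })
  report <- results
  report$P_burden_emp_str <- format_empirical_p(report$P_burden_emp,
                                                cfg$n_perm)
  report$P_SKAT_emp_str <- format_empirical_p(report$P_SKAT_emp,
                                              cfg$n_perm)
  lam <- list(burden = attr(results, "lambda_burden")$lambda,
              skat = attr(results, "lambda_skat")$lambda)
  write_results_tsv(report, file.path(out_dir, "results.tsv"),
                    c(hdr, list(lambda_burden = sprintf("%.2f", lam$burden),
                                lambda_skat = sprintf("%.2f", lam$skat))))
  # --- candidate selection -------------------------------------------
  candidates <- stage("select", {
    if (cfg$alpha >= 1) {
      out <- results
      out$direction <- ifelse(out$OR > 1, "risk", "protective")
      out[order(out$P_burden_emp, out$P_SKAT_emp), , drop = FALSE]
    } else {
      select_candidates(results, alpha = cfg$alpha)
    }
  })
  write_results_tsv(candidates, file.path(out_dir, "candidates.tsv"), hdr)
  # --- enrichment -----------------------------------------------------
  enr <- NULL
  if (!is.null(gdt) && nrow(candidates) > 0L &&
      nrow(candidates) < nrow(results)) {
    enr <- stage("enrichment", {
      enrichment_test(candidates$gene, results$gene, gdt,
                      R = cfg$enrichment_R, seed = cfg$seed)
    })
    write_results_tsv(
      data.frame(observed = enr$observed, expected_mean = enr$expected_mean,
                 expected_sd = enr$expected_sd, z = enr$z, p = enr$p,
                 p_empirical = enr$p_empirical, R = enr$R,
                 universe_size = enr$universe_size),
      file.path(out_dir, "enrichment.tsv"), hdr)
  }
  manifest <- c(prov, list(
    n_samples = n_samples(geno), n_variants_postqc = n_variants(geno),
    n_variants_pruned = length(pruned_idx),
    n_genes_tested = nrow(results),
    n_candidates = nrow(candidates),
    lambda_burden = lam$burden, lambda_skat = lam$skat))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(qc_report = qc$report, tally = tally,
                 functional = functional, pcs = pcs,
                 pruned_idx = pruned_idx, results = results,
                 candidates = candidates, enrichment = enr,
                 manifest = manifest))
}
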