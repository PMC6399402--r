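#' Pooled rare-marker table
#'
#' Concatenates the dosage columns of all polymorphic rare variants of all
#' tested genes into one table, with a column-to-source-gene map.  Random
#' marker sets of matching size are drawn from it by
#' [empirical_correct()]; it must be built from the same pruned
#' independent set as the observed tests.
#'
#' @param geno A [genotype_matrix()] (pruned independent set).
#' @param regions Gene-region `data.frame`.
#' @param maf_max Rare-variant threshold.
#' @return List of class `pooled_marker_table`: `dosages`, `variant_idx`,
#'   `gene_map` (source gene per column).
#' @export
build_pooled_table <- function(geno, regions, maf_max = 0.01) {
  assign <- assign_variants(regions, geno$variants)
  st <- variant_stats_table(geno)
  cols <- integer()
  gene_map <- character()
  for (g in names(assign)) {
    idx <- assign[[g]]
    idx <- idx[st$mac[idx] >= 1L & st$maf[idx] < maf_max]
    cols <- c(cols, idx)
    gene_map <- c(gene_map, rep(g, length(idx)))
  }
  structure(list(dosages = geno$dosages[, cols, drop = FALSE],
                 variant_idx = cols, gene_map = gene_map),
            class = "pooled_marker_table")
}

# Empirical p-value from observed and replicate p-values:
# (r + 1) / (N + 1), r = #{replicates <= observed}; never exactly 0.
empirical_pvalue <- function(obs_p, replicate_p) {
  n <- length(replicate_p)
  (sum(replicate_p <= obs_p) + 1) / (n + 1)
}

#' Pooled-marker permutation multiple-testing correction
#'
#' For each tested gene, `n_perm` replicates draw (without replacement
#' within a replicate) as many columns from the pooled rare-marker table
#' as the gene has markers (`NMUT`), run the identical burden and SKAT
#' tests with identical covariates, and GC-correct the replicate p-values
#' with the observed family lambdas.  The empirical corrected p-value is
#' `(r + 1) / (n_perm + 1)` where `r` counts replicates at or below the
#' observed GC-corrected p-value.  Deterministic given `seed`.
#'
#' @param results Output of [run_all_genes()] (with GC columns).
#' @param pooled A [build_pooled_table()] result from the same genotype
#'   matrix.
#' @param status 0/1 phenotype vector.
#' @param pcs Covariates used for the observed tests.
#' @param n_perm Number of replicates.
#' @param seed Integer seed.
#' @param weights_beta SKAT weighting parameters.
#' @return `results` with columns `P_burden_emp`, `P_SKAT_emp` appended;
#'   attribute `n_perm` records the replicate count.
#' @export
empirical_correct <- function(results, pooled, status, pcs = NULL,
                              n_perm = 1000L, seed = 1L,
                              weights_beta = c(1, 25)) {
  stopifnot(inherits(pooled, "pooled_marker_table"))
  if (is.null(attr(results, "lambda_burden"))) {
    stop("results must carry GC lambdas (run_all_genes with gc = TRUE)")
  }
  set.seed(as.integer(seed))
  m_pool <- ncol(pooled$dosages)
  if (any(results$NMUT > m_pool)) {
    stop("a gene has more markers (", max(results$NMUT),
         ") than the pooled table holds (", m_pool, ")")
  }
  lb <- attr(results, "lambda_burden")
  ls <- attr(results, "lambda_skat")
  null <- fit_null_model(status, pcs)
  emp_b <- emp_s <- numeric(nrow(results))
  for (i in seq_len(nrow(results))) {
    m <- results$NMUT[i]
    pb <- ps <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      cols <- sample.int(m_pool, m)
      D <- pooled$dosages[, cols, drop = FALSE]
      bt <- burden_test(burden_score(D), status, covariates = pcs)
      sk <- skat_test(D, null, weights_beta = weights_beta)
      pb[b] <- bt$p_raw
      ps[b] <- sk$p_raw
    }
    pb <- gc_correct(pb, lb)
    ps <- gc_correct(ps, ls)
    emp_b[i] <- empirical_pvalue(results$P_burden_gc[i], pb[!is.na(pb)])
    emp_s[i] <- empirical_pvalue(results$P_SKAT_gc[i], ps[!is.na(ps)])
  }
  results$P_burden_emp <- emp_b
  results$P_SKAT_emp <- emp_s
  attr(results, "n_perm") <- as.integer(n_perm)
  results
}

#' Select candidate genes by the SKAT-and-burden intersection rule
#'
#' A gene is selected when both its genomic-control-corrected and its
#' empirical (multi-testing) corrected p-values fall below `alpha` in
#' *both* test families.  Direction is `risk` for OR > 1, `protective`
#' otherwise.  Output is sorted by empirical burden p, then empirical
#' SKAT p.
#'
#' @param results Output of [empirical_correct()].
#' @param alpha Significance level.
#' @return The selected subset of `results` with a `direction` column.
#' @export
select_candidates <- function(results, alpha = 0.05) {
  need <- c("P_burden_gc", "P_SKAT_gc", "P_burden_emp", "P_SKAT_emp")
  if (!all(need %in% names(results))) {
    stop("results must carry GC-corrected and empirical p-value columns")
  }
  sel <- !is.na(results$P_burden_gc) & !is.na(results$P_SKAT_gc) &
    results$P_burden_gc < alpha & results$P_burden_emp < alpha &
    results$P_SKAT_gc < alpha & results$P_SKAT_emp < alpha
  out <- results[sel, , drop = FALSE]
  out$direction <- ifelse(out$OR > 1, "risk", "protective")
  out[order(out$P_burden_emp, out$P_SKAT_emp), , drop = FALSE]
}

#' Render empirical p-values for reports
#'
#' Values at the permutation floor `1/(n_perm + 1)` are rendered as
#' `"<1.00E-03"`-style bounds (one over the replicate count); others in
#' scientific notation.
#'
#' @param p Empirical p-values.
#' @param n_perm Replicate count used to compute them.
#' @return Character vector.
#' @export
format_empirical_p <- function(p, n_perm) {
  floor_p <- 1 / (n_perm + 1)
  ifelse(p <= floor_p + 1e-12,
         sprintf("<%.2E", 1 / n_perm),
         sprintf("%.2E", p))
}
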