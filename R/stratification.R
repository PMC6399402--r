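#' Select ancestry-informative markers
#'
#' Ranks common markers by the maximum pairwise absolute allele-frequency
#' difference between the supplied groups and accepts them greedily
#' subject to pairwise `r^2 < r2_max` with markers already accepted, until
#' `k` markers are selected or candidates are exhausted.
#'
#' @param geno A [genotype_matrix()] (common variants expected).
#' @param group_labels Vector of group labels, one per sample (>= 2
#'   groups).
#' @param r2_max Pairwise independence threshold.
#' @param k Number of markers requested.
#' @return Integer vector of selected variant indices (warns when fewer
#'   than `k` are acceptable).
#' @export
select_informative_markers <- function(geno, group_labels, r2_max = 0.1,
                                       k = 100L) {
  stopifnot(inherits(geno, "genotype_matrix"))
  groups <- unique(group_labels)
  if (length(groups) < 2L) stop("need at least two groups")
  freqs <- vapply(groups, function(g) {
    colMeans(geno$dosages[group_labels == g, , drop = FALSE],
             na.rm = TRUE) / 2
  }, numeric(n_variants(geno)))
  score <- apply(freqs, 1, function(f) max(dist(f)))
  ord <- order(score, decreasing = TRUE)
  accepted <- integer()
  for (j in ord) {
    if (length(accepted) >= k) break
    ok <- TRUE
    for (a in accepted) {
      if (pairwise_r2(geno$dosages[, j], geno$dosages[, a]) >= r2_max) {
        ok <- FALSE
        break
      }
    }
    if (ok) accepted <- c(accepted, j)
  }
  if (length(accepted) < k) {
    warning("only ", length(accepted), " of ", k,
            " requested markers acceptable at r2 < ", r2_max)
  }
  sort(accepted)
}

#' Principal components of standardized genotypes
#'
#' Genotypes are centered by twice the sample allele frequency and scaled
#' by `sqrt(2 p (1 - p))`; missing values become 0 after centering.
#' Constant markers are skipped.  Components are deterministic: each
#' component's sign is fixed by forcing its largest-magnitude marker
#' loading positive.
#'
#' @param geno A [genotype_matrix()].
#' @param variant_idx Optional marker subset (e.g. from
#'   [select_informative_markers()]).
#' @param k Number of components.
#' @return List of class `pc_set`: `scores` (samples x k), `loadings`
#'   (markers x k), `var_explained`, `markers_used`.
#' @export
pca_genotypes <- function(geno, variant_idx = NULL, k = 10L) {
  stopifnot(inherits(geno, "genotype_matrix"))
  vi <- variant_idx %||% seq_len(n_variants(geno))
  X <- geno$dosages[, vi, drop = FALSE]
  p <- colMeans(X, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  if (!all(keep)) {
    message("pca: skipping ", sum(!keep), " constant marker(s)")
  }
  X <- X[, keep, drop = FALSE]
  vi <- vi[keep]
  p <- p[keep]
  if (ncol(X) == 0L) stop("no polymorphic markers for PCA")
  k <- min(k, nrow(X) - 1L, ncol(X))
  Z <- sweep(X, 2, 2 * p)
  Z[is.na(Z)] <- 0
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(Z, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(i) {
    v <- sv$v[, i]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sweep(sv$u, 2, sv$d[seq_len(k)] * flip, "*")
  loadings <- sweep(sv$v, 2, flip, "*")
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  rownames(scores) <- geno$samples$sample_id
  structure(list(scores = scores, loadings = loadings,
                 var_explained = sv$d^2 / sum(sv$d^2),
                 markers_used = vi),
            class = "pc_set")
}

#' Genomic-control inflation factor
#'
#' Converts p-values to 1-df chi-square quantiles and reports
#' `lambda = median(chi2) / qchisq(0.5, 1)` (reference median 0.4549).
#'
#' @param p_values Vector of p-values in (0, 1\].
#' @param source Optional label of the test family.
#' @return List of class `lambda_gc`: `lambda`, `n_tests`, `source`.
#' @export
genomic_lambda <- function(p_values, source = NA_character_) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) == 0L) stop("no p-values supplied")
  if (any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  chi <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  structure(list(lambda = stats::median(chi) / stats::qchisq(0.5, 1),
                 n_tests = length(p_values), source = source),
            class = "lambda_gc")
}

#' @export
print.lambda_gc <- function(x, ...) {
  cat(sprintf("lambda_GC = %.2f (%d tests%s)\n", x$lambda, x$n_tests,
              if (is.na(x$source)) "" else paste0(", ", x$source)))
  invisible(x)
}

#' Genomic-control correction of p-values
#'
#' Each p-value is mapped to its 1-df chi-square quantile, the statistic is
#' divided by `lambda`, and the deflated statistic is mapped back to a
#' p-value.  `lambda = 1` is the identity; `lambda > 1` strictly increases
#' every p < 1.  Ordering is preserved.
#'
#' @param p_values Vector of p-values in (0, 1\].
#' @param lambda Inflation factor (> 0), or a [genomic_lambda()] result.
#' @return Corrected p-values.
#' @export
gc_correct <- function(p_values, lambda) {
  if (inherits(lambda, "lambda_gc")) lambda <- lambda$lambda
  if (!is.numeric(lambda) || lambda <= 0) stop("lambda must be > 0")
  chi <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::pchisq(chi / lambda, df = 1, lower.tail = FALSE)
}
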