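#' Construct a genotype matrix
#'
#' The central container of the package: a samples x variants dosage matrix
#' (counts of the alternate allele, `0`/`1`/`2`, `NA` for missing) together
#' with per-variant and per-sample metadata.
#'
#' @param dosages Integer or numeric matrix, samples in rows, variants in
#'   columns.  Allowed values are 0, 1, 2 and `NA`.
#' @param variants `data.frame` with one row per variant and at least the
#'   columns `chrom`, `pos` (1-based), `id`, `ref`, `alt`.  Optional columns:
#'   `info_score` (imputation quality in \[0, 1\]) and `annotation`
#'   (functional category label).
#' @param samples `data.frame` with one row per sample and at least the
#'   column `sample_id`.  Optional columns: `status` (0 = control,
#'   1 = case) and `subpop` (ancestry label, synthetic cohorts only).
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `variants` and `samples`.
#' @export
#' @examples
#' g <- genotype_matrix(
#'   matrix(c(0L, 1L, 2L, 0L), 2, 2),
#'   data.frame(chrom = "1", pos = c(100L, 200L), id = c("v1", "v2"),
#'              ref = "A", alt = "G"),
#'   data.frame(sample_id = c("s1", "s2"))
#' )
#' dim(g)
genotype_matrix <- function(dosages, variants, samples) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  stopifnot(is.data.frame(variants), is.data.frame(samples))
  if (nrow(samples) != nrow(dosages) || nrow(variants) != ncol(dosages)) {
    stop("dosage dimensions (", nrow(dosages), " x ", ncol(dosages),
         ") do not match sample/variant metadata (", nrow(samples), " x ",
         nrow(variants), ")")
  }
  need_v <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need_v %in% names(variants))) {
    stop("variants must have columns: ", paste(need_v, collapse = ", "))
  }
  if (!"sample_id" %in% names(samples)) {
    stop("samples must have a sample_id column")
  }
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  if (any(variants$pos < 1L)) stop("variant positions must be >= 1")
  if ("info_score" %in% names(variants)) {
    isc <- variants$info_score
    if (any(!is.na(isc) & (isc < 0 | isc > 1))) {
      stop("info_score values must lie in [0, 1]")
    }
  }
  rownames(dosages) <- samples$sample_id
  colnames(dosages) <- variants$id
  structure(list(dosages = dosages,
                 variants = as.data.frame(variants, stringsAsFactors = FALSE),
                 samples = as.data.frame(samples, stringsAsFactors = FALSE)),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) c(nrow(x$dosages), ncol(x$dosages))

#' Number of samples / variants in a genotype matrix
#' @param x A `genotype_matrix`.
#' @return Integer count.
#' @export
n_samples <- function(x) nrow(x$dosages)

#' @rdname n_samples
#' @export
n_variants <- function(x) ncol(x$dosages)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", n_samples(x), "samples x", n_variants(x),
      "variants\n")
  if ("status" %in% names(x$samples) && !all(is.na(x$samples$status))) {
    cat("  cases:", sum(x$samples$status == 1, na.rm = TRUE),
        " controls:", sum(x$samples$status == 0, na.rm = TRUE), "\n")
  }
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing dosage rate: %.4f\n", miss))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x A `genotype_matrix`.
#' @param samples Optional integer/logical index over samples.
#' @param variants Optional integer/logical index over variants.
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
subset_geno <- function(x, samples = NULL, variants = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  si <- if (is.null(samples)) seq_len(n_samples(x)) else samples
  vi <- if (is.null(variants)) seq_len(n_variants(x)) else variants
  genotype_matrix(x$dosages[si, vi, drop = FALSE],
                  x$variants[vi, , drop = FALSE],
                  x$samples[si, , drop = FALSE])
}

#' Per-variant call rate
#' @param x A `genotype_matrix`.
#' @return Numeric vector, fraction of non-missing genotypes per variant.
#' @export
variant_call_rate <- function(x) colMeans(!is.na(x$dosages))

#' Per-sample call rate
#' @param x A `genotype_matrix`.
#' @return Numeric vector, fraction of non-missing genotypes per sample.
#' @export
sample_call_rate <- function(x) rowMeans(!is.na(x$dosages))
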