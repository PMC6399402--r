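#' Count gene-disease annotations hit by a gene list
#'
#' Number of (gene, disease) pairs whose gene appears in the list; a gene
#' annotated for three diseases contributes three.
#'
#' @param gene_list Character vector of gene ids.
#' @param table Gene-disease `data.frame` (`gene_id`, `disease_id`).
#' @return Integer count.
#' @export
count_annotations <- function(gene_list, table) {
  sum(table$gene_id %in% gene_list)
}

#' Resampling test for annotation enrichment
#'
#' Compares the annotation count of a result list against `R` random gene
#' sets of the same size drawn uniformly without replacement from the
#' tested-gene universe.  Reports the Z-score
#' `(observed - mean) / sd` over replicates and its one-sided upper-tail
#' normal p-value (enrichment direction); an exact resampling p-value
#' `(r + 1)/(R + 1)` is also returned.
#'
#' @param result_list Candidate gene ids (must be a proper subset of
#'   `universe`).
#' @param universe All tested gene ids.
#' @param table Gene-disease annotation `data.frame`.
#' @param R Number of random gene sets.
#' @param seed Integer seed.
#' @return List of class `enrichment_result`: `observed`, `expected_mean`,
#'   `expected_sd`, `z`, `p`, `p_empirical`, `R`, `universe_size`,
#'   `replicate_counts`.
#' @export
enrichment_test <- function(result_list, universe, table, R = 1000L,
                            seed = 1L) {
  if (R < 100L) stop("R must be >= 100")
  if (!all(result_list %in% universe)) {
    stop("result_list must be a subset of the universe")
  }
  n <- length(result_list)
  if (n >= length(universe)) {
    stop("result_list must be strictly smaller than the universe")
  }
  set.seed(as.integer(seed))
  observed <- count_annotations(result_list, table)
  counts <- vapply(seq_len(R), function(b) {
    count_annotations(sample(universe, n), table)
  }, numeric(1))
  mu <- mean(counts)
  sdev <- stats::sd(counts)
  if (sdev == 0) {
    stop("replicate annotation counts are constant (sd = 0); ",
         "Z undefined - is the annotation table empty or saturated?")
  }
  z <- (observed - mu) / sdev
  structure(list(observed = observed, expected_mean = mu,
                 expected_sd = sdev, z = z,
                 p = stats::pnorm(z, lower.tail = FALSE),
                 p_empirical = (sum(counts >= observed) + 1) / (R + 1),
                 R = R, universe_size = length(universe),
                 replicate_counts = counts),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(paste0("enrichment: observed %d annotations vs %.2f +/- %.2f",
                     " expected (R = %d)\n  Z = %.3f, one-sided P = %.3g",
                     " (resampling P = %.3g)\n"),
              x$observed, x$expected_mean, x$expected_sd, x$R, x$z, x$p,
              x$p_empirical))
  invisible(x)
}
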