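#' Pairwise composite linkage-disequilibrium r-squared
#'
#' Squared Pearson correlation of two dosage vectors over jointly called
#' samples (composite LD; no phasing required).  A pair monomorphic on its
#' joint support has undefined correlation and is reported as 0.
#'
#' @param dosage_a,dosage_b Dosage vectors.
#' @return r-squared in \[0, 1\].
#' @export
pairwise_r2 <- function(dosage_a, dosage_b) {
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  if (sum(ok) < 2L) stop("need >= 2 jointly called samples")
  a <- dosage_a[ok]
  b <- dosage_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    message("pairwise_r2: monomorphic on joint support; returning 0")
    return(0)
  }
  stats::cor(a, b)^2
}

#' Greedy sliding-window LD pruning
#'
#' Within each window of `window` consecutive (position-sorted) variants,
#' any still-kept pair with `r^2 >= threshold` loses its lower-MAF member
#' (tie: the later position is removed); the window slides by `step`.
#' Sweeps repeat until a full pass removes nothing, which makes the
#' operation idempotent.
#'
#' @param geno A [genotype_matrix()] with position-sorted variants, or a
#'   plain dosage matrix.
#' @param threshold Removal threshold on pairwise r-squared.
#' @param window Window width in variants.
#' @param step Window slide in variants.
#' @return List of class `prune_result`: `kept` and `removed` variant
#'   indices, and `trigger` (for each removed variant, the index of the
#'   partner that triggered removal).
#' @export
prune_ld <- function(geno, threshold = 0.1, window = 50L, step = 5L) {
  d <- if (inherits(geno, "genotype_matrix")) geno$dosages else as.matrix(geno)
  m <- ncol(d)
  if (m == 0L) {
    return(structure(list(kept = integer(), removed = integer(),
                          trigger = integer()), class = "prune_result"))
  }
  maf <- vapply(seq_len(m), function(j) minor_allele_stats(d[, j])$maf,
                numeric(1))
  kept <- seq_len(m)
  removed <- integer()
  trigger <- integer()
  repeat {
    any_removed <- FALSE
    alive <- rep(TRUE, length(kept))
    starts <- seq(1L, max(1L, length(kept) - 1L), by = step)
    for (s in starts) {
      win <- s:min(s + window - 1L, length(kept))
      if (length(win) < 2L) next
      for (ii in seq_along(win)[-length(win)]) {
        i <- win[ii]
        if (!alive[i]) next
        for (jj in seq(ii + 1L, length(win))) {
          j <- win[jj]
          if (!alive[j]) next
          vi <- kept[i]
          vj <- kept[j]
          r2 <- suppressMessages(pairwise_r2(d[, vi], d[, vj]))
          if (r2 >= threshold) {
            # drop the lower-MAF member; tie -> later position
            victim <- if (maf[vi] < maf[vj]) i
                      else if (maf[vj] < maf[vi]) j
                      else j
            alive[victim] <- FALSE
            removed <- c(removed, kept[victim])
            trigger <- c(trigger, kept[if (victim == i) j else i])
            any_removed <- TRUE
            if (victim == i) break
          }
        }
      }
    }
    kept <- kept[alive]
    if (!any_removed) break
  }
  structure(list(kept = kept, removed = sort(removed),
                 trigger = trigger[order(removed)]),
            class = "prune_result")
}

#' Per-gene LD pruning
#'
#' Applies [prune_ld()] independently within each gene region (the testing
#' unit) and returns the union of kept variant indices.
#'
#' @param geno A [genotype_matrix()].
#' @param regions Gene-region `data.frame` (`gene_id`, `chrom`, `start`,
#'   `end`).
#' @param ... Passed to [prune_ld()].
#' @return Sorted integer vector of kept variant indices (variants not in
#'   any region are dropped).
#' @export
prune_by_gene <- function(geno, regions, ...) {
  assign <- assign_variants(regions, geno$variants)
  kept <- integer()
  for (idx in assign) {
    if (length(idx) == 0L) next
    pr <- prune_ld(geno$dosages[, idx, drop = FALSE], ...)
    kept <- c(kept, idx[pr$kept])
  }
  sort(unique(kept))
}
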