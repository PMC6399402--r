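#' Minor-allele statistics for one variant
#'
#' The minor allele is the lower-frequency allele over the combined
#' case-control sample; a tie at 0.5 designates the alternate allele as
#' minor.  Counts and frequencies are computed over called (non-missing)
#' genotypes only.
#'
#' @param dosage Vector of alternate-allele dosages (0/1/2, `NA` missing).
#' @return A list of class `variant_stats` with elements `maf`, `mac`,
#'   `n_called`, `call_rate`, `minor_is_alt` and `category` (see
#'   [classify_rare()]).
#' @export
#' @examples
#' # one heterozygote among 8,277 individuals: MAF = 0.006%
#' d <- c(1L, rep(0L, 8276))
#' round(100 * minor_allele_stats(d)$maf, 3)
minor_allele_stats <- function(dosage) {
  called <- !is.na(dosage)
  n_called <- sum(called)
  if (n_called == 0L) stop("all genotypes missing; MAF undefined")
  alt <- sum(dosage[called])
  n2 <- 2L * n_called
  minor_is_alt <- alt <= n2 - alt           # tie -> alt designated minor
  mac <- as.integer(min(alt, n2 - alt))
  maf <- mac / n2
  structure(list(maf = maf, mac = mac, n_called = n_called,
                 call_rate = n_called / length(dosage),
                 minor_is_alt = minor_is_alt,
                 category = classify_rare(mac, maf)),
            class = "variant_stats")
}

#' Rare-variant category of a variant
#'
#' Categories partition all polymorphic variants: `singleton` (minor-allele
#' count exactly 1, regardless of sample size), `very_rare` (MAC > 1 and
#' MAF < 0.1%), `rare_strict` (0.1% <= MAF <= 1%; the boundary MAF = 0.1%
#' belongs here so the two intervals partition), and `common` (MAF > 1%).
#' Monomorphic input gets the distinct label `monomorphic`.
#'
#' @param mac Minor-allele count.
#' @param maf Minor-allele frequency (fraction in \[0, 0.5\]).
#' @return Category label (character).
#' @export
classify_rare <- function(mac, maf) {
  stopifnot(length(mac) == 1L, length(maf) == 1L)
  if (mac == 0L) return("monomorphic")
  if (mac == 1L) return("singleton")
  if (maf < 0.001) return("very_rare")
  if (maf <= 0.01) return("rare_strict")
  "common"
}

#' Column-wise minor-allele summaries
#'
#' Vectorized companion of [minor_allele_stats()] over all variants of a
#' genotype matrix.
#'
#' @param geno A [genotype_matrix()].
#' @return `data.frame` with columns `id`, `mac`, `maf`, `n_called`,
#'   `call_rate`, `minor_is_alt`, `category`.
#' @export
variant_stats_table <- function(geno) {
  d <- geno$dosages
  n_called <- colSums(!is.na(d))
  if (any(n_called == 0L)) {
    stop("variant(s) with all genotypes missing: ",
         paste(utils::head(geno$variants$id[n_called == 0L]), collapse = ", "))
  }
  alt <- colSums(d, na.rm = TRUE)
  n2 <- 2 * n_called
  mac <- as.integer(pmin(alt, n2 - alt))
  maf <- mac / n2
  category <- ifelse(mac == 0L, "monomorphic",
              ifelse(mac == 1L, "singleton",
              ifelse(maf < 0.001, "very_rare",
              ifelse(maf <= 0.01, "rare_strict", "common"))))
  data.frame(id = geno$variants$id, mac = mac, maf = maf,
             n_called = n_called, call_rate = n_called / nrow(d),
             minor_is_alt = alt <= n2 - alt, category = category,
             stringsAsFactors = FALSE)
}

rare_categories <- c("singleton", "very_rare", "rare_strict")

#' Tally rare-variant categories
#'
#' Builds the per-category accounting of independent rare variation: number
#' of variants and summed minor-allele counts per category, with column
#' percentages.  Input variants are restricted to polymorphic rare
#' variants (MAF < 1% is expected upstream; a defensive subset is applied).
#'
#' @param geno A [genotype_matrix()] of independent rare variants.
#' @return A `category_tally` `data.frame`; see [category_tally()].
#' @export
tally_categories <- function(geno) {
  st <- variant_stats_table(geno)
  st <- st[st$category %in% rare_categories, , drop = FALSE]
  counts <- alleles <- stats::setNames(numeric(3), rare_categories)
  for (cat in rare_categories) {
    sub <- st[st$category == cat, , drop = FALSE]
    counts[cat] <- nrow(sub)
    alleles[cat] <- sum(sub$mac)
  }
  category_tally(counts, alleles)
}

#' Category tally from counts
#'
#' Computes column percentages from per-category variant counts and
#' minor-allele sums.  Exposed separately so published accounting tables
#' can be recomputed directly from their counts.
#'
#' @param counts Named numeric vector of variant counts for categories
#'   `singleton`, `very_rare`, `rare_strict`.
#' @param allele_sums Named numeric vector of summed minor-allele counts
#'   for the same categories.
#' @return `data.frame` of class `category_tally` with columns `category`,
#'   `n_variants`, `pct_variants`, `minor_alleles`, `pct_alleles`.
#' @export
#' @examples
#' category_tally(
#'   c(singleton = 189893, very_rare = 676621, rare_strict = 439810),
#'   c(singleton = 189893, very_rare = 4671537, rare_strict = 24266676)
#' )
category_tally <- function(counts, allele_sums) {
  counts <- counts[rare_categories]
  allele_sums <- allele_sums[rare_categories]
  if (any(is.na(counts)) || any(is.na(allele_sums))) {
    stop("counts and allele_sums must be named by category: ",
         paste(rare_categories, collapse = ", "))
  }
  if (allele_sums[["singleton"]] != counts[["singleton"]]) {
    stop("singleton minor-allele sum must equal the singleton count")
  }
  tot_n <- sum(counts)
  tot_a <- sum(allele_sums)
  out <- data.frame(
    category = rare_categories,
    n_variants = as.numeric(counts),
    pct_variants = if (tot_n > 0) 100 * counts / tot_n else rep(0, 3),
    minor_alleles = as.numeric(allele_sums),
    pct_alleles = if (tot_a > 0) 100 * allele_sums / tot_a else rep(0, 3),
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("category_tally", "data.frame")
  out
}

#' Functional-annotation shares from category counts
#'
#' Companion of [functional_tally()] operating directly on per-category
#' variant counts, so published annotation tables can be recomputed from
#' the counts they print.
#'
#' @param n_all Named numeric vector of variant counts per functional
#'   category (full set).
#' @param n_pruned Optional named vector for the pruned (independent)
#'   subset, over the same categories.
#' @return `data.frame` with columns `category`, `n_all`, `pct_all` and,
#'   when given, `n_pruned`, `pct_pruned`.
#' @export
#' @examples
#' functional_tally_counts(c(intronic = 2305643, other = 403962))
functional_tally_counts <- function(n_all, n_pruned = NULL) {
  out <- data.frame(category = names(n_all), n_all = as.numeric(n_all),
                    pct_all = 100 * as.numeric(n_all) / sum(n_all),
                    stringsAsFactors = FALSE)
  if (!is.null(n_pruned)) {
    n_pruned <- n_pruned[names(n_all)]
    out$n_pruned <- as.numeric(n_pruned)
    out$pct_pruned <- 100 * as.numeric(n_pruned) / sum(n_pruned)
  }
  out
}

#' Functional-annotation tally of rare variants
#'
#' Counts and percentages per functional category (ANNOVAR-style labels)
#' for the full rare variant set and, optionally, for the subset surviving
#' LD pruning.  Variants without a label are counted under `unannotated`.
#'
#' @param variants `data.frame` with a variant `id` column and an
#'   `annotation` column (may contain `NA`).
#' @param pruned_ids Optional character vector of variant ids in the
#'   pruned (independent) set.
#' @return `data.frame` with columns `category`, `n_all`, `pct_all` and,
#'   when `pruned_ids` is given, `n_pruned`, `pct_pruned`.
#' @export
functional_tally <- function(variants, pruned_ids = NULL) {
  ann <- variants$annotation
  if (is.null(ann)) ann <- rep(NA_character_, nrow(variants))
  ann[is.na(ann) | ann == ""] <- "unannotated"
  tab <- table(ann)
  out <- data.frame(category = names(tab), n_all = as.numeric(tab),
                    pct_all = 100 * as.numeric(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  if (!is.null(pruned_ids)) {
    keep <- variants$id %in% pruned_ids
    tabp <- table(factor(ann[keep], levels = names(tab)))
    out$n_pruned <- as.numeric(tabp)
    out$pct_pruned <- if (sum(tabp) > 0) {
      100 * as.numeric(tabp) / sum(tabp)
    } else rep(0, nrow(out))
  }
  out[order(-out$n_all), , drop = FALSE]
}
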