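#' Quality-control thresholds
#'
#' Default values reproduce a stringent GWAS-scaffold and post-imputation
#' filtering scheme: per-sample call rate at least 90%, per-variant call
#' rate at least 98%, MAF at least 1% (scaffold stage only),
#' Hardy-Weinberg exact p at least 1e-4 overall and 0.01 in controls,
#' differential-missingness p at least 1e-5, pairwise kinship below
#' 0.055, and for imputed data an info score at least 0.75 with variant
#' call rate 99% and sample call rate 95% (no MAF restriction).
#'
#' All thresholds are inclusive on the "keep" side.
#'
#' @param sample_call_rate_min,variant_call_rate_min,maf_min,hwe_p_min_all,hwe_p_min_controls,diff_missing_p_max,kinship_max,imp_info_min,imp_variant_call_min,imp_sample_call_min
#'   Individual thresholds; see Details.
#' @return A named list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(sample_call_rate_min = 0.90,
                          variant_call_rate_min = 0.98,
                          maf_min = 0.01,
                          hwe_p_min_all = 1e-4,
                          hwe_p_min_controls = 0.01,
                          diff_missing_p_max = 1e-5,
                          kinship_max = 0.055,
                          imp_info_min = 0.75,
                          imp_variant_call_min = 0.99,
                          imp_sample_call_min = 0.95) {
  th <- list(sample_call_rate_min = sample_call_rate_min,
             variant_call_rate_min = variant_call_rate_min,
             maf_min = maf_min,
             hwe_p_min_all = hwe_p_min_all,
             hwe_p_min_controls = hwe_p_min_controls,
             diff_missing_p_max = diff_missing_p_max,
             kinship_max = kinship_max,
             imp_info_min = imp_info_min,
             imp_variant_call_min = imp_variant_call_min,
             imp_sample_call_min = imp_sample_call_min)
  rates <- unlist(th)
  if (any(rates < 0 | rates > 1)) stop("all thresholds must lie in [0, 1]")
  structure(th, class = "qc_thresholds")
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test of Hardy-Weinberg proportions: given the sample
#' size and minor-allele count, the p-value is the summed probability of
#' every heterozygote configuration whose conditional probability does not
#' exceed that of the observed configuration.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (major homozygote, heterozygote,
#'   minor homozygote; orientation is irrelevant).
#' @return Exact p-value in (0, 1\].
#' @export
#' @examples
#' hwe_exact_test(25, 50, 25)  # modal configuration: p = 1
#' hwe_exact_test(5, 0, 5)     # strong heterozygote deficit
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be nonnegative integers")
  }
  n <- sum(counts)
  if (n == 0L) stop("all genotype counts are zero")
  r <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)  # minor-allele count
  if (r == 0L) return(1.0)
  hs <- seq(r %% 2, min(r, 2 * n - r), by = 2)
  # log P(h | n, r) up to a constant: n! / (nAA! h! naa!) * 2^h
  lp <- h_log_weight(hs, n, r)
  lp <- lp - max(lp)
  pr <- exp(lp)
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hs)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

h_log_weight <- function(h, n, r) {
  n_minor_hom <- (r - h) / 2
  n_major_hom <- n - h - n_minor_hom
  h * log(2) - lfactorial(n_minor_hom) - lfactorial(h) -
    lfactorial(n_major_hom)
}

#' Differential-missingness test
#'
#' Tests whether genotype missingness differs between cases and controls
#' for one variant (2 x 2 table of missing/called vs status).  Uses
#' Fisher's exact test when any expected cell count is below 5, otherwise
#' the 1-df chi-square test without continuity correction.
#'
#' @param miss_cases,obs_cases Missing and called genotype counts in cases.
#' @param miss_controls,obs_controls Same for controls.
#' @return p-value.
#' @export
differential_missingness_test <- function(miss_cases, obs_cases,
                                          miss_controls, obs_controls) {
  tab <- matrix(c(miss_cases, obs_cases, miss_controls, obs_controls), 2, 2)
  if (any(tab < 0)) stop("counts must be nonnegative")
  if (sum(tab) == 0) stop("all counts are zero")
  if (any(colSums(tab) == 0)) stop("each status group needs genotypes")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    stats::fisher.test(tab)$p.value
  } else {
    stats::chisq.test(tab, correct = FALSE)$p.value
  }
}

#' Robust pairwise kinship estimate
#'
#' Pedigree-free estimator from shared heterozygosity and opposite
#' homozygosity:
#' `phi = (N_het.het - 2 * N_opp.hom) / (N_het(i) + N_het(j))`,
#' computed over jointly called genotypes.  Duplicates/MZ twins give 0.5,
#' unrelated pairs scatter around 0 (negative values possible).
#'
#' @param dosage_i,dosage_j Dosage vectors of the two samples.
#' @param min_overlap Minimum jointly called genotypes for a reliable
#'   estimate (pairs below it are flagged, not dropped).
#' @return List with `kinship`, `n_overlap`, `reliable`.
#' @export
kinship_estimate <- function(dosage_i, dosage_j, min_overlap = 100L) {
  ok <- !is.na(dosage_i) & !is.na(dosage_j)
  di <- dosage_i[ok]
  dj <- dosage_j[ok]
  n_het_het <- sum(di == 1L & dj == 1L)
  n_opp <- sum((di == 0L & dj == 2L) | (di == 2L & dj == 0L))
  denom <- sum(di == 1L) + sum(dj == 1L)
  phi <- if (denom > 0) (n_het_het - 2 * n_opp) / denom else NA_real_
  list(kinship = phi, n_overlap = sum(ok),
       reliable = sum(ok) >= min_overlap && denom > 0)
}

qc_log_entry <- function(stage, type, n_removed, n_retained) {
  data.frame(stage = stage, type = type, n_removed = n_removed,
             n_retained = n_retained, stringsAsFactors = FALSE)
}

#' GWAS-scaffold quality control
#'
#' Applies, in a fixed and logged order: sample call rate, variant call
#' rate, MAF, Hardy-Weinberg (whole sample at `hwe_p_min_all`, controls at
#' `hwe_p_min_controls`), differential missingness between cases and
#' controls, and relatedness (from each pair at or above `kinship_max`, the
#' member with the lower call rate is removed; ties by sample order).
#' Thresholds are inclusive on the keep side.  Re-running on the output is
#' a no-op.
#'
#' @param geno A [genotype_matrix()]; `geno$samples$status` is required for
#'   the stratified filters.
#' @param thresholds A [qc_thresholds()].
#' @return List with `geno` (filtered) and `report` (`data.frame` of
#'   per-stage removal counts).
#' @export
apply_scaffold_qc <- function(geno, thresholds = qc_thresholds()) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (!"status" %in% names(geno$samples) ||
      all(is.na(geno$samples$status))) {
    stop("scaffold QC needs case/control status for HWE and ",
         "differential-missingness stratification")
  }
  th <- thresholds
  report <- list()
  # 1. samples by call rate
  keep <- sample_call_rate(geno) >= th$sample_call_rate_min
  report[[1]] <- qc_log_entry("sample_call_rate", "sample",
                              sum(!keep), sum(keep))
  if (!any(keep)) stop("no samples survive the sample call-rate filter")
  geno <- subset_geno(geno, samples = which(keep))
  # 2. variants by call rate
  keep <- variant_call_rate(geno) >= th$variant_call_rate_min
  report[[2]] <- qc_log_entry("variant_call_rate", "variant",
                              sum(!keep), sum(keep))
  if (!any(keep)) stop("no variants survive the variant call-rate filter")
  geno <- subset_geno(geno, variants = which(keep))
  # 3. MAF (scaffold stage: common-variant backbone)
  st <- variant_stats_table(geno)
  keep <- st$maf >= th$maf_min
  report[[3]] <- qc_log_entry("maf", "variant", sum(!keep), sum(keep))
  if (!any(keep)) stop("no variants survive the MAF filter")
  geno <- subset_geno(geno, variants = which(keep))
  # 4. HWE: whole sample and controls-only
  status <- geno$samples$status
  keep <- vapply(seq_len(n_variants(geno)), function(j) {
    d <- geno$dosages[, j]
    p_all <- hwe_from_dosage(d)
    p_ctr <- hwe_from_dosage(d[status == 0L])
    p_all >= th$hwe_p_min_all && p_ctr >= th$hwe_p_min_controls
  }, logical(1))
  report[[4]] <- qc_log_entry("hwe", "variant", sum(!keep), sum(keep))
  if (!any(keep)) stop("no variants survive the HWE filter")
  geno <- subset_geno(geno, variants = which(keep))
  # 5. differential missingness
  status <- geno$samples$status
  n_ca <- sum(status == 1L)
  n_co <- sum(status == 0L)
  miss <- is.na(geno$dosages)
  m_ca <- colSums(miss[status == 1L, , drop = FALSE])
  m_co <- colSums(miss[status == 0L, , drop = FALSE])
  keep <- vapply(seq_len(n_variants(geno)), function(j) {
    differential_missingness_test(m_ca[j], n_ca - m_ca[j],
                                  m_co[j], n_co - m_co[j]) >=
      th$diff_missing_p_max
  }, logical(1))
  report[[5]] <- qc_log_entry("differential_missingness", "variant",
                              sum(!keep), sum(keep))
  if (!any(keep)) stop("no variants survive the differential-missingness filter")
  geno <- subset_geno(geno, variants = which(keep))
  # 6. relatedness
  drop <- related_samples_to_drop(geno, th$kinship_max)
  keep <- !(seq_len(n_samples(geno)) %in% drop)
  report[[6]] <- qc_log_entry("kinship", "sample", sum(!keep), sum(keep))
  if (!any(keep)) stop("no samples survive the kinship filter")
  geno <- subset_geno(geno, samples = which(keep))
  list(geno = geno, report = do.call(rbind, report))
}

hwe_from_dosage <- function(d) {
  d <- d[!is.na(d)]
  if (length(d) == 0L) return(1.0)
  hwe_exact_test(sum(d == 0L), sum(d == 1L), sum(d == 2L))
}

# Greedy removal: scan pairs in sample order; whenever a pair with
# kinship >= threshold (and both members still retained) is found, drop
# the member with the lower call rate (tie -> the later sample).
related_samples_to_drop <- function(geno, kinship_max) {
  n <- n_samples(geno)
  if (n < 2L) return(integer())
  cr <- sample_call_rate(geno)
  dropped <- logical(n)
  for (i in seq_len(n - 1L)) {
    if (dropped[i]) next
    for (j in seq(i + 1L, n)) {
      if (dropped[j]) next
      k <- kinship_estimate(geno$dosages[i, ], geno$dosages[j, ])
      if (!k$reliable) next
      if (k$kinship >= kinship_max) {
        victim <- if (cr[j] < cr[i]) j else if (cr[i] < cr[j]) i else j
        dropped[victim] <- TRUE
        if (victim == i) break
      }
    }
  }
  which(dropped)
}

#' Post-imputation quality control
#'
#' Removes variants with imputation info score below `imp_info_min` or
#' call rate below `imp_variant_call_min`, then samples with call rate
#' below `imp_sample_call_min`.  No allele-frequency restriction is
#' applied at this stage: rare variants are the point of the downstream
#' analysis.
#'
#' @inheritParams apply_scaffold_qc
#' @return List with `geno` and `report` as in [apply_scaffold_qc()].
#' @export
apply_imputation_qc <- function(geno, thresholds = qc_thresholds()) {
  stopifnot(inherits(geno, "genotype_matrix"))
  th <- thresholds
  if (!"info_score" %in% names(geno$variants) ||
      any(is.na(geno$variants$info_score))) {
    stop("imputation QC requires an info_score for every variant")
  }
  report <- list()
  keep <- geno$variants$info_score >= th$imp_info_min &
    variant_call_rate(geno) >= th$imp_variant_call_min
  report[[1]] <- qc_log_entry("imputation_variant", "variant",
                              sum(!keep), sum(keep))
  if (!any(keep)) stop("no variants survive the imputation variant filter")
  geno <- subset_geno(geno, variants = which(keep))
  keep <- sample_call_rate(geno) >= th$imp_sample_call_min
  report[[2]] <- qc_log_entry("imputation_sample", "sample",
                              sum(!keep), sum(keep))
  if (!any(keep)) stop("no samples survive the imputation sample filter")
  geno <- subset_geno(geno, samples = which(keep))
  list(geno = geno, report = do.call(rbind, report))
}
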