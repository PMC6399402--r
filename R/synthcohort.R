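#' Specification of a synthetic case-control cohort
#'
#' Collects every knob of the cohort generator.  Defaults describe a
#' stratification-free European-like cohort at reduced scale with the
#' rare-skewed site frequency spectrum observed in dense imputation
#' experiments: roughly half of all polymorphic markers are rare
#' (MAF < 1%), and among those rare markers singletons, "very rare"
#' variants (MAF < 0.1%) and strict-sense rare variants
#' (0.1% <= MAF <= 1%) split approximately 14.5% / 51.8% / 33.7%.
#'
#' @param n_cases,n_controls Sample sizes (>= 1).
#' @param n_subpops Number of subpopulations.
#' @param fst Balding-Nichols divergence parameter in \[0, 1); scalar or one
#'   value per subpopulation.  `0` means no differentiation.
#' @param subpop_mixing Matrix with rows `case` and `control` giving the
#'   subpopulation proportions of each status group; each row sums to 1.
#'   Unequal rows induce stratification confounding.  Default: uniform.
#' @param n_genes Number of gene regions to simulate.
#' @param variants_per_gene Length-2 integer range; each gene draws its
#'   variant count uniformly from it.
#' @param sfs_weights Named numeric vector of target proportions for the
#'   categories `singleton`, `very_rare`, `rare_strict`, `common`; must sum
#'   to 1.
#' @param ld_block_size Number of consecutive variants forming one
#'   linkage-disequilibrium block (haplotypes correlated within a block,
#'   independent across blocks).
#' @param ld_rho Latent Gaussian correlation of haplotype alleles within a
#'   block, in \[0, 1).
#' @param missing_rate Per-genotype missing probability.
#' @param info_score_dist Length-2 interval in \[0, 1\] from which fabricated
#'   imputation info scores are drawn uniformly.
#' @param seed Integer seed; the generator is deterministic given the spec.
#'
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 1500, n_controls = 1500,
                        n_subpops = 1, fst = 0,
                        subpop_mixing = NULL,
                        n_genes = 50, variants_per_gene = c(5L, 30L),
                        sfs_weights = c(singleton = 0.074,
                                        very_rare = 0.2645,
                                        rare_strict = 0.1722,
                                        common = 0.4893),
                        ld_block_size = 5, ld_rho = 0.8,
                        missing_rate = 0.002,
                        info_score_dist = c(0.75, 1),
                        seed = 1L) {
  if (is.null(subpop_mixing)) {
    subpop_mixing <- matrix(1 / n_subpops, 2, n_subpops,
                            dimnames = list(c("case", "control"), NULL))
  }
  spec <- structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_subpops = as.integer(n_subpops),
    fst = rep_len(fst, n_subpops), subpop_mixing = subpop_mixing,
    n_genes = as.integer(n_genes),
    variants_per_gene = as.integer(variants_per_gene),
    sfs_weights = sfs_weights, ld_block_size = as.integer(ld_block_size),
    ld_rho = ld_rho, missing_rate = missing_rate,
    info_score_dist = info_score_dist, seed = as.integer(seed)),
    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (n_cases < 1L || n_controls < 1L) {
      stop("n_cases and n_controls must both be >= 1")
    }
    if (any(fst < 0) || any(fst >= 1)) stop("fst must lie in [0, 1)")
    cats <- c("singleton", "very_rare", "rare_strict", "common")
    if (!all(cats %in% names(sfs_weights))) {
      stop("sfs_weights must be named: ", paste(cats, collapse = ", "))
    }
    if (any(sfs_weights < 0) || abs(sum(sfs_weights) - 1) > 1e-8) {
      stop("sfs_weights must be nonnegative and sum to 1")
    }
    n2 <- 2 * (n_cases + n_controls)
    # very_rare needs an integer minor-allele count with 2 <= mac and
    # mac / 2N < 0.001; infeasible at small cohorts
    if (sfs_weights["very_rare"] > 0 && 0.001 * n2 <= 2) {
      stop("infeasible SFS: very_rare category (MAC >= 2, MAF < 0.1%) ",
           "cannot be realized with ", n_cases + n_controls,
           " samples; set its weight to 0 or enlarge the cohort")
    }
    # rare_strict needs an integer MAC >= 2 with 0.1% <= MAC/2N <= 1%
    if (sfs_weights["rare_strict"] > 0 && floor(0.01 * n2) < 2) {
      stop("infeasible SFS: rare_strict category cannot be realized with ",
           n_cases + n_controls, " samples")
    }
    if (length(variants_per_gene) != 2L || variants_per_gene[1] < 1L ||
        variants_per_gene[2] < variants_per_gene[1]) {
      stop("variants_per_gene must be an increasing length-2 range >= 1")
    }
    if (nrow(subpop_mixing) != 2L || ncol(subpop_mixing) != n_subpops ||
        any(abs(rowSums(subpop_mixing) - 1) > 1e-8)) {
      stop("subpop_mixing must be a 2 x n_subpops matrix with rows ",
           "(case, control) each summing to 1")
    }
    if (missing_rate < 0 || missing_rate >= 1) {
      stop("missing_rate must lie in [0, 1)")
    }
    if (length(info_score_dist) != 2L || any(info_score_dist < 0) ||
        any(info_score_dist > 1) ||
        info_score_dist[1] > info_score_dist[2]) {
      stop("info_score_dist must be an interval inside [0, 1]")
    }
    if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)")
    invisible(NULL)
  })
}

# Frequency bands (as MAF fractions) of each SFS category at cohort size n.
sfs_bands <- function(n) {
  n2 <- 2 * n
  list(singleton = c(0.5 / n2, 1.5 / n2),
       very_rare = c(1 / n2, 0.001),
       rare_strict = c(0.001, 0.01),
       common = c(0.01, 0.5))
}

# Inverse-frequency density on [lo, hi]: f = lo * (hi/lo)^U.
rfreq_inv <- function(k, lo, hi) lo * (hi / lo)^stats::runif(k)

# Realized minor-allele category of one dosage column (pre-missingness).
realized_category <- function(mac, n2) {
  maf <- mac / n2
  if (mac == 0L || mac == n2) "monomorphic"
  else if (mac == 1L || mac == n2 - 1L) "singleton"
  else if (maf < 0.001 || maf > 1 - 0.001) "very_rare"
  else if (maf <= 0.01 || maf >= 1 - 0.01) "rare_strict"
  else "common"
}

#' Simulate a stratified case-control cohort
#'
#' Draws ancestral allele frequencies from an inverse-frequency site
#' frequency spectrum truncated to the requested category bands, derives
#' per-subpopulation frequencies by the Balding-Nichols model
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, and generates haplotypes with
#' block-diagonal linkage disequilibrium through a latent Gaussian copula.
#' Singletons are realized as exactly one minor-allele copy; other
#' categories are enforced by redrawing a column (marginally, dropping its
#' block coupling) when binomial sampling throws its realized minor-allele
#' count out of the target band.  Case/control labels carry no genetic
#' signal here; confounding enters only through `subpop_mixing`.  Use
#' [spike_effects()] to generate phenotypes driven by gene burdens.
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `geno` ([genotype_matrix()]), `pheno`
#'   (`data.frame`: `sample_id`, `status`, `subpop`) and `regions`
#'   (`data.frame`: `gene_id`, `chrom`, `start`, `end`, 1-based inclusive).
#' @export
simulate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_cases + spec$n_controls
  n2 <- 2L * n
  status <- rep(c(1L, 0L), c(spec$n_cases, spec$n_controls))
  subpop <- integer(n)
  subpop[status == 1L] <- sample.int(spec$n_subpops, spec$n_cases,
                                     replace = TRUE,
                                     prob = spec$subpop_mixing["case", ])
  subpop[status == 0L] <- sample.int(spec$n_subpops, spec$n_controls,
                                     replace = TRUE,
                                     prob = spec$subpop_mixing["control", ])
  bands <- sfs_bands(n)
  m_range <- seq(spec$variants_per_gene[1], spec$variants_per_gene[2])
  m_per_gene <- if (length(m_range) == 1L) {
    rep(m_range, spec$n_genes)  # degenerate range: sample() would misfire
  } else {
    sample(m_range, spec$n_genes, replace = TRUE)
  }
  m_total <- sum(m_per_gene)
  category <- sample(names(spec$sfs_weights), m_total, replace = TRUE,
                     prob = spec$sfs_weights)
  p_anc <- numeric(m_total)
  for (cat in unique(category)) {
    idx <- which(category == cat)
    b <- bands[[cat]]
    p_anc[idx] <- rfreq_inv(length(idx), b[1], b[2])
  }
  # Per-subpop frequencies under Balding-Nichols divergence.
  p_sub <- matrix(rep(p_anc, each = spec$n_subpops), spec$n_subpops, m_total)
  for (s in seq_len(spec$n_subpops)) {
    f <- spec$fst[s]
    if (f > 0) {
      p_sub[s, ] <- stats::rbeta(m_total, p_anc * (1 - f) / f,
                                 (1 - p_anc) * (1 - f) / f)
    }
  }
  hap_sub <- rep(subpop, each = 2L)       # subpop of each of the 2N haplotypes
  sq <- sqrt(spec$ld_rho)
  sq1 <- sqrt(1 - spec$ld_rho)
  dos <- matrix(0L, n, m_total)
  j0 <- 0L
  for (g in seq_len(spec$n_genes)) {
    m <- m_per_gene[g]
    cols <- j0 + seq_len(m)
    blocks <- split(cols, ceiling(seq_len(m) / spec$ld_block_size))
    for (blk in blocks) {
      mb <- length(blk)
      thr <- stats::qnorm(pmin(pmax(t(p_sub[hap_sub, blk, drop = FALSE]),
                                    1e-12), 1 - 1e-12))  # mb x 2N
      z0 <- stats::rnorm(n2)
      z <- sq * matrix(z0, mb, n2, byrow = TRUE) +
        sq1 * matrix(stats::rnorm(mb * n2), mb, n2)
      hap <- z < thr                       # mb x 2N allele indicators
      d <- hap[, seq(1, n2, 2), drop = FALSE] +
        hap[, seq(2, n2, 2), drop = FALSE]
      dos[, blk] <- t(d)
    }
    j0 <- j0 + m
  }
  # Enforce SFS categories: singletons exactly, other bands by marginal
  # redraw (30 attempts, then keep the last draw).
  for (j in seq_len(m_total)) {
    if (category[j] == "singleton") {
      dos[, j] <- 0L
      carrier <- (sample.int(n2, 1L) + 1L) %/% 2L
      dos[carrier, j] <- 1L
    } else {
      tries <- 0L
      while (realized_category(marginal_mac(dos[, j], n2), n2) !=
             category[j] && tries < 30L) {
        hap <- stats::runif(n2) < p_sub[hap_sub, j]
        dos[, j] <- hap[seq(1, n2, 2)] + hap[seq(2, n2, 2)]
        tries <- tries + 1L
      }
    }
  }
  if (spec$missing_rate > 0) {
    dos[matrix(stats::runif(n * m_total) < spec$missing_rate,
               n, m_total)] <- NA_integer_
  }
  # Variant coordinates: genes laid head to tail on one chromosome.
  spacing <- 64L
  gap <- 10000L
  pos <- integer(m_total)
  regions <- data.frame(gene_id = sprintf("GENE%04d", seq_len(spec$n_genes)),
                        chrom = "1",
                        start = 0L, end = 0L, stringsAsFactors = FALSE)
  at <- 1L
  j0 <- 0L
  for (g in seq_len(spec$n_genes)) {
    m <- m_per_gene[g]
    pos[j0 + seq_len(m)] <- at + spacing * (seq_len(m) - 1L)
    regions$start[g] <- at
    regions$end[g] <- at + spacing * (m - 1L)
    at <- regions$end[g] + gap
    j0 <- j0 + m
  }
  variants <- data.frame(
    chrom = "1", pos = pos,
    id = sprintf("var%06d", seq_len(m_total)),
    ref = "A", alt = "G",
    info_score = stats::runif(m_total, spec$info_score_dist[1],
                              spec$info_score_dist[2]),
    gene_id = rep(regions$gene_id, m_per_gene),
    target_category = category,
    ancestral_freq = p_anc,
    stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sprintf("S%05d", seq_len(n)),
                        status = status, subpop = subpop,
                        stringsAsFactors = FALSE)
  geno <- genotype_matrix(dos, variants, samples)
  pheno <- samples
  list(geno = geno, pheno = pheno, regions = regions)
}

marginal_mac <- function(d, n2) {
  s <- sum(d)
  min(s, n2 - s)
}

#' Per-gene effect specification
#'
#' @param gene_id Gene identifier (must match a region).
#' @param beta Log-odds per minor allele of the gene's burden score;
#'   positive for risk (aggregate OR > 1), negative for protective
#'   (aggregate OR < 1).
#' @param direction Optional `"risk"`/`"protective"` label; must agree with
#'   `sign(beta)` if given.
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(gene_id, beta, direction = NULL) {
  implied <- if (beta >= 0) "risk" else "protective"
  if (!is.null(direction) && direction != implied) {
    stop("direction '", direction, "' inconsistent with sign(beta)")
  }
  structure(list(gene_id = gene_id, beta = beta, direction = implied),
            class = "effect_spec")
}

#' Spike gene-burden effects into a cohort
#'
#' Draws case/control status from the logistic model
#' `logit P(case) = alpha + sum_g beta_g * burden_g(i)` where `burden_g(i)`
#' is sample `i`'s minor-allele count over gene `g`'s variants.  The
#' intercept `alpha` is solved numerically so the marginal prevalence
#' matches `baseline_prevalence`.  When `n_cases`/`n_controls` are
#' requested the realized cases and controls are subsampled to those
#' counts.
#'
#' @param geno A [genotype_matrix()] (the sample pool).
#' @param regions Gene region `data.frame` (`gene_id`, `chrom`, `start`,
#'   `end`).
#' @param effects List of [effect_spec()] objects.
#' @param baseline_prevalence Target marginal case probability.
#' @param n_cases,n_controls Optional subsampled design sizes.
#' @param seed Integer seed.
#' @return A list: `pheno` (`data.frame` with `sample_id`, `status`,
#'   `subpop` for the retained samples) and `sample_idx` (their row indices
#'   in `geno`).
#' @export
spike_effects <- function(geno, regions, effects,
                          baseline_prevalence = 0.1,
                          n_cases = NULL, n_controls = NULL, seed = 1L) {
  stopifnot(inherits(geno, "genotype_matrix"))
  set.seed(as.integer(seed))
  eta <- numeric(n_samples(geno))
  assign <- assign_variants(regions, geno$variants)
  for (ef in effects) {
    if (!ef$gene_id %in% regions$gene_id) {
      stop("effect gene '", ef$gene_id, "' has no gene region")
    }
    idx <- assign[[ef$gene_id]]
    if (length(idx) == 0L) next
    eta <- eta + ef$beta *
      burden_score(geno$dosages[, idx, drop = FALSE])
  }
  alpha <- stats::uniroot(
    function(a) mean(stats::plogis(a + eta)) - baseline_prevalence,
    interval = c(-40, 40), tol = 1e-10)$root
  y <- stats::rbinom(length(eta), 1L, stats::plogis(alpha + eta))
  idx <- seq_along(y)
  if (!is.null(n_cases) || !is.null(n_controls)) {
    n_cases <- n_cases %||% sum(y == 1L)
    n_controls <- n_controls %||% sum(y == 0L)
    if (sum(y == 1L) < n_cases) {
      stop("only ", sum(y == 1L), " cases realized but ", n_cases,
           " requested; simulate a larger pool or raise the prevalence")
    }
    if (sum(y == 0L) < n_controls) {
      stop("only ", sum(y == 0L), " controls realized but ", n_controls,
           " requested; simulate a larger pool")
    }
    idx <- sort(c(sample(which(y == 1L), n_cases),
                  sample(which(y == 0L), n_controls)))
  }
  pheno <- data.frame(sample_id = geno$samples$sample_id[idx],
                      status = y[idx],
                      subpop = if ("subpop" %in% names(geno$samples)) {
                        geno$samples$subpop[idx]
                      } else NA_integer_,
                      stringsAsFactors = FALSE)
  list(pheno = pheno, sample_idx = idx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate an OMIM-style gene-disease annotation table
#'
#' Each gene receives annotations with probability `p_annotated`, boosted
#' to `p_annotated * causal_boost` for genes in `causal_genes`; an
#' annotated gene contributes between `diseases_per_gene[1]` and
#' `diseases_per_gene[2]` distinct (gene, disease) pairs.
#'
#' @param genes Character vector of gene ids (the universe).
#' @param p_annotated Baseline annotation probability.
#' @param causal_boost Multiplier applied to causal genes' annotation
#'   probability; `p_annotated * causal_boost` must not exceed 1.
#' @param causal_genes Subset of `genes` carrying boosted annotation.
#' @param diseases_per_gene Length-2 integer range of diseases per
#'   annotated gene.
#' @param n_diseases Size of the disease identifier pool.
#' @param seed Integer seed.
#' @return `data.frame` with columns `gene_id`, `disease_id`; rows unique.
#' @export
simulate_annotations <- function(genes, p_annotated = 0.3,
                                 causal_boost = 1,
                                 causal_genes = character(),
                                 diseases_per_gene = c(1L, 3L),
                                 n_diseases = NULL, seed = 1L) {
  p_causal <- p_annotated * causal_boost
  if (p_causal < 0 || p_causal > 1) {
    stop("p_annotated * causal_boost must lie in [0, 1]")
  }
  set.seed(as.integer(seed))
  n_diseases <- n_diseases %||% max(50L, 3L * length(genes))
  pool <- sprintf("D%05d", seq_len(n_diseases))
  p <- ifelse(genes %in% causal_genes, p_causal, p_annotated)
  hit <- stats::runif(length(genes)) < p
  out <- vector("list", sum(hit))
  k <- 0L
  for (i in which(hit)) {
    k <- k + 1L
    nd <- sample(seq(diseases_per_gene[1], diseases_per_gene[2]), 1L)
    out[[k]] <- data.frame(gene_id = genes[i],
                           disease_id = sample(pool, nd),
                           stringsAsFactors = FALSE)
  }
  if (k == 0L) {
    return(data.frame(gene_id = character(), disease_id = character(),
                      stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, out))
}
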