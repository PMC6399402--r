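test_that("variants map to genes by inclusive 1-based containment,
           sharing overlaps", {
  regions <- data.frame(gene_id = c("A", "B"), chrom = "1",
                        start = c(100L, 150L), end = c(200L, 300L))
  variants <- data.frame(chrom = "1",
                         pos = c(99L, 100L, 150L, 200L, 201L, 300L))
  asg <- assign_variants(regions, variants)
  expect_equal(asg$A, c(2L, 3L, 4L))     # boundaries included
  expect_equal(asg$B, c(3L, 4L, 5L, 6L)) # overlap shared with A
  # wrong chromosome: not assigned
  variants2 <- data.frame(chrom = "2", pos = 150L)
  expect_equal(length(assign_variants(regions, variants2)$A), 0L)
})

test_that("burden scores sum minor-allele dosages with missing as zero", {
  d <- rbind(c(1L, 2L, 0L),
             c(0L, NA, 1L),
             c(2L, 0L, 0L))
  expect_equal(burden_score(d), c(3, 1, 2))
  expect_equal(burden_score(matrix(0L, 4, 3)), rep(0, 4))
  # a column whose minor allele is the reference is flipped before summing
  flip <- matrix(c(2L, 2L, 2L, 1L), ncol = 1)
  expect_equal(burden_score(flip), c(0, 0, 0, 1))
})

test_that("burden test equals a hand-rolled maximum-likelihood oracle and
           reports Wald intervals", {
  set.seed(61)
  n <- 400
  x <- rbinom(n, 2, 0.15)
  y <- rbinom(n, 1, plogis(-0.5 + 0.4 * x))
  bt <- burden_test(x, y)
  expect_equal(bt$beta, oracle_logistic_slope(x, y), tolerance = 1e-6)
  expect_equal(bt$or_, exp(bt$beta))
  expect_equal(bt$ci95_lo, exp(bt$beta - qnorm(0.975) * bt$se))
  expect_true(bt$ci95_lo < bt$or_ && bt$or_ < bt$ci95_hi)
  expect_false(bt$firth)
  # OR direction matches the case-control mean difference in scores
  expect_equal(bt$or_ > 1, mean(x[y == 1]) > mean(x[y == 0]))
  # constant scores are untestable, not an error
  expect_true(burden_test(rep(2, n), y)$untestable)
})

test_that("complete separation falls back to penalized likelihood with a
           finite interval", {
  y <- rep(c(0L, 1L), each = 30)
  x <- c(rep(0, 30), rep(1, 30))  # perfectly separates
  bt <- burden_test(x, y)
  expect_true(bt$firth)
  expect_true(is.finite(bt$beta) && is.finite(bt$se))
  expect_true(bt$p_raw > 0 && bt$p_raw <= 1)
  expect_true(bt$or_ > 1)
})

test_that("single-variant SKAT collapses to the 1-df score test", {
  set.seed(62)
  n <- 250
  g <- rbinom(n, 2, 0.12)
  y <- rbinom(n, 1, 0.4)
  nm <- fit_null_model(y)
  sk <- skat_test(matrix(g, ncol = 1), nm, weights = 1)
  mu <- mean(y)
  U <- sum(g * (y - mu))
  V <- mu * (1 - mu) * sum((g - mean(g))^2)
  expect_equal(sk$p_raw, pchisq(U^2 / V, 1, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("SKAT is invariant to variant order and allele-label flips", {
  set.seed(63)
  n <- 300
  G <- sapply(runif(6, 0.02, 0.2), function(f) rbinom(n, 2, f))
  y <- rbinom(n, 1, 0.5)
  nm <- fit_null_model(y)
  p0 <- skat_test(G, nm)$p_raw
  expect_equal(skat_test(G[, sample(6)], nm)$p_raw, p0, tolerance = 1e-8)
  Gf <- G
  Gf[, 2] <- 2L - Gf[, 2]
  expect_equal(skat_test(Gf, nm)$p_raw, p0, tolerance = 1e-8)
})

test_that("the three SKAT p-value routes agree within their approximation
           error", {
  set.seed(64)
  n <- 400
  G <- sapply(runif(8, 0.01, 0.1), function(f) rbinom(n, 2, f))
  y <- rbinom(n, 1, 0.5)
  nm <- fit_null_model(y)
  p_liu <- skat_test(G, nm, p_method = "liu")$p_raw
  p_int <- skat_test(G, nm, p_method = "integration")$p_raw
  p_perm <- skat_test(G, nm, p_method = "permutation",
                      n_resample = 20000L)$p_raw
  expect_lt(abs(p_liu - p_int), 0.01)
  # the asymptotic mixture deviates from the exact finite-sample null by
  # a bounded amount at this scale (documented small-sample behavior)
  expect_lt(abs(p_int - p_perm), 0.05)
})

test_that("SKAT with covariates matches an explicit projected quadratic
           form", {
  set.seed(65)
  n <- 300
  z <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.5 * z))
  G <- sapply(runif(5, 0.05, 0.2), function(f) rbinom(n, 2, f))
  nm <- fit_null_model(y, covariates = cbind(z))
  sk <- skat_test(G, nm, weights = rep(1, 5))
  expect_equal(sk$q_stat, sum(drop(crossprod(G, y - nm$mu))^2),
               tolerance = 1e-9)
  expect_true(all(sk$eigenvalues > 0))
  expect_lte(length(sk$eigenvalues), 5)
})

test_that("run_all_genes ranks a spiked gene first and is deterministic", {
  sim <- simulate_cohort(cohort_spec(
    n_cases = 1000, n_controls = 1000, n_genes = 8,
    variants_per_gene = c(15, 25),
    sfs_weights = c(singleton = 0.1, very_rare = 0, rare_strict = 0.6,
                    common = 0.3),
    missing_rate = 0, seed = 66))
  sp <- spike_effects(sim$geno, sim$regions,
                      list(effect_spec("GENE0004", log(3))),
                      baseline_prevalence = 0.4, n_cases = 700,
                      n_controls = 700, seed = 67)
  g <- subset_geno(sim$geno, samples = sp$sample_idx)
  g$samples$status <- sp$pheno$status
  res <- suppressMessages(run_all_genes(g, sim$regions))
  expect_equal(res$gene[which.min(res$P_burden_raw)], "GENE0004")
  expect_equal(res$gene[which.min(res$P_SKAT_raw)], "GENE0004")
  expect_true(all(c("P_burden_gc", "P_SKAT_gc") %in% names(res)))
  expect_equal(res$NMUT, vapply(res$gene, function(gg) {
    idx <- assign_variants(sim$regions, g$variants)[[gg]]
    st <- variant_stats_table(g)
    sum(st$mac[idx] >= 1 & st$maf[idx] < 0.01)
  }, numeric(1), USE.NAMES = FALSE))
  res2 <- suppressMessages(run_all_genes(g, sim$regions))
  expect_identical(res, res2)
  # empty region set exits cleanly
  empty <- run_all_genes(g, sim$regions[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("per-status minor-allele sums reconcile with direct counting", {
  sim <- null_cohort(n_cases = 200, n_controls = 200, n_genes = 3,
                     seed = 68)
  g <- sim$geno
  res <- suppressMessages(run_all_genes(g, sim$regions, gc = FALSE))
  st <- variant_stats_table(g)
  for (i in seq_len(nrow(res))) {
    idx <- assign_variants(sim$regions, g$variants)[[res$gene[i]]]
    idx <- idx[st$mac[idx] >= 1 & st$maf[idx] < 0.01]
    sc <- burden_score(g$dosages[, idx, drop = FALSE])
    expect_equal(res$nMAF.aff[i], sum(sc[g$samples$status == 1]))
    expect_equal(res$nMAF.ctr[i], sum(sc[g$samples$status == 0]))
  }
})
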