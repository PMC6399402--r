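test_that("genomic lambda matches its reference points", {
  expect_equal(genomic_lambda(rep(0.5, 11))$lambda, 1.0)
  set.seed(41)
  p <- runif(50000)
  expect_lt(abs(genomic_lambda(p)$lambda - 1), 0.03)
  # doubling every chi-square statistic doubles lambda
  chi <- qchisq(p, 1, lower.tail = FALSE)
  p2 <- pchisq(2 * chi, 1, lower.tail = FALSE)
  expect_equal(genomic_lambda(p2)$lambda, 2 * genomic_lambda(p)$lambda,
               tolerance = 1e-10)
  expect_error(genomic_lambda(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(genomic_lambda(c(0.5, 1.2)), "\\(0, 1\\]")
  expect_error(genomic_lambda(numeric()), "no p-values")
})

test_that("genomic-control correction deflates, preserves order and
           inverts cleanly", {
  p <- c(1e-6, 1e-3, 0.05, 0.3, 0.9, 1)
  expect_equal(gc_correct(p, 1), p)
  # chi-square oracle at p = 0.05, lambda = 2
  expect_equal(gc_correct(0.05, 2),
               pchisq(qchisq(0.05, 1, lower.tail = FALSE) / 2, 1,
                      lower.tail = FALSE))
  corrected <- gc_correct(p, 1.7)
  expect_false(is.unsorted(corrected))
  expect_true(all(corrected[p < 1] > p[p < 1]))
  # lambda then 1/lambda recovers the input
  expect_equal(gc_correct(gc_correct(p, 1.7), 1 / 1.7), p,
               tolerance = 1e-12)
  expect_error(gc_correct(p, 0), "lambda")
})

test_that("PCA separates simulated subpopulations and is equivariant", {
  sim <- simulate_cohort(cohort_spec(
    n_cases = 150, n_controls = 150, n_subpops = 2, fst = 0.1,
    subpop_mixing = matrix(0.5, 2, 2,
                           dimnames = list(c("case", "control"), NULL)),
    n_genes = 30, variants_per_gene = c(10, 20),
    sfs_weights = c(singleton = 0, very_rare = 0, rare_strict = 0.2,
                    common = 0.8),
    missing_rate = 0, seed = 44))
  st <- variant_stats_table(sim$geno)
  common <- which(st$category == "common")
  pcs <- pca_genotypes(sim$geno, variant_idx = common, k = 5)
  r <- cor(pcs$scores[, 1], as.numeric(sim$geno$samples$subpop == 2))
  expect_gt(abs(r), 0.9)
  expect_equal(ncol(pcs$scores), 5)
  expect_true(all(diff(pcs$var_explained) < 1e-12))
  # permuting samples permutes scores identically (incl. the sign fix)
  perm <- sample(n_samples(sim$geno))
  pcs_p <- pca_genotypes(subset_geno(sim$geno, samples = perm),
                         variant_idx = common, k = 5)
  expect_equal(unname(pcs_p$scores), unname(pcs$scores[perm, ]),
               tolerance = 1e-8)
})

test_that("without population structure, PC1 carries no case-control
           signal beyond chance", {
  nonsig <- vapply(1:20, function(i) {
    sim <- simulate_cohort(cohort_spec(
      n_cases = 60, n_controls = 60, n_subpops = 1, fst = 0,
      n_genes = 15, variants_per_gene = c(10, 20),
      sfs_weights = c(singleton = 0, very_rare = 0, rare_strict = 0.1,
                      common = 0.9),
      missing_rate = 0, seed = 400 + i))
    pcs <- suppressMessages(pca_genotypes(sim$geno, k = 1))
    cor.test(pcs$scores[, 1],
             sim$geno$samples$status)$p.value > 0.05
  }, logical(1))
  expect_gte(mean(nonsig), 0.85)
})

test_that("duplicated samples coincide on the principal components", {
  set.seed(45)
  d <- sapply(runif(60, 0.1, 0.4), function(f) rbinom(40, 2, f))
  d[2, ] <- d[1, ]
  g <- toy_geno(d)
  pcs <- pca_genotypes(g, k = 3)
  expect_equal(pcs$scores[1, ], pcs$scores[2, ], tolerance = 1e-10)
})

test_that("informative-marker selection ranks fixed differences first and
           respects pairwise independence", {
  set.seed(46)
  n <- 100
  grp <- rep(c("a", "b"), each = n / 2)
  d <- sapply(runif(40, 0.3, 0.5), function(f) rbinom(n, 2, f))
  d[, 7] <- ifelse(grp == "a", 0L, 2L)  # fixed difference
  g <- toy_geno(d)
  sel <- select_informative_markers(g, grp, k = 10)
  expect_true(7 %in% sel)
  # selected markers are pairwise independent at the threshold
  for (i in seq_along(sel)) {
    for (j in seq_len(i - 1L)) {
      expect_lt(pairwise_r2(d[, sel[i]], d[, sel[j]]), 0.1)
    }
  }
  expect_warning(select_informative_markers(g, grp, k = 200),
                 "acceptable")
  expect_error(select_informative_markers(g, rep("a", n), k = 5),
               "two groups")
})
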