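test_that("cohort generation is deterministic and honors its invariants", {
  spec <- cohort_spec(n_cases = 400, n_controls = 400, n_genes = 8,
                      variants_per_gene = c(5, 12),
                      sfs_weights = c(singleton = 0.15, very_rare = 0,
                                      rare_strict = 0.5, common = 0.35),
                      missing_rate = 0.01, seed = 42)
  sim1 <- simulate_cohort(spec)
  sim2 <- simulate_cohort(spec)
  expect_identical(sim1$geno$dosages, sim2$geno$dosages)
  expect_identical(sim1$pheno, sim2$pheno)
  expect_equal(n_samples(sim1$geno), 800)
  vals <- sim1$geno$dosages[!is.na(sim1$geno$dosages)]
  expect_true(all(vals %in% 0:2))
  expect_true(all(sim1$geno$variants$info_score >= 0.75 &
                    sim1$geno$variants$info_score <= 1))
  expect_true(all(sim1$geno$variants$pos >= 1))
  # regions contain their variants
  asg <- assign_variants(sim1$regions, sim1$geno$variants)
  expect_equal(sort(unlist(asg, use.names = FALSE)),
               seq_len(n_variants(sim1$geno)))
})

test_that("singletons are realized as exactly one minor-allele copy", {
  sim <- null_cohort(n_genes = 20, vpg = c(10, 20), seed = 7,
                     weights = c(singleton = 0.5, very_rare = 0,
                                 rare_strict = 0.3, common = 0.2))
  st <- variant_stats_table(sim$geno)
  is_singleton <- sim$geno$variants$target_category == "singleton"
  expect_gt(sum(is_singleton), 50)
  expect_true(all(st$mac[is_singleton] == 1L))
})

test_that("without structure, realized MAF stays within binomial error of
           the drawn ancestral frequency", {
  sim <- simulate_cohort(cohort_spec(
    n_cases = 500, n_controls = 500, n_subpops = 1, fst = 0,
    n_genes = 60, variants_per_gene = c(18, 25), ld_rho = 0,
    sfs_weights = c(singleton = 0, very_rare = 0, rare_strict = 0.5,
                    common = 0.5),
    missing_rate = 0, seed = 11))
  expect_gt(n_variants(sim$geno), 1000)
  f_target <- sim$geno$variants$ancestral_freq
  f_real <- colMeans(sim$geno$dosages) / 2
  se <- sqrt(f_target * (1 - f_target) / (2 * n_samples(sim$geno)))
  # category enforcement truncates a few draws; almost all variants must
  # sit inside a 5-SE binomial envelope
  expect_gt(mean(abs(f_real - f_target) <= 5 * se), 0.97)
  expect_lt(abs(mean(f_real - f_target)), 0.001)
})

test_that("realized SFS category proportions match the requested weights", {
  sim <- simulate_cohort(cohort_spec(
    n_cases = 1200, n_controls = 1200, n_genes = 80,
    variants_per_gene = c(12, 28),
    sfs_weights = c(singleton = 0.145, very_rare = 0.518,
                    rare_strict = 0.337, common = 0),
    missing_rate = 0, seed = 13))
  st <- variant_stats_table(sim$geno)
  prop <- table(factor(st$category, levels = c("singleton", "very_rare",
                                               "rare_strict"))) / nrow(st)
  expect_lt(abs(prop[["singleton"]] - 0.145), 0.03)
  expect_lt(abs(prop[["very_rare"]] - 0.518), 0.03)
  expect_lt(abs(prop[["rare_strict"]] - 0.337), 0.03)
})

test_that("null spike keeps the baseline prevalence and spiked effects
           recover their direction", {
  sim <- simulate_cohort(cohort_spec(
    n_cases = 2000, n_controls = 2000, n_genes = 3,
    variants_per_gene = c(20, 20),
    sfs_weights = c(singleton = 0, very_rare = 0, rare_strict = 1,
                    common = 0),
    missing_rate = 0, seed = 3))
  # beta = 0: realized prevalence within binomial error of baseline
  sp0 <- spike_effects(sim$geno, sim$regions, list(),
                       baseline_prevalence = 0.25, seed = 5)
  n <- nrow(sp0$pheno)
  expect_lt(abs(mean(sp0$pheno$status) - 0.25),
            3 * sqrt(0.25 * 0.75 / n))
  # beta = log(2): burden-test CI covers OR 2
  sp <- spike_effects(sim$geno, sim$regions,
                      list(effect_spec("GENE0001", log(2))),
                      baseline_prevalence = 0.3,
                      n_cases = 900, n_controls = 900, seed = 6)
  g <- subset_geno(sim$geno, samples = sp$sample_idx)
  idx <- assign_variants(sim$regions, g$variants)[["GENE0001"]]
  bt <- burden_test(burden_score(g$dosages[, idx]), sp$pheno$status)
  expect_true(bt$ci95_lo < 2 && 2 < bt$ci95_hi)
  expect_gt(bt$or_, 1)
  # protective effect: recovered OR < 1
  spp <- spike_effects(sim$geno, sim$regions,
                       list(effect_spec("GENE0002", -log(2))),
                       baseline_prevalence = 0.3,
                       n_cases = 900, n_controls = 900, seed = 7)
  gp <- subset_geno(sim$geno, samples = spp$sample_idx)
  idxp <- assign_variants(sim$regions, gp$variants)[["GENE0002"]]
  btp <- burden_test(burden_score(gp$dosages[, idxp]), spp$pheno$status)
  expect_lt(btp$or_, 1)
})

test_that("spike_effects refuses designs larger than the realized pool", {
  sim <- null_cohort(n_cases = 100, n_controls = 100, n_genes = 2, seed = 9)
  expect_error(
    spike_effects(sim$geno, sim$regions, list(),
                  baseline_prevalence = 0.05, n_cases = 150,
                  n_controls = 10, seed = 1),
    "larger pool|cases realized")
})

test_that("effect_spec enforces direction/sign consistency", {
  expect_equal(effect_spec("G1", log(2))$direction, "risk")
  expect_equal(effect_spec("G1", -0.5)$direction, "protective")
  expect_error(effect_spec("G1", 0.5, direction = "protective"),
               "inconsistent")
})

test_that("simulate_annotations honors probabilities and degenerate
           settings", {
  genes <- sprintf("G%04d", 1:1000)
  expect_equal(nrow(simulate_annotations(genes, p_annotated = 0, seed = 1)),
               0L)
  tab <- simulate_annotations(genes, p_annotated = 1,
                              diseases_per_gene = c(1, 1), seed = 2)
  expect_setequal(unique(tab$gene_id), genes)
  expect_equal(anyDuplicated(tab), 0L)
  expect_error(simulate_annotations(genes, p_annotated = 0.5,
                                    causal_boost = 3, seed = 3),
               "\\[0, 1\\]")
  causal <- genes[1:200]
  tab2 <- simulate_annotations(genes, p_annotated = 0.2, causal_boost = 3,
                               causal_genes = causal, seed = 4)
  rate_causal <- mean(causal %in% tab2$gene_id)
  rate_rest <- mean(setdiff(genes, causal) %in% tab2$gene_id)
  expect_gt(rate_causal, rate_rest + 0.2)
})

test_that("invalid cohort specifications are rejected with clear errors", {
  expect_error(cohort_spec(fst = 1), "fst")
  expect_error(cohort_spec(sfs_weights = c(singleton = 0.5,
                                           very_rare = 0.2,
                                           rare_strict = 0.2,
                                           common = 0.2)),
               "sum to 1")
  # very_rare band empty at small cohorts (MAC >= 2 and MAF < 0.1%)
  expect_error(cohort_spec(n_cases = 150, n_controls = 150,
                           sfs_weights = c(singleton = 0.1,
                                           very_rare = 0.3,
                                           rare_strict = 0.3,
                                           common = 0.3)),
               "infeasible SFS")
  expect_error(cohort_spec(n_subpops = 2,
                           subpop_mixing = matrix(c(0.6, 0.6, 0.5, 0.5),
                                                  2, 2)),
               "subpop_mixing")
  expect_error(cohort_spec(missing_rate = 1), "missing_rate")
})
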