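test_that("HWE exact test matches its closed cases and the enumeration
           oracle", {
  expect_equal(hwe_exact_test(10, 0, 0), 1.0)
  expect_equal(hwe_exact_test(25, 50, 25), 1.0)
  # frozen from the enumeration oracle over n_Aa in {0, 2, ..., 10}
  expect_equal(oracle_hwe(5, 0, 5), 0.00136396107, tolerance = 1e-7)
  expect_equal(hwe_exact_test(5, 0, 5), oracle_hwe(5, 0, 5),
               tolerance = 1e-12)
  for (tab in list(c(3, 4, 3), c(8, 1, 1), c(0, 10, 0), c(1, 2, 7))) {
    expect_equal(hwe_exact_test(tab[1], tab[2], tab[3]),
                 oracle_hwe(tab[1], tab[2], tab[3]), tolerance = 1e-12)
  }
  expect_error(hwe_exact_test(0, 0, 0), "zero")
  expect_error(hwe_exact_test(-1, 2, 3), "nonnegative")
})

test_that("differential-missingness test picks the right branch and
           boundary behavior", {
  # no missing data at all: p = 1
  expect_equal(differential_missingness_test(0, 100, 0, 100), 1.0)
  # equal missingness at large n: clearly nonsignificant
  expect_gt(differential_missingness_test(50, 950, 50, 950), 0.5)
  # grossly differential: removed at the 1e-5 cutoff
  expect_lt(differential_missingness_test(50, 950, 0, 1000), 1e-5)
  # expected cell < 5 routes to Fisher; equals fisher.test directly
  tab <- matrix(c(3, 97, 0, 100), 2, 2)
  expect_equal(differential_missingness_test(3, 97, 0, 100),
               stats::fisher.test(tab)$p.value)
  # all cells comfortable: equals 1-df chi-square without correction
  tab2 <- matrix(c(30, 70, 50, 50), 2, 2)
  expect_equal(differential_missingness_test(30, 70, 50, 50),
               stats::chisq.test(tab2, correct = FALSE)$p.value)
  expect_error(differential_missingness_test(0, 0, 0, 0), "zero")
})

test_that("kinship estimator recovers duplicates and unrelated pairs", {
  set.seed(5)
  d <- rbinom(10000, 2, 0.3)
  dup <- kinship_estimate(d, d)
  expect_equal(dup$kinship, 0.5)
  e <- rbinom(10000, 2, 0.3)
  unrel <- kinship_estimate(d, e)
  expect_lt(abs(unrel$kinship), 0.02)
  short <- kinship_estimate(d[1:50], e[1:50])
  expect_false(short$reliable)
})

test_that("the per-sample call-rate threshold is inclusive at 90%", {
  set.seed(7)
  n <- 100  # large enough that single NAs keep variant call rates >= 98%
  m <- 60
  d <- sapply(runif(m, 0.2, 0.4), function(f) rbinom(n, 2, f))
  d[1, 1:7] <- NA  # call rate 53/60 = 0.883: removed
  d[2, 1:6] <- NA  # call rate 54/60 = 0.900: kept (inclusive)
  g <- toy_geno(d, status = rep(c(1L, 0L), length.out = n))
  # only the call-rate filter may act here, so verify nothing else does
  out <- apply_scaffold_qc(g)
  expect_false("s1" %in% out$geno$samples$sample_id)
  expect_true("s2" %in% out$geno$samples$sample_id)
  expect_equal(n_variants(out$geno), m)
})

test_that("scaffold QC applies inclusive thresholds in the documented
           order and reconciles its report", {
  set.seed(8)
  n <- 120
  m <- 60
  d <- sapply(runif(m, 0.1, 0.4), function(f) rbinom(n, 2, f))
  # variant 5: MAF below 1% -> removed at the scaffold stage
  d[, 5] <- 0L
  d[3, 5] <- 1L  # MAC 1 of 240 chromosomes: MAF ~0.4%
  # variant 6: gross HWE violation (opposite homozygotes, no hets)
  d[, 6] <- rep(c(0L, 2L), length.out = n)
  # sample 1: call rate 0.883 -> removed; sample 2 well clear of 90%
  d[1, 10:(9 + ceiling(0.11 * m))] <- NA
  d[2, 10:11] <- NA
  status <- rep(c(1L, 0L), length.out = n)
  g <- toy_geno(d, status = status)
  out <- apply_scaffold_qc(g)
  expect_false("s1" %in% out$geno$samples$sample_id)
  expect_true("s2" %in% out$geno$samples$sample_id)
  expect_false("v5" %in% out$geno$variants$id)
  expect_false("v6" %in% out$geno$variants$id)
  # report reconciliation: each stage starts from the previous stage's
  # retained count of its own type
  rep <- out$report
  expected_in <- list(sample = n, variant = m)
  for (i in seq_len(nrow(rep))) {
    ty <- rep$type[i]
    expect_equal(rep$n_removed[i] + rep$n_retained[i], expected_in[[ty]])
    expected_in[[ty]] <- rep$n_retained[i]
  }
  expect_equal(rep$n_retained[nrow(rep)], n_samples(out$geno))
  # idempotence: re-running QC on its own output removes nothing
  out2 <- apply_scaffold_qc(out$geno)
  expect_equal(out2$report$n_removed, rep(0L, nrow(out2$report)))
  expect_identical(out2$geno$dosages, out$geno$dosages)
})

test_that("related samples lose the lower-call-rate member at the 0.055
           threshold", {
  set.seed(10)
  n <- 30
  m <- 400
  d <- sapply(runif(m, 0.2, 0.45), function(f) rbinom(n, 2, f))
  d[2, ] <- d[1, ]          # duplicate pair (kinship 0.5)
  d[2, 1:20] <- NA          # member 2 has the lower call rate
  g <- toy_geno(d, status = rep(c(1L, 0L), length.out = n))
  out <- apply_scaffold_qc(g)
  expect_true("s1" %in% out$geno$samples$sample_id)
  expect_false("s2" %in% out$geno$samples$sample_id)
})

test_that("imputation QC keeps boundary info scores and never filters on
           frequency", {
  set.seed(12)
  n <- 200
  d <- sapply(rep(0.3, 5), function(f) rbinom(n, 2, f))
  d[, 3] <- 0L
  d[1, 3] <- 1L  # MAF 0.25%: must survive (no frequency restriction)
  info <- c(0.74, 0.75, 0.9, 1, 0.8)
  g <- toy_geno(d, info_score = info)
  out <- apply_imputation_qc(g)
  expect_false("v1" %in% out$geno$variants$id)  # info 0.74 < 0.75
  expect_true("v2" %in% out$geno$variants$id)   # boundary kept
  expect_true("v3" %in% out$geno$variants$id)   # rare but well imputed
  # clean input: identity
  g2 <- toy_geno(d, info_score = rep(1, 5))
  out2 <- apply_imputation_qc(g2)
  expect_identical(out2$geno$dosages, g2$dosages)
  expect_equal(sum(out2$report$n_removed), 0L)
  # missing info scores refuse to run
  g3 <- toy_geno(d)
  expect_error(apply_imputation_qc(g3), "info_score")
})
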