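# Independent oracles used to validate the package's statistical
# primitives.  Each one is deliberately implemented from first principles
# (plain factorials, direct formulas, brute-force enumeration) and shares
# no code with the implementation under test.

# Exact Hardy-Weinberg p-value by explicit enumeration of heterozygote
# configurations; probabilities from direct factorial products (small n).
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  r <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (r == 0) return(1)
  hs <- seq(r %% 2, min(r, 2 * n - r), by = 2)
  pr <- vapply(hs, function(h) {
    nmin <- (r - h) / 2
    nmaj <- n - h - nmin
    factorial(n) / (factorial(nmin) * factorial(h) * factorial(nmaj)) * 2^h
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hs)]
  sum(pr[pr <= obs * (1 + 1e-9)])
}

# Direct-formula squared Pearson correlation over jointly called samples.
oracle_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]
  b <- b[ok]
  sxy <- sum((a - mean(a)) * (b - mean(b)))
  sxx <- sum((a - mean(a))^2)
  syy <- sum((b - mean(b))^2)
  (sxy / sqrt(sxx * syy))^2
}

# Maximum-likelihood logistic fit of y ~ 1 + x by hand-rolled
# Newton-Raphson (no glm), returning the slope.
oracle_logistic_slope <- function(x, y, tol = 1e-12, max_iter = 100) {
  b <- c(0, 0)
  X <- cbind(1, x)
  for (i in seq_len(max_iter)) {
    mu <- 1 / (1 + exp(-drop(X %*% b)))
    grad <- drop(crossprod(X, y - mu))
    hess <- crossprod(X * (mu * (1 - mu)), X)
    step <- solve(hess, grad)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  unname(b[2])
}

# Residual-permutation reference distribution for the SKAT Q statistic,
# vectorized over B draws; returns the upper-tail probability of q.
oracle_skat_perm <- function(G, y, weights, q, B = 100000L) {
  r <- y - mean(y)
  n <- length(r)
  WG <- weights * t(G)
  count <- 0L
  done <- 0L
  while (done < B) {
    b <- min(20000L, B - done)
    P <- vapply(seq_len(b), function(i) r[sample.int(n)], numeric(n))
    count <- count + sum(colSums((WG %*% P)^2) >= q)
    done <- done + b
  }
  count / B
}

# Small deterministic genotype matrix for structural tests.
toy_geno <- function(dosages, status = NULL, pos = NULL,
                     info_score = NULL) {
  d <- as.matrix(dosages)
  m <- ncol(d)
  n <- nrow(d)
  v <- data.frame(chrom = "1",
                  pos = if (is.null(pos)) seq_len(m) * 10L else pos,
                  id = paste0("v", seq_len(m)), ref = "A", alt = "G",
                  stringsAsFactors = FALSE)
  if (!is.null(info_score)) v$info_score <- info_score
  s <- data.frame(sample_id = paste0("s", seq_len(n)),
                  stringsAsFactors = FALSE)
  if (!is.null(status)) s$status <- status
  genotype_matrix(d, v, s)
}

# Null single-population cohort at modest scale, reused across tests.
null_cohort <- function(n_cases = 300, n_controls = 300, n_genes = 10,
                        vpg = c(5, 15), seed = 1,
                        weights = c(singleton = 0.1, very_rare = 0,
                                    rare_strict = 0.55, common = 0.35),
                        missing_rate = 0) {
  simulate_cohort(cohort_spec(
    n_cases = n_cases, n_controls = n_controls, n_genes = n_genes,
    variants_per_gene = vpg, sfs_weights = weights,
    missing_rate = missing_rate, seed = seed))
}
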