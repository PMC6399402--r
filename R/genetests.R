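#' Assign variants to gene regions
#'
#' A variant belongs to every gene whose 1-based inclusive `[start, end]`
#' interval contains its position on the same chromosome (overlapping
#' genes share variants).  Imputation-context buffers around genes are a
#' separate concern and never enter the test set.
#'
#' @param regions Gene-region `data.frame` (`gene_id`, `chrom`, `start`,
#'   `end`).
#' @param variants Variant `data.frame` (`chrom`, `pos`).
#' @return Named list (by `gene_id`) of integer variant indices.
#' @export
assign_variants <- function(regions, variants) {
  out <- vector("list", nrow(regions))
  names(out) <- regions$gene_id
  for (g in seq_len(nrow(regions))) {
    out[[g]] <- which(variants$chrom == regions$chrom[g] &
                        variants$pos >= regions$start[g] &
                        variants$pos <= regions$end[g])
  }
  out
}

#' Per-sample rare-variant burden score
#'
#' Sum of minor-allele dosages over a gene's variants; a missing dosage
#' contributes 0.  Columns whose minor allele is the reference allele are
#' flipped (`2 - dosage`) before summing.
#'
#' @param dosage_sub Dosage matrix restricted to one gene's variants.
#' @return Numeric vector of per-sample scores.
#' @export
burden_score <- function(dosage_sub) {
  d <- as.matrix(dosage_sub)
  if (ncol(d) == 0L) return(numeric(nrow(d)))
  for (j in seq_len(ncol(d))) {
    st <- minor_allele_stats(d[, j])
    if (!st$minor_is_alt) d[, j] <- 2L - d[, j]
  }
  d[is.na(d)] <- 0
  rowSums(d)
}

#' Covariates-only logistic null model
#'
#' Fits `status ~ covariates` by logistic regression; the fitted
#' probabilities and residuals feed both the burden test (as the anchored
#' model) and SKAT (as the score-test null).
#'
#' @param status 0/1 vector.
#' @param covariates Optional numeric matrix (e.g. principal components).
#' @return List of class `null_model`: `mu` (fitted probabilities), `res`
#'   (`status - mu`), `X` (design incl. intercept), `status`.
#' @export
fit_null_model <- function(status, covariates = NULL) {
  if (length(unique(status[!is.na(status)])) < 2L) {
    stop("both statuses must be present")
  }
  X <- cbind(`(Intercept)` = rep(1, length(status)), covariates)
  fit <- stats::glm.fit(X, status, family = stats::binomial())
  mu <- fit$fitted.values
  if (any(mu <= 0 | mu >= 1)) {
    mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
  }
  structure(list(mu = mu, res = status - mu, X = X, status = status),
            class = "null_model")
}

#' Case-control burden test
#'
#' Logistic regression of status on the per-sample burden score plus
#' covariates.  Inference on the burden coefficient is Wald by default
#' (`OR = exp(beta)`, 95% CI `exp(beta +/- 1.96 SE)`); a likelihood-ratio
#' p-value is available.  Under (quasi-)complete separation the fit falls
#' back to Firth-penalized likelihood and is flagged.
#'
#' @param scores Per-sample burden scores ([burden_score()]).
#' @param status 0/1 vector.
#' @param covariates Optional numeric covariate matrix.
#' @param method `"wald"` (default) or `"lrt"` for the p-value.
#' @return List of class `burden_result`: `beta`, `se`, `or_`, `ci95_lo`,
#'   `ci95_hi`, `p_raw`, `method`, `firth`, `untestable`.
#' @export
burden_test <- function(scores, status, covariates = NULL,
                        method = c("wald", "lrt")) {
  method <- match.arg(method)
  if (length(unique(status)) < 2L) stop("both statuses must be present")
  if (stats::var(scores) == 0) {
    return(structure(list(beta = NA_real_, se = NA_real_, or_ = NA_real_,
                          ci95_lo = NA_real_, ci95_hi = NA_real_,
                          p_raw = NA_real_, method = method, firth = FALSE,
                          untestable = TRUE),
                     class = "burden_result"))
  }
  X <- cbind(`(Intercept)` = rep(1, length(status)), burden = scores,
             covariates)
  fit <- suppressWarnings(stats::glm.fit(X, status,
                                         family = stats::binomial()))
  beta <- fit$coefficients["burden"]
  se_wald <- tryCatch({
    XtWX <- crossprod(X * (fit$fitted.values * (1 - fit$fitted.values)), X)
    sqrt(solve(XtWX)["burden", "burden"])
  }, error = function(e) Inf)
  # quasi-complete separation leaves a flat likelihood: huge |beta| or SE
  separated <- !fit$converged || any(fit$fitted.values < 1e-8) ||
    any(fit$fitted.values > 1 - 1e-8) || is.na(beta) ||
    abs(beta) > 10 || !is.finite(se_wald) || se_wald > 10
  firth <- FALSE
  if (separated) {
    firth <- TRUE
    ff <- firth_logistic(X, status)
    beta <- ff$beta["burden"]
    se <- ff$se["burden"]
    p <- stats::pchisq((beta / se)^2, df = 1, lower.tail = FALSE)
  } else {
    se <- se_wald
    if (method == "wald") {
      p <- stats::pchisq((beta / se)^2, df = 1, lower.tail = FALSE)
    } else {
      fit0 <- stats::glm.fit(X[, -2L, drop = FALSE], status,
                             family = stats::binomial())
      p <- stats::pchisq(fit0$deviance - fit$deviance, df = 1,
                         lower.tail = FALSE)
    }
  }
  z975 <- stats::qnorm(0.975)
  structure(list(beta = unname(beta), se = unname(se),
                 or_ = exp(unname(beta)),
                 ci95_lo = exp(unname(beta) - z975 * unname(se)),
                 ci95_hi = exp(unname(beta) + z975 * unname(se)),
                 p_raw = unname(p), method = method, firth = firth,
                 untestable = FALSE),
            class = "burden_result")
}

# Firth-penalized logistic regression (Jeffreys-prior score adjustment),
# used only as the separation fallback of burden_test.
firth_logistic <- function(X, y, max_iter = 50L, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  names(beta) <- colnames(X)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    XtWX <- crossprod(X * w, X)
    cov <- solve(XtWX)
    h <- rowSums((X %*% cov) * X) * w      # hat-matrix diagonal
    U <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    step <- drop(cov %*% U)
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  w <- stats::plogis(eta) * (1 - stats::plogis(eta))
  cov <- solve(crossprod(X * w, X))
  list(beta = beta, se = sqrt(diag(cov)))
}

#' Sequence kernel association test (SKAT)
#'
#' Variance-component score test
#' `Q = (y - mu)' G W G' (y - mu)` with `G` the gene's dosage matrix,
#' `W = diag(w_j^2)` and, by default, `w_j = dbeta(MAF_j, 1, 25)` (flat
#' weights available).  The null distribution of `Q` is the mixture
#' `sum_k lambda_k chi2_1`, with `lambda_k` the nonzero eigenvalues of
#' `P0^{1/2} G W G' P0^{1/2}` under the covariates-only logistic null.
#' The p-value uses a moment-matching (noncentral chi-square)
#' approximation and is replaced by numerical characteristic-function
#' integration when it falls below 0.01 (or always, with
#' `p_method = "integration"`).
#'
#' @param dosage_sub Dosage matrix restricted to one gene's variants
#'   (missing dosages contribute 0, as in the burden score).
#' @param null_model A [fit_null_model()] result.
#' @param weights Optional explicit per-variant weights `w_j` (not
#'   squared); overrides `weights_beta`.
#' @param weights_beta Parameters of the Beta-density MAF weighting;
#'   `c(1, 1)` gives flat weights.
#' @param p_method `"auto"` (moment matching, integration cross-check
#'   below 0.01), `"liu"`, `"integration"`, or `"permutation"` (exact
#'   finite-sample null by residual permutation; preferred at small
#'   sample sizes where the chi-square mixture is only asymptotic, and
#'   strictly valid without covariates).
#' @param n_resample Residual permutations for `p_method = "permutation"`.
#' @return List of class `skat_result`: `q_stat`, `p_raw`, `eigenvalues`,
#'   `p_method`, `untestable`.
#' @export
skat_test <- function(dosage_sub, null_model, weights = NULL,
                      weights_beta = c(1, 25),
                      p_method = c("auto", "liu", "integration",
                                   "permutation"),
                      n_resample = 10000L) {
  p_method <- match.arg(p_method)
  stopifnot(inherits(null_model, "null_model"))
  G <- as.matrix(dosage_sub)
  if (ncol(G) == 0L) stop("need >= 1 variant")
  storage.mode(G) <- "double"
  G[is.na(G)] <- 0
  if (is.null(weights)) {
    f <- colMeans(G) / 2
    maf <- pmin(f, 1 - f)
    weights <- stats::dbeta(maf, weights_beta[1], weights_beta[2])
  }
  r <- null_model$res
  s <- drop(crossprod(G, r)) * weights
  q <- sum(s^2)
  # nonzero eigenvalues of P0^{1/2} G W G' P0^{1/2} via the m x m form
  # W^{1/2} G' P0 G W^{1/2}, with P0 = V - V X (X'VX)^{-1} X' V
  v <- null_model$mu * (1 - null_model$mu)
  X <- null_model$X
  VG <- G * v
  XtVX <- crossprod(X * v, X)
  P0G <- VG - (X * v) %*% solve(XtVX, crossprod(X, VG))
  A <- crossprod(G, P0G) * tcrossprod(weights)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > max(ev, 0) * 1e-10 & ev > 0]
  if (length(ev) == 0L) {
    return(structure(list(q_stat = q, p_raw = NA_real_,
                          eigenvalues = numeric(), p_method = p_method,
                          untestable = TRUE),
                     class = "skat_result"))
  }
  p <- switch(p_method,
    liu = liu_pvalue(q, ev),
    integration = imhof_pvalue(q, ev),
    permutation = skat_perm_pvalue(q, G, weights, r, n_resample),
    auto = {
      p0 <- liu_pvalue(q, ev)
      used <- "liu"
      if (!is.na(p0) && p0 < 0.01) {
        # cross-check by characteristic-function inversion; keep it only
        # when the quadrature is trustworthy (deep in the tail the
        # oscillatory integrand loses all precision to cancellation)
        pI <- imhof_pvalue(q, ev)
        if (is.finite(pI) && pI > 1e-12 && pI < 1 &&
            (abs(pI - p0) < 0.01 || abs(log10(pI / p0)) < 1)) {
          p0 <- pI
          used <- "integration"
        }
      }
      attr(p0, "used") <- used
      p0
    })
  used <- attr(p, "used") %||% p_method
  structure(list(q_stat = q, p_raw = max(min(as.numeric(p), 1), 1e-300),
                 eigenvalues = ev, p_method = used, untestable = FALSE),
            class = "skat_result")
}

# Residual-permutation tail probability of Q; (r+1)/(B+1) estimator.
skat_perm_pvalue <- function(q, G, weights, res, n_resample) {
  n <- length(res)
  WG <- weights * t(G)                     # m x n
  count <- 0L
  block <- 20000L
  done <- 0L
  while (done < n_resample) {
    b <- min(block, n_resample - done)
    P <- vapply(seq_len(b), function(i) res[sample.int(n)], numeric(n))
    Qb <- colSums((WG %*% P)^2)
    count <- count + sum(Qb >= q)
    done <- done + b
  }
  (count + 1) / (n_resample + 1)
}

# Moment-matching (modified Liu) tail probability of sum lambda_k chi2_1.
liu_pvalue <- function(q, lambda) {
  c1 <- sum(lambda)
  c2 <- sum(lambda^2)
  c3 <- sum(lambda^3)
  c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2
    a <- sqrt(l)
    d <- 0
  }
  tstar <- (q - c1) / sqrt(2 * c2)
  mu_x <- l + d
  sigma_x <- sqrt(2) * sqrt(l + 2 * d)
  stats::pchisq(tstar * sigma_x + mu_x, df = l, ncp = d,
                lower.tail = FALSE)
}

# Imhof-type numerical inversion of the characteristic function of
# sum lambda_k chi2_1; essentially exact for well-separated eigenvalues.
imhof_pvalue <- function(q, lambda) {
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    sin(theta) / (u * rho)
  }
  int <- try(stats::integrate(integrand, 0, Inf, rel.tol = 1e-9,
                              subdivisions = 2000L)$value, silent = TRUE)
  if (inherits(int, "try-error")) {
    int <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-6,
                            subdivisions = 5000L, stop.on.error = FALSE)$value
  }
  min(max(0.5 + int / pi, 1e-14), 1)
}

#' Run burden and SKAT tests over all genes
#'
#' For every gene region: restrict to its polymorphic rare variants
#' (MAF < `maf_max`), compute the burden test and SKAT against the shared
#' covariates-only null model, then estimate one genomic-control lambda
#' per test family from the raw gene-level p-values and append
#' GC-corrected columns.  Genes without testable markers are skipped with
#' a message.
#'
#' @param geno A [genotype_matrix()] of the pruned independent rare-variant
#'   set (common variants are tolerated and filtered out per gene).
#' @param regions Gene-region `data.frame`.
#' @param pcs Optional samples x k matrix of stratification covariates.
#' @param maf_max Rare-variant threshold (default 1%).
#' @param weights_beta SKAT MAF-weighting parameters.
#' @param gc Apply genomic-control correction columns (needs >= 2 genes).
#' @return `data.frame` with one row per tested gene: `gene`, `NMUT`,
#'   `nMAF.aff`, `nMAF.ctr`, `OR`, `CI_95lo`, `CI_95up`, `P_burden_raw`,
#'   `P_SKAT_raw` and, when `gc = TRUE`, `P_burden_gc`, `P_SKAT_gc`.
#'   Attributes `lambda_burden` and `lambda_skat` carry the
#'   [genomic_lambda()] results; attribute `skipped` lists untested genes.
#' @export
run_all_genes <- function(geno, regions, pcs = NULL, maf_max = 0.01,
                          weights_beta = c(1, 25), gc = TRUE) {
  stopifnot(inherits(geno, "genotype_matrix"))
  status <- geno$samples$status
  null <- fit_null_model(status, pcs)
  assign <- assign_variants(regions, geno$variants)
  st <- variant_stats_table(geno)
  rows <- list()
  skipped <- character()
  for (g in regions$gene_id) {
    idx <- assign[[g]]
    idx <- idx[st$mac[idx] >= 1L & st$maf[idx] < maf_max]
    if (length(idx) == 0L) {
      skipped <- c(skipped, g)
      next
    }
    D <- geno$dosages[, idx, drop = FALSE]
    sc <- burden_score(D)
    # minor-allele sums by status (missing excluded by burden_score)
    nmaf_aff <- sum(sc[status == 1L])
    nmaf_ctr <- sum(sc[status == 0L])
    bt <- burden_test(sc, status, covariates = pcs)
    sk <- skat_test(D, null, weights_beta = weights_beta)
    rows[[g]] <- data.frame(
      gene = g, NMUT = length(idx),
      nMAF.aff = nmaf_aff, nMAF.ctr = nmaf_ctr,
      OR = bt$or_, CI_95lo = bt$ci95_lo, CI_95up = bt$ci95_hi,
      P_burden_raw = bt$p_raw, P_SKAT_raw = sk$p_raw,
      burden_untestable = bt$untestable, skat_untestable = sk$untestable,
      stringsAsFactors = FALSE)
  }
  if (length(skipped)) {
    message("skipped ", length(skipped), " gene(s) with no testable markers")
  }
  if (length(rows) == 0L) {
    out <- data.frame(gene = character(), NMUT = integer(),
                      nMAF.aff = numeric(), nMAF.ctr = numeric(),
                      OR = numeric(), CI_95lo = numeric(),
                      CI_95up = numeric(), P_burden_raw = numeric(),
                      P_SKAT_raw = numeric(), stringsAsFactors = FALSE)
    attr(out, "skipped") <- skipped
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (gc) {
    okb <- !out$burden_untestable & !is.na(out$P_burden_raw)
    oks <- !out$skat_untestable & !is.na(out$P_SKAT_raw)
    lb <- genomic_lambda(out$P_burden_raw[okb], source = "burden")
    ls <- genomic_lambda(out$P_SKAT_raw[oks], source = "SKAT")
    out$P_burden_gc <- gc_correct(out$P_burden_raw, lb)
    out$P_SKAT_gc <- gc_correct(out$P_SKAT_raw, ls)
    attr(out, "lambda_burden") <- lb
    attr(out, "lambda_skat") <- ls
  }
  attr(out, "skipped") <- skipped
  out
}
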