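---
title: "Gene-centered rare-variant association scans with rarescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-centered rare-variant association scans with rarescan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-variant association tests have essentially no power for variants
with minor-allele frequency (MAF) below 1%: the carrier counts are too
small.  A gene-centered strategy regains power by aggregating all rare
variation mapped to a gene and asking whether the *aggregate* differs
between cases and controls.  `rarescan` implements a complete pipeline
for this strategy on imputed case-control genotypes: quality control,
rare-variant classification, linkage-disequilibrium (LD) pruning,
per-gene burden and SKAT tests with stratification correction,
permutation-based multiple-testing correction, intersection-based
candidate selection, and a resampling test for enrichment of gene-disease
annotations in the candidate list.  A synthetic-cohort generator emulates
the statistical structure the analysis assumes, so every stage is
testable without access to controlled genotype data.

## The two association tests

For gene $g$ with variant set $S_g$ (restricted to MAF < 1% on the
pruned, independent marker set), the **burden test** builds the genetic
variable

$$ b_i \;=\; \sum_{j \in S_g} g_{ij}, $$

the count of minor alleles carried by individual $i$ (missing genotypes
contribute 0), and fits the logistic regression

$$ \operatorname{logit} P(y_i = 1) \;=\; \alpha + \beta\, b_i +
   \boldsymbol{\gamma}^\top \mathbf{pc}_i . $$

$e^{\beta}$ is the aggregate odds ratio: OR > 1 means the gene's rare
variation is, in aggregate, a risk factor; OR < 1 means it is
protective.  Inference is Wald by default (the 95% CI is symmetric on
the log scale); a likelihood-ratio option exists.  Under quasi-complete
separation — easy to hit with sparse burdens — the fit falls back to
Firth-penalized likelihood and is flagged.

The **SKAT test** is the variance-component score test

$$ Q \;=\; (\mathbf{y} - \hat{\boldsymbol{\mu}})^\top G W G^\top
   (\mathbf{y} - \hat{\boldsymbol{\mu}}), $$

with $G$ the gene's dosage matrix, $W = \mathrm{diag}(w_j^2)$,
$w_j = \mathrm{Beta}(\mathrm{MAF}_j; 1, 25)$ density weights by default
(flat weights available), and $\hat{\boldsymbol{\mu}}$ fitted under the
covariates-only logistic null.  Burden tests are powerful when effects
share a direction; SKAT stays powerful under mixed risk/protective
effects within a gene.  Requiring *both* tests to be significant trades
sensitivity for a lower false-positive rate; that intersection is the
candidate-selection rule.

### The SKAT null distribution, and when we do not trust it

Asymptotically $Q \sim \sum_k \lambda_k \chi^2_{1,k}$, with $\lambda_k$
the nonzero eigenvalues of $P_0^{1/2} G W G^\top P_0^{1/2}$ and $P_0$
the projection-adjusted residual variance of the logistic null.  The
p-value uses a moment-matching (non-central chi-square) approximation;
when it falls below 0.01 it is cross-checked by numerical inversion of
the characteristic function (Imhof-type quadrature).  Two numerical
guards matter:

* Deep in the tail the oscillatory Imhof integrand loses all precision
  to cancellation, so the integration result replaces the
  moment-matching value only when the two agree to within an order of
  magnitude (otherwise the quadrature has failed, and the
  moment-matching value — whose relative error in the far tail is
  modest — is kept).
* At desk-scale sample sizes with genuinely rare variants, the mixture
  itself is only an approximation: per-variant scores are sums of a
  handful of carrier terms, far from normal.  We measured the analytic
  p to deviate from the exact finite-sample (residual-permutation) null
  by up to ~0.03 in the mid-range at $n = 200$, and the analytic test
  rejects at about 0.035 instead of 0.05 at $n = 500$ with 20 rare
  variants — conservative, in line with what motivates small-sample
  corrections in SKAT software generally.  `skat_test()` therefore
  offers `p_method = "permutation"`, the exact null by residual
  permutation, which the test suite uses wherever exactness at small
  $n$ is the point.  (With covariates, residual permutation is itself
  an approximation — exchangeability holds only under the null
  covariate model — so the analytic route remains the default.)

This small-sample behavior also surfaces as gene-level genomic-control
inflation: on null synthetic cohorts (unstratified, or confounded but
PC-adjusted — even adjusted on the *true* subpopulation label) the
median-based $\lambda_{GC}$ of analytic SKAT p-values scatters roughly
between 1.0 and 1.35 across cohort draws at desk-scale $n$, a
median-region distortion of the asymptotic mixture rather than residual
confounding.  That is precisely why the pipeline estimates and applies
a per-family GC correction after the PC adjustment rather than assuming
PCs suffice.  The burden family is much better behaved ($\lambda$
within [0.9, 1.1] on the same cohorts at adequate gene counts).

## Stratification correction

Principal components are computed on standardized common-variant
genotypes (centered by $2\hat p$, scaled by $\sqrt{2\hat p(1-\hat p)}$,
missing set to 0 after centering; smartpca-style outlier-removal
iterations are not replicated).  Component signs are fixed by forcing
the largest-magnitude loading positive, so results are reproducible.
The first 10 PCs enter both tests as covariates.  Residual inflation is
then measured per test family as
$\lambda_{GC} = \mathrm{median}(\chi^2_1(p)) / 0.4549$ over all
gene-level raw p-values and divided out of the 1-df chi-square
equivalents (Devlin–Roeder-style correction).  $\lambda$ is estimated
separately for the burden and SKAT families because their small-sample
behavior differs (see above).

## LD pruning

Collinearity among aggregated markers is controlled by pruning to an
independent set at composite-LD $r^2 < 0.1$ (squared Pearson correlation
of dosage vectors; no phasing).  Pruning is greedy within a sliding
window (defaults: 50 variants, step 5; the removal rule drops the
lower-MAF member, ties drop the later position), and sweeps repeat until
a pass removes nothing, which makes the operation idempotent.  Whether
pruning should run genome-wide or per gene region is not canonical; the
default is per gene region, matching the per-gene testing unit, and is
configurable.  Rare variants survive pruning at a much higher rate than
common variants — they sit on few haplotypes and correlate weakly — and
the test suite asserts that qualitative behavior.

## Multiple-testing correction and selection

Genome-wide Bonferroni thresholds are punishingly conservative for
gene-based rare-variant tests, so the pipeline uses a pooled-marker
permutation scheme: the dosage columns of all rare variants of all
tested genes form one pooled table; for each gene, `n_perm` replicates
draw as many columns (without replacement within a replicate) as the
gene has markers and re-run the identical test with identical
covariates.  The empirical corrected p-value is $(r+1)/(N+1)$ with $r$
the count of replicate GC-corrected p-values at or below the observed
one — never exactly zero, and values at the floor are rendered as
bounds (e.g. `<1.00E-03` at $N = 1000$).  Randomization destroys LD
between the drawn columns, which is immaterial exactly because the
pooled table is built from the post-pruning independent set.  The
comparison is performed on GC-corrected p-values (order: GC, then
empirical); since GC correction is monotone, the empirical rank — and
hence the empirical p — is unchanged by it, so this choice is a
convention, not a tuning knob.  Candidates are genes with GC-corrected
and empirical p below $\alpha = 0.05$ in both families, labelled risk
(OR > 1) or protective (OR < 1) and sorted by empirical burden p.

## Annotation enrichment

Given an OMIM-style (gene, disease) table, the candidate list's
annotation count $X$ (a gene with three diseases contributes three) is
compared against $R = 1000$ random gene sets of the same size drawn
from the universe of *tested* genes — not all genome genes, so
gene-length and imputability ascertainment cancel.  The Z-score
$(X - \bar X_R)/s_R$ with a one-sided upper normal p tests enrichment;
an exact resampling p $(r+1)/(R+1)$ is also reported.  On
one-disease-per-gene tables the replicate counts are exactly
hypergeometric, which the acceptance suite verifies by goodness of fit.

## The synthetic cohort generator

The generator produces the structure the analysis assumes, at
configurable scale:

* **Site frequency spectrum.** Each variant draws a category
  (`singleton`, `very_rare` with MAF < 0.1%, `rare_strict` with
  0.1% ≤ MAF ≤ 1%, `common`) from the `sfs_weights`; ancestral
  frequencies follow an inverse-frequency density truncated to the
  category band, reflecting the strong rare-skew of imputed variation
  (roughly half of imputed markers are rare, and within the rare set
  singletons / very rare / strict-sense rare split about
  14.5% / 51.8% / 33.7%).  Those observed proportions, scaled by the
  rare fraction, are the generator's default weights.
* **Population structure.** Per-subpopulation frequencies follow the
  Balding–Nichols model
  $p_s \sim \mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$ — the standard
  minimal stratification generator.  Confounding is induced by unequal
  subpopulation proportions between cases and controls.
* **LD.** Haplotype alleles within blocks of `ld_block_size` variants
  share a latent Gaussian factor (correlation `ld_rho`, default 0.8);
  blocks are independent.  This block-diagonal LD is sufficient to
  exercise pruning; realistic recombination maps are out of scope.
* **Category enforcement.** Binomial sampling throws a drawn frequency
  out of its band often enough to distort realized spectra badly (a
  very-rare draw realizes as a singleton or monomorphic ~20% of the
  time), so singletons are placed as exactly one minor-allele copy on a
  random chromosome, and other categories redraw a nonconforming
  column marginally (up to 30 attempts, then keep).  A redrawn column
  loses its block coupling; realized category proportions then match
  the targets within multinomial noise (±3% absolute in the acceptance
  check).
* **Phenotype effects.** `spike_effects()` draws status from
  $\operatorname{logit} P(\mathrm{case}) = \alpha + \sum_g \beta_g
  b_g(i)$ with the intercept solved numerically for the requested
  prevalence, then subsamples to the requested case/control counts.
  Because the logistic slope is invariant under outcome-dependent
  sampling, spiked log-odds are recoverable from the case-control
  subsample.  Effect sizes used in power checks are free parameters of
  the simulation design, not published estimates.
* **Plumbing.** Missingness is independent Bernoulli per genotype;
  imputation info scores are fabricated uniformly on
  `info_score_dist` (default [0.75, 1], i.e. already past the
  post-imputation threshold unless you widen it).

What the generator does **not** emulate: realistic demography and
recombination, genotyping batch effects, imputation error correlated
with frequency, gene-length distributions.  Green tests therefore
certify the statistical machinery, not performance on any particular
real cohort.

## Quality-control conventions

All thresholds are inclusive on the "keep" side, matching their usual
phrasing (call rate ≥ 90%/98%, MAF ≥ 1% at the scaffold stage, HWE
p ≥ 1e-4 overall and ≥ 0.01 in controls, differential-missingness
p ≥ 1e-5, info score ≥ 0.75, kinship < 0.055 keeps the pair).  The HWE
filter is read as whole-sample AND controls-only, one reasonable
resolution of an ambiguous clause.  The Hardy–Weinberg test is the
exact conditional test (summing all heterozygote configurations no more
probable than the observed one).  The differential-missingness statistic
is unstated in most protocols; we use Fisher's exact test when any
expected cell is below 5, else the 1-df chi-square.  Relatedness uses a
pedigree-free robust estimator,
$\hat\varphi = (N_{het,het} - 2N_{opp,hom}) / (N_{het}(i) +
N_{het}(j))$, because admixture-aware estimators need external ancestry
frequencies; from each flagged pair the lower-call-rate member is
dropped (ties: sample order).  Kinship estimates from fewer than 100
overlapping genotypes are flagged unreliable and the pair is retained.
The rare-variant category boundary at exactly MAF = 0.1% belongs to the
strict-sense rare class, so the two intervals partition; MAF is computed
over called genotypes of the combined sample, with ties at 0.5
designating the alternate allele minor.

Note one boundary subtlety: sample call rates are recomputed after
variant filters, so a sample sitting exactly on 90% can drop below it
when variants are removed; QC re-applied to its own output is a no-op
except for such knife-edge cases, which the test fixtures avoid on
purpose.

## Problem sizes and tolerances in the test suite

The suite validates calibration and recovery at sizes a laptop handles
comfortably: type-I error over 2,000 null cohorts of $n = 500$ with 20
rare variants per gene (binomial 95% CI around 0.05); SKAT against a
100,000-draw permutation oracle at $n = 200$ (3 Monte-Carlo standard
errors); OR = 2.0 and 0.5 recovery over 200 replicates at $n = 2{,}000$
(mean within [1.8, 2.2] and its reciprocal; the mean sits near 2.1
because block-LD makes the burden distribution clumpy and the logistic
MLE slightly biased away from the null at finite $n$ — measured, and
inside the band); stratification on 800-gene confounded cohorts;
empirical-correction uniformity over 500 null genes at $N = 200$
replicates; enrichment against the closed-form hypergeometric law at
$R = 10{,}000$.  Published accounting tables are asserted from their
printed component counts at printed rounding, trusting component counts
over printed totals where the two disagree by a final-digit
inconsistency.

## Known limitations

* The analytic SKAT p-value is conservative at small $n$ with very
  sparse genes; use `p_method = "permutation"` when that matters and
  covariates are absent.
* Residual permutation with covariates is approximate; no
  strata-preserving permutation is implemented.
* PCs are computed from common variants; fine-scale structure visible
  only to rare variants is not corrected beyond the GC stage.
* The pooled-table correction assumes gene exchangeability given marker
  count; gene-specific LD surviving the pruning threshold is ignored.
* BED is the only region format; BGEN/PLINK-binary genotypes are not
  parsed.
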