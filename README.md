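# rarescan

Gene-centered rare-variant association scans for case-control cohorts.

Single-variant association tests are essentially powerless below a minor
allele frequency (MAF) of 1%. `rarescan` implements the alternative
strategy used for densely imputed case-control studies: aggregate all
rare variation mapped to each protein-coding gene and test the
aggregate, genome-wide. It is aimed at statistical geneticists who have
imputed genotypes (VCF with per-variant imputation info scores, or a
plain dosage matrix), a phenotype table and gene regions (BED), and want
a reproducible pipeline from QC to a ranked candidate-gene table.

## What it computes

For each gene *g* with rare-variant set *S<sub>g</sub>* (MAF < 1%, pruned
to pairwise independence at r² < 0.1):

* **Burden test** — logistic regression
  logit P(yᵢ = 1) = α + β bᵢ + γ′pcᵢ, where bᵢ = Σ<sub>j∈S_g</sub> gᵢⱼ
  is the per-individual minor-allele count. exp(β) is the aggregate odds
  ratio: OR > 1 risk, OR < 1 protective. Wald inference, with a
  Firth-penalized fallback under separation.
* **SKAT** — the variance-component score test
  Q = (y − μ̂)′ G W G′(y − μ̂) with Beta(1, 25) MAF weights; null
  distribution Σ λₖχ²₁ from the eigenvalues of the projected kernel,
  p-values by moment matching, characteristic-function integration, or
  exact residual permutation.
* **Stratification correction** — the first 10 principal components of
  standardized common-variant genotypes as covariates, then per-family
  genomic control: λ = median(χ²)/0.4549, statistics divided by λ.
* **Multiple-testing correction** — pooled-marker permutation: random
  same-size marker sets drawn from the pooled rare-variant table give an
  empirical corrected p of (r + 1)/(N + 1) per gene and family.
* **Selection** — candidates must pass GC-corrected and empirical p
  < 0.05 in *both* tests; the intersection suppresses false positives.
* **Enrichment** — a resampling Z-score test for over-representation of
  OMIM-style gene-disease annotations in the candidate list, against
  random gene sets from the tested-gene universe.

A synthetic-cohort generator (Balding–Nichols subpopulations,
rare-skewed site frequency spectrum, LD blocks, missingness, fabricated
info scores, spiked per-gene risk/protective effects) makes the whole
pipeline testable without controlled-access data.

## Worked example

Simulate a cohort with one risk and one protective gene spiked in, run
the full pipeline, and look at the candidate table:

```r
library(rarescan)

spec <- cohort_spec(n_cases = 1250, n_controls = 1250, n_genes = 40,
                    variants_per_gene = c(15, 25),
                    sfs_weights = c(singleton = 0.08, very_rare = 0,
                                    rare_strict = 0.57, common = 0.35),
                    seed = 42)
sim <- simulate_cohort(spec)
sp <- spike_effects(sim$geno, sim$regions,
                    list(effect_spec("GENE0007",  log(3)),   # risk
                         effect_spec("GENE0012", -log(3))),  # protective
                    baseline_prevalence = 0.4,
                    n_cases = 800, n_controls = 800, seed = 43)
geno <- subset_geno(sim$geno, samples = sp$sample_idx)
gdt <- simulate_annotations(sim$regions$gene_id, p_annotated = 0.4,
                            causal_boost = 2,
                            causal_genes = c("GENE0007", "GENE0012"),
                            seed = 44)

cfg <- run_config(geno = "", pheno = "", regions = "",
                  out_dir = tempfile(), n_perm = 500, n_pcs = 4,
                  seed = 45)
cfg$geno <- geno; cfg$pheno <- sp$pheno; cfg$regions <- sim$regions
cfg$gene_disease <- gdt
res <- run_pipeline(cfg)

res$manifest[c("lambda_burden", "lambda_skat")]
res$candidates[, c("gene", "NMUT", "nMAF.aff", "nMAF.ctr", "OR",
                   "CI_95lo", "CI_95up", "P_burden_emp", "P_SKAT_emp",
                   "direction")]
res$enrichment
```

Output (this run):

```
lambda_burden: 1.23  lambda_skat: 1.11
     gene NMUT nMAF.aff nMAF.ctr    OR CI_95lo CI_95up P_burden_emp P_SKAT_emp  direction
 GENE0007   12       70       21 2.887   1.791   4.655        0.002     0.0020       risk
 GENE0012   11       32       96 0.342   0.229   0.511        0.002     0.0020 protective
 GENE0005   12       34       63 0.599   0.407   0.882        0.018     0.0339 protective
enrichment: observed 3 annotations vs 3.10 +/- 1.85 expected (R = 1000)
  Z = -0.055, one-sided P = 0.522 (resampling P = 0.622)
```

Reading it: both spiked genes top the table with the correct direction —
GENE0007 carries 70 minor alleles in 800 cases vs 21 in 800 controls
(NMUT = 12 independent rare variants; aggregate OR 2.9), GENE0012 is
mirror-image protective (OR 0.34); `0.002` is the permutation floor
1/(N+1) at N = 500, rendered as `<2.00E-03` in the written table.
GENE0005 is a chance hit at these thresholds — the intersection rule
reduces but does not abolish false positives. The λ values near 1 say
stratification is under control (the cohort has a single
subpopulation), and the enrichment test is null, as expected with only
two causal genes feeding the annotation boost. `run_pipeline()` also
writes `qc_report.tsv`, `category_tally.tsv`, `pcs.tsv`, `results.tsv`,
`candidates.tsv`, `enrichment.tsv` and a `manifest.yaml` recording
seeds, thresholds and λs under `cfg$out_dir`.

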