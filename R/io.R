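#' Read genotypes from VCF or dosage TSV
#'
#' VCF (v4.2) `GT` fields are mapped to alternate-allele dosages
#' (`./.` and `.` become missing); the per-variant imputation quality is
#' read from the INFO key `INFO` (absent scores are left `NA` and flagged
#' by downstream imputation QC).  Multi-allelic records are split into one
#' biallelic record per alternate allele, with a warning.  Positions are
#' 1-based as in VCF.  Duplicate variant ids are suffixed.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"` (the dosage
#'   dialect of [write_dosage_tsv()]).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "tsv") return(read_dosage_tsv(path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(vcf)
  if (is.null(dim(fx))) fx <- t(fx)  # single-record files drop to vector
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) {
    gt <- matrix(gt, nrow = nrow(fix), dimnames = list(fix$ID, names(gt)))
  }
  info <- suppressWarnings(
    as.numeric(vcfR::extract.info(vcf, element = "INFO")))
  if (all(is.na(info)) && nrow(fix) > 0) {
    warning("no INFO imputation-quality key found; info scores left NA")
  }
  n_alt <- lengths(strsplit(fix$ALT, ",", fixed = TRUE))
  if (any(n_alt > 1)) {
    warning("splitting ", sum(n_alt > 1),
            " multi-allelic record(s) into biallelic records")
  }
  dos_rows <- vector("list", sum(n_alt))
  meta <- vector("list", sum(n_alt))
  k <- 0L
  for (j in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[j], ",", fixed = TRUE)[[1]]
    alleles <- strsplit(gt[j, ], "[/|]")
    for (a in seq_along(alts)) {
      k <- k + 1L
      dos_rows[[k]] <- vapply(alleles, function(al) {
        if (length(al) == 0L || anyNA(al) || any(al == ".")) {
          return(NA_integer_)
        }
        sum(al == as.character(a))
      }, integer(1))
      id <- fix$ID[j]
      if (is.na(id) || id == ".") {
        id <- paste0(fix$CHROM[j], ":", fix$POS[j])
      }
      if (length(alts) > 1L) id <- paste0(id, "_alt", a)
      meta[[k]] <- data.frame(chrom = fix$CHROM[j],
                              pos = as.integer(fix$POS[j]), id = id,
                              ref = fix$REF[j], alt = alts[a],
                              info_score = info[j],
                              stringsAsFactors = FALSE)
    }
  }
  variants <- do.call(rbind, meta)
  if (anyDuplicated(variants$id)) {
    message("suffixing duplicate variant ids")
    variants$id <- make.unique(variants$id, sep = "_dup")
  }
  dosages <- t(do.call(rbind, dos_rows))
  samples <- data.frame(sample_id = colnames(gt), stringsAsFactors = FALSE)
  genotype_matrix(dosages, variants, samples)
}

#' Write a genotype matrix to plain-text VCF v4.2
#'
#' Dosages map to unphased `GT` (`0/0`, `0/1`, `1/1`, `./.`); the
#' imputation quality is written as the INFO key `INFO`.
#'
#' @param geno A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  v <- geno$variants
  info <- if ("info_score" %in% names(v) && !all(is.na(v$info_score))) {
    sprintf("INFO=%.6g", v$info_score)
  } else rep(".", nrow(v))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix(gt_code[as.character(geno$dosages)],
               nrow(geno$dosages), ncol(geno$dosages))
  gt[is.na(geno$dosages)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=rarescan",
    paste0("##INFO=<ID=INFO,Number=1,Type=Float,",
           "Description=\"Imputation info score\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", geno$samples$sample_id), collapse = "\t"))
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", info,
                "GT", sep = "\t")
  body <- paste(body, apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Dosage TSV dialect
#'
#' Samples x variants table, first column `sample_id`, `NA` for missing;
#' used by tests and small pipelines that bypass VCF.  Variant metadata
#' beyond the ids is not carried by this format.
#'
#' @param geno A [genotype_matrix()].
#' @param path File path.
#' @return `write_dosage_tsv`: `path` invisibly; `read_dosage_tsv`: a
#'   [genotype_matrix()] with placeholder coordinates.
#' @export
write_dosage_tsv <- function(geno, path) {
  df <- data.frame(sample_id = geno$samples$sample_id,
                   geno$dosages, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  dosages <- as.matrix(df[, -1, drop = FALSE])
  genotype_matrix(dosages,
                  data.frame(chrom = "1", pos = seq_len(ncol(dosages)),
                             id = colnames(dosages), ref = "A", alt = "G",
                             stringsAsFactors = FALSE),
                  data.frame(sample_id = as.character(df[[1]]),
                             stringsAsFactors = FALSE))
}

#' Read a phenotype/covariate table
#'
#' Tab-separated, columns `sample_id`, `status` (0 = control, 1 = case)
#' and optionally `subpop`.
#'
#' @param path File path.
#' @return `data.frame`.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "status") %in% names(df))) {
    stop("phenotype table needs columns sample_id and status")
  }
  if (!all(df$status %in% c(0L, 1L, NA))) {
    stop("status must be coded 0 (control) / 1 (case)")
  }
  df
}

#' Write a phenotype table
#' @param pheno `data.frame` with `sample_id`, `status`, optional `subpop`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene regions from BED
#'
#' BED is 0-based half-open on disk; coordinates are converted once, here,
#' to the package-wide 1-based inclusive convention.
#'
#' @param path BED file (4+ columns; the name column holds the gene id).
#' @return `data.frame` with `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gene_regions <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(gene_id = if (!is.null(gr$name)) gr$name else
               paste0("region", seq_along(gr)),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write gene regions to BED
#'
#' The internal 1-based inclusive intervals are converted back to BED's
#' 0-based half-open convention by the exporter.
#'
#' @param regions `data.frame` with `gene_id`, `chrom`, `start`, `end`.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_gene_regions <- function(regions, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start, end = regions$end),
    name = regions$gene_id)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a gene-disease annotation table
#'
#' Tab-separated `gene_id`, `disease_id` pairs (OMIM-style); duplicate
#' pairs are dropped.
#'
#' @param path File path.
#' @return `data.frame`.
#' @export
read_gene_disease <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "disease_id") %in% names(df))) {
    stop("gene-disease table needs columns gene_id and disease_id")
  }
  unique(df[, c("gene_id", "disease_id")])
}

#' Read a variant functional-annotation table
#'
#' Tab-separated `variant_id`, `category` (ANNOVAR-style vocabulary).
#'
#' @param path File path.
#' @return `data.frame`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("variant_id", "category") %in% names(df))) {
    stop("annotation table needs columns variant_id and category")
  }
  df
}

#' Write a results table with a provenance header
#'
#' Prepends `# key: value` comment lines naming the thresholds and seeds
#' that produced the table.
#'
#' @param df `data.frame` to write.
#' @param path Output path.
#' @param header Named list/vector written as comment lines.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(df, path, header = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(header)) {
    writeLines(paste0("# ", k, ": ",
                      paste(unlist(header[[k]]), collapse = ",")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles input paths, thresholds (defaulting to the package's stringent
#' QC scheme) and seeds for [run_pipeline()].  Configurations round-trip
#' through YAML unchanged ([read_run_config()], [write_run_config()]).
#'
#' @param geno,pheno,regions Input paths (genotypes, phenotype TSV, BED).
#' @param annotations,gene_disease Optional annotation table paths.
#' @param out_dir Output directory.
#' @param thresholds A [qc_thresholds()] list.
#' @param r2_threshold,prune_window,prune_step LD-pruning parameters.
#' @param n_pcs Number of stratification covariates.
#' @param maf_max Rare-variant threshold.
#' @param weights_beta SKAT weighting parameters.
#' @param n_perm Permutation replicates for the empirical correction.
#' @param alpha Candidate-selection level (`>= 1` disables filtering).
#' @param enrichment_R Enrichment resampling replicates.
#' @param seed Integer seed for every stochastic stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(geno, pheno, regions, annotations = NULL,
                       gene_disease = NULL, out_dir = "rarescan_out",
                       thresholds = qc_thresholds(), r2_threshold = 0.1,
                       prune_window = 50L, prune_step = 5L, n_pcs = 10L,
                       maf_max = 0.01, weights_beta = c(1, 25),
                       n_perm = 1000L, alpha = 0.05,
                       enrichment_R = 1000L, seed = 1L) {
  stopifnot(r2_threshold > 0, maf_max > 0, maf_max <= 0.5, n_perm >= 1,
            alpha > 0, n_pcs >= 0)
  structure(list(geno = geno, pheno = pheno, regions = regions,
                 annotations = annotations, gene_disease = gene_disease,
                 out_dir = out_dir, thresholds = thresholds,
                 r2_threshold = r2_threshold,
                 prune_window = as.integer(prune_window),
                 prune_step = as.integer(prune_step),
                 n_pcs = as.integer(n_pcs), maf_max = maf_max,
                 weights_beta = weights_beta, n_perm = as.integer(n_perm),
                 alpha = alpha, enrichment_R = as.integer(enrichment_R),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$thresholds <- do.call(qc_thresholds, x$thresholds)
  do.call(run_config, x)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$thresholds <- unclass(x$thresholds)
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}
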