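#' Hard-filter thresholds for variant quality control
#'
#' Defaults are the standard GATK-style hard-filter bounds used for SNP
#' quality control: a locus is removed when any *present* metric violates its
#' bound (`QD < 2.0`, `QUAL < 30.0`, `FS > 60.0`, `MQ < 40.0`, `SOR > 3.0`,
#' `MQRankSum < -12.5`) or when its missing rate reaches `max_missing`
#' (default 0.95). Metrics absent from the VCF INFO field never trigger
#' removal, so pre-filtered public VCFs pass through unchanged.
#'
#' @param qd_min,qual_min,fs_max,mq_min,sor_max,mqranksum_min numeric bounds.
#' @param max_missing loci with `missing_rate >= max_missing` are removed.
#' @return A `filter_config` list of thresholds.
#' @export
filter_config <- function(qd_min = 2.0, qual_min = 30.0, fs_max = 60.0,
                          mq_min = 40.0, sor_max = 3.0,
                          mqranksum_min = -12.5, max_missing = 0.95) {
  structure(list(qd_min = qd_min, qual_min = qual_min, fs_max = fs_max,
                 mq_min = mq_min, sor_max = sor_max,
                 mqranksum_min = mqranksum_min, max_missing = max_missing),
            class = "filter_config")
}

info_metric_names <- c("QD", "FS", "MQ", "SOR", "MQRankSum")

#' Read a VCF file into a dosage matrix and variant table
#'
#' Parses a VCF 4.x file (via `VariantAnnotation::readVcf`) into the package's
#' internal genotype model: an integer samples x loci matrix of alternate
#' allele dosages (0/1/2, `NA` for missing) and a per-locus variant table
#' carrying position, alleles, QUAL, the hard-filter INFO metrics when
#' present, and the per-locus missing rate.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @param multiallelic `"error"` (default) rejects records with more than one
#'   ALT allele; `"first_alt"` keeps the first ALT and treats genotypes
#'   carrying other ALT alleles as missing.
#' @return list with `genotypes` (integer matrix, samples x loci, dimnames
#'   set, `NA` = missing) and `variants` (data.frame with columns chrom, pos,
#'   ref, alt, qual, QD, FS, MQ, SOR, MQRankSum, missing_rate).
#' @export
read_vcf <- function(path, multiallelic = c("error", "first_alt")) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) abort_stage("genotype_io", paste0("VCF not found: ", path))
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) abort_stage(
      "genotype_io", paste0("malformed VCF '", path, "': ", conditionMessage(e)))
  )
  gt <- tryCatch(VariantAnnotation::geno(vcf)$GT, error = function(e) NULL)
  if (is.null(gt)) abort_stage("genotype_io", "VCF has no GT FORMAT field")

  rr <- SummarizedExperiment::rowRanges(vcf)
  alt_list <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(alt_list)
  if (any(n_alt != 1)) {
    if (multiallelic == "error") {
      abort_stage("genotype_io", sprintf(
        "%d multiallelic record(s); rerun with multiallelic = 'first_alt' to keep first ALT",
        sum(n_alt != 1)))
    }
  }
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(rr$REF)
  alt <- vapply(seq_along(alt_list), function(i) {
    a <- alt_list[[i]]
    if (length(a) == 0) "." else as.character(a[1])
  }, character(1))
  qual <- rr$QUAL

  # GT strings -> dosage; phased and unphased treated identically
  dosage_of <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    alleles <- strsplit(g, "[/|]", fixed = FALSE)[[1]]
    if (length(alleles) != 2)
      abort_stage("genotype_io", paste0("non-diploid GT '", g, "'"))
    if (any(alleles == ".")) return(NA_integer_)
    ai <- suppressWarnings(as.integer(alleles))
    if (any(is.na(ai)))
      abort_stage("genotype_io", paste0("unparseable GT '", g, "'"))
    if (any(ai > 1)) {
      if (multiallelic == "first_alt") return(NA_integer_)
      abort_stage("genotype_io", paste0("GT '", g, "' references ALT allele > 1"))
    }
    sum(ai)
  }
  uniq <- unique(as.vector(gt))
  lut <- vapply(uniq, dosage_of, integer(1))
  names(lut) <- uniq
  dos <- matrix(lut[as.vector(gt)], nrow = nrow(gt), ncol = ncol(gt))
  # readVcf yields variants x samples; internal convention is samples x loci
  G <- t(dos)
  rownames(G) <- colnames(gt)

  vt <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   qual = as.numeric(qual), stringsAsFactors = FALSE)
  inf <- VariantAnnotation::info(vcf)
  for (m in info_metric_names) {
    vt[[m]] <- if (m %in% colnames(inf)) as.numeric(inf[[m]]) else NA_real_
  }
  vt$missing_rate <- colMeans(is.na(G))
  rownames(vt) <- NULL
  colnames(G) <- locus_key(vt$chrom, vt$pos, vt$ref, vt$alt)
  list(genotypes = G, variants = vt)
}

#' Write a dosage matrix as a VCF 4.2 file
#'
#' Inverse of [read_vcf()] for biallelic SNPs: dosages 0/1/2 become GT
#' `0/0`, `0/1`, `1/1`; `NA` becomes `./.`. Hard-filter INFO metrics present
#' in `variants` are emitted in the INFO column with matching header lines.
#'
#' @param genotypes integer samples x loci dosage matrix (`NA` = missing).
#' @param variants variant table as returned by [read_vcf()]; `qual` and the
#'   INFO metric columns may be `NA`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, variants, path) {
  stopifnot(ncol(genotypes) == nrow(variants))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=autogs",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand bias">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##INFO=<ID=SOR,Number=1,Type=Float,Description="Strand odds ratio">',
    '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="Mapping quality rank sum">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t")
  ), con)
  gt_str <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  fmt_num <- function(x) formatC(x, format = "g", digits = 6)
  for (j in seq_len(nrow(variants))) {
    v <- variants[j, ]
    present <- info_metric_names[!vapply(variants[j, info_metric_names],
                                         is.na, logical(1))]
    info <- if (length(present) == 0) "." else
      paste(paste0(present, "=", fmt_num(unlist(v[present]))), collapse = ";")
    g <- genotypes[, j]
    gcol <- ifelse(is.na(g), "./.", gt_str[as.character(g)])
    writeLines(paste(c(v$chrom, v$pos, ".", v$ref, v$alt,
                       if (is.na(v$qual)) "." else fmt_num(v$qual),
                       ".", info, "GT", gcol), collapse = "\t"), con)
  }
  invisible(path)
}

#' Apply hard filters to a variant table
#'
#' A locus is dropped iff any present metric violates its bound (strict
#' inequalities: `QD < 2.0`, `QUAL < 30.0`, `FS > 60.0`, `MQ < 40.0`,
#' `SOR > 3.0`, `MQRankSum < -12.5`) or `missing_rate >= max_missing`.
#' Absent (`NA`) metrics never disqualify a locus. Idempotent and independent
#' of locus order.
#'
#' @param variants variant table from [read_vcf()] or
#'   [simulate_genotypes()].
#' @param config a [filter_config()].
#' @return logical keep-mask over the rows of `variants`.
#' @export
filter_variants <- function(variants, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  viol <- function(x, bad) !is.na(x) & bad(x)
  drop <- viol(variants$QD, function(x) x < config$qd_min) |
    viol(variants$qual, function(x) x < config$qual_min) |
    viol(variants$FS, function(x) x > config$fs_max) |
    viol(variants$MQ, function(x) x < config$mq_min) |
    viol(variants$SOR, function(x) x > config$sor_max) |
    viol(variants$MQRankSum, function(x) x < config$mqranksum_min) |
    (variants$missing_rate >= config$max_missing)
  keep <- !drop
  if (!any(keep)) warning("filter_variants: no loci pass the filters")
  keep
}

#' Impute missing genotype dosages
#'
#' Replaces every `NA` entry by the per-locus most frequent dosage; ties are
#' broken toward the lower dosage. Non-missing entries are never altered.
#'
#' @param genotypes integer samples x loci dosage matrix.
#' @param method only `"mode"` is implemented.
#' @return matrix of the same shape with no missing entries.
#' @export
impute_missing <- function(genotypes, method = "mode") {
  method <- match.arg(method, "mode")
  if (!anyNA(genotypes)) return(genotypes)
  counts <- rbind(colSums(genotypes == 0L, na.rm = TRUE),
                  colSums(genotypes == 1L, na.rm = TRUE),
                  colSums(genotypes == 2L, na.rm = TRUE))
  all_missing <- colSums(counts) == 0
  if (any(all_missing)) {
    abort_stage("genotype_io", sprintf(
      "cannot impute: %d locus/loci are 100%% missing (e.g. column %d)",
      sum(all_missing), which(all_missing)[1]))
  }
  # which.max returns the first maximum, so ties resolve to the lower dosage
  modes <- apply(counts, 2, which.max) - 1L
  idx <- which(is.na(genotypes), arr.ind = TRUE)
  genotypes[idx] <- modes[idx[, 2]]
  genotypes
}

#' Read a phenotype table
#'
#' Expects a CSV with a header and columns `sample,value[,env]` (extra
#' columns are ignored). Sample ids are matched case-sensitively and must be
#' unique within an environment.
#'
#' @param path CSV path.
#' @return data.frame with columns `sample`, `value` and, when present,
#'   `env`.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    abort_stage("genotype_io", "phenotype CSV needs at least 2 columns (sample,value)")
  cn <- tolower(colnames(df))
  sample_col <- if ("sample" %in% cn) which(cn == "sample")[1] else 1L
  value_col <- if ("value" %in% cn) which(cn == "value")[1] else 2L
  env_col <- if ("env" %in% cn) which(cn == "env")[1] else NA_integer_
  out <- data.frame(sample = as.character(df[[sample_col]]),
                    value = df[[value_col]], stringsAsFactors = FALSE)
  if (!is.numeric(out$value)) {
    suppressWarnings(v <- as.numeric(out$value))
    if (anyNA(v)) abort_stage("genotype_io", sprintf(
      "non-numeric trait value '%s' for sample '%s'",
      out$value[which(is.na(v))[1]], out$sample[which(is.na(v))[1]]))
    out$value <- v
  }
  if (any(!is.finite(out$value)))
    abort_stage("genotype_io", "non-finite trait values in phenotype CSV")
  if (!is.na(env_col)) out$env <- as.character(df[[env_col]])
  key <- if (is.null(out$env)) out$sample else paste(out$sample, out$env)
  if (anyDuplicated(key)) abort_stage("genotype_io", sprintf(
    "duplicate sample id within environment: '%s'", key[duplicated(key)][1]))
  out
}

#' Write a prediction table as CSV
#'
#' Emits `sample,prediction[,env]` with a header row.
#'
#' @param predictions data.frame with columns `sample`, `prediction` and
#'   optionally `env`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  stopifnot(all(c("sample", "prediction") %in% colnames(predictions)))
  cols <- c("sample", "prediction", intersect("env", colnames(predictions)))
  utils::write.csv(predictions[, cols, drop = FALSE], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
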