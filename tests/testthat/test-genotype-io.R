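test_that("VCF round trip reproduces the simulated dosage matrix and INFO metrics", {
  cfg <- tiny_cfg(n = 5, L = 3, missing_rate = 0.2)
  sim <- simulate_genotypes(cfg)
  tf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$genotypes, sim$variants, tf)
  rt <- read_vcf(tf)
  expect_identical(unname(rt$genotypes), unname(sim$genotypes))
  expect_identical(rownames(rt$genotypes), rownames(sim$genotypes))
  expect_equal(rt$variants$pos, sim$variants$pos)
  for (m in c("QD", "FS", "MQ", "SOR", "MQRankSum"))
    expect_equal(rt$variants[[m]], sim$variants[[m]], tolerance = 1e-4)
  expect_equal(rt$variants$missing_rate, sim$variants$missing_rate)
})

test_that("GT strings map to dosages per the alt-allele-count definition", {
  tf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3", "s4"), collapse = "\t"),
    paste(c("1", "100", ".", "A", "C", "50", ".", ".", "GT",
            "0/1", "1|0", "1/1", "0/0"), collapse = "\t"),
    paste(c("1", "200", ".", "G", "T", "50", ".", ".", "GT",
            "./.", "./.", "./.", "./."), collapse = "\t")), tf)
  d <- read_vcf(tf)
  expect_equal(unname(d$genotypes[, 1]), c(1L, 1L, 2L, 0L))
  expect_true(all(is.na(d$genotypes[, 2])))
  expect_equal(d$variants$missing_rate, c(0, 1))
  # INFO metrics absent from the file stay NA
  expect_true(all(is.na(d$variants$QD)))
})

test_that("multiallelic and non-diploid records are rejected with clear errors", {
  tf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1"), collapse = "\t"),
    paste(c("1", "100", ".", "A", "C,G", "50", ".", ".", "GT", "1/2"),
          collapse = "\t")), tf)
  expect_error(read_vcf(tf), "multiallelic")
  d <- read_vcf(tf, multiallelic = "first_alt")
  expect_true(is.na(d$genotypes[1, 1]))  # allele 2 treated as missing

  tf2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1"), collapse = "\t"),
    paste(c("1", "100", ".", "A", "C", "50", ".", ".", "GT", "0"),
          collapse = "\t")), tf2)
  expect_error(read_vcf(tf2), "non-diploid")
})

test_that("hard filters drop exactly the hand-enumerated violators", {
  vt <- ten_locus_table()
  keep <- filter_variants(vt)
  expect_equal(which(!keep), c(2L, 4L, 6L, 8L))
  expect_equal(sum(keep), 6L)

  # a QD just under the bound is dropped; exact boundary values are kept
  vt2 <- ten_locus_table()[1, ]
  vt2$QD <- 1.9
  expect_false(filter_variants(vt2))
  vt3 <- ten_locus_table()[1, ]
  vt3$QD <- 2.0; vt3$qual <- 30.0; vt3$FS <- 60.0; vt3$MQ <- 40.0
  vt3$SOR <- 3.0; vt3$MQRankSum <- -12.5
  expect_true(filter_variants(vt3))

  # missing-rate removal at >= 0.95; absent metrics never disqualify
  vt4 <- ten_locus_table()[1:2, ]
  vt4$QD <- NA; vt4$FS <- NA; vt4$MQ <- NA; vt4$SOR <- NA
  vt4$MQRankSum <- NA; vt4$qual <- NA
  vt4$missing_rate <- c(0.94, 0.95)
  expect_equal(filter_variants(vt4), c(TRUE, FALSE))
})

test_that("filter_variants is idempotent and order-equivariant", {
  cfg <- tiny_cfg(L = 40, bad_info_frac = 0.1)
  vt <- simulate_genotypes(cfg)$variants
  keep <- filter_variants(vt)
  expect_identical(filter_variants(vt[keep, ]), rep(TRUE, sum(keep)))
  set.seed(1)
  perm <- sample(nrow(vt))
  expect_identical(filter_variants(vt[perm, ]), keep[perm])
})

test_that("mode imputation matches a brute-force column mode with lower-dosage ties", {
  expect_equal(unname(impute_missing(
    matrix(c(0L, 0L, 2L, NA), 4, 1))[4, 1]), 0L)
  # tie between 0 and 2 -> lower dosage
  expect_equal(unname(impute_missing(
    matrix(c(0L, 2L, NA), 3, 1))[3, 1]), 0L)

  G <- tiny_panel(n = 40, L = 25)
  expect_identical(impute_missing(G), G)  # no missing: unchanged

  set.seed(9)
  Gm <- G
  Gm[sample(length(Gm), length(Gm) %/% 10)] <- NA
  Gi <- impute_missing(Gm)
  expect_false(anyNA(Gi))
  # non-missing entries never altered
  expect_identical(Gi[!is.na(Gm)], Gm[!is.na(Gm)])
  # brute-force per-column mode oracle
  for (j in seq_len(ncol(Gm))) {
    obs <- Gm[, j][!is.na(Gm[, j])]
    tab <- table(factor(obs, levels = 0:2))
    mode_j <- as.integer(names(tab)[which.max(tab)])
    expect_true(all(Gi[is.na(Gm[, j]), j] == mode_j))
  }
  # 100% missing locus cannot be imputed
  Gall <- G
  Gall[, 3] <- NA
  expect_error(impute_missing(Gall), "100% missing")
})

test_that("phenotype CSV reading validates and round-trips", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,value", "s1,1.5", "s2,2.5"), tf)
  ph <- read_phenotypes(tf)
  expect_equal(nrow(ph), 2)
  expect_equal(ph$value, c(1.5, 2.5))

  out <- withr::local_tempfile(fileext = ".csv")
  write_predictions(data.frame(sample = ph$sample, prediction = ph$value),
                    out)
  again <- utils::read.csv(out)
  expect_equal(again$prediction, ph$value)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,value", "s1,1.5", "s1,2.5"), bad)
  expect_error(read_phenotypes(bad), "duplicate")
  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,value", "s1,abc"), bad2)
  expect_error(read_phenotypes(bad2), "non-numeric")

  # same sample in two environments is legal
  ok <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,value,env", "s1,1.5,E1", "s1,2.5,E2"), ok)
  expect_equal(nrow(read_phenotypes(ok)), 2)
})
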