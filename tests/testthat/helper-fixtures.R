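# Shared fixture builders. Everything is generated in code at test time;
# no files ship with the package.

tiny_cfg <- function(n = 50, L = 30, ...) {
  sim_config(n = n, L = L, n_qtl = max(2L, min(8L, L %/% 3)), h2 = 0.9,
             seed = 101, ...)
}

tiny_panel <- function(n = 50, L = 30, ...) {
  sim <- simulate_genotypes(tiny_cfg(n, L, ...))
  sim$genotypes
}

# A 10-locus variant table in which exactly 4 loci violate one filter bound
# each (hand-enumerated truth: loci 2, 4, 6, 8 fail).
ten_locus_table <- function() {
  vt <- data.frame(
    chrom = "1", pos = 1:10 * 100,
    ref = "A", alt = "C",
    qual = rep(500, 10),
    QD = rep(20, 10), FS = rep(5, 10), MQ = rep(55, 10),
    SOR = rep(1, 10), MQRankSum = rep(0, 10),
    missing_rate = rep(0, 10), stringsAsFactors = FALSE)
  vt$QD[2] <- 1.9          # QD < 2.0
  vt$FS[4] <- 60.5         # FS > 60.0
  vt$MQ[6] <- 39.0         # MQ < 40.0
  vt$MQRankSum[8] <- -13   # MQRankSum < -12.5
  vt
}

write_bed <- function(df, path) {
  writeLines(paste(df$chrom, df$start0, df$end, df$name, df$score,
                   df$strand, sep = "\t"), path)
  path
}

write_gff3 <- function(df, path) {
  writeLines(c("##gff-version 3",
               paste(df$chrom, "test", df$type, df$start, df$end, ".",
                     df$strand, ".", paste0("ID=", df$id), sep = "\t")),
             path)
  path
}

expect_same_predictions <- function(p1, p2, tol = 0) {
  if (tol == 0) expect_identical(p1, p2) else
    expect_equal(p1, p2, tolerance = tol)
}
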