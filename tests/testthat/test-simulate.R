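test_that("genotype simulation honours inbred mode, MAF and reproducibility", {
  cfg <- sim_config(n = 2000, L = 40, n_qtl = 10, seed = 13)
  inb <- simulate_genotypes(cfg, inbred = TRUE)
  expect_false(any(inb$genotypes == 1L, na.rm = TRUE))
  out <- simulate_genotypes(cfg)
  # empirical allele frequency within 3 binomial SDs of the generating p
  phat <- colMeans(out$genotypes) / 2
  se <- sqrt(out$maf * (1 - out$maf) / (2 * cfg$n))
  z <- abs(phat - out$maf) / se
  expect_lt(max(z), 5)          # every locus consistent with binomial sampling
  expect_lt(mean(z), 1.5)       # and typical deviations near the expected ~0.8
  expect_identical(simulate_genotypes(cfg)$genotypes, out$genotypes)
  # INFO violations appear at the requested rate
  cfgb <- sim_config(n = 10, L = 100, n_qtl = 10, bad_info_frac = 0.05, seed = 13)
  vt <- simulate_genotypes(cfgb)$variants
  expect_equal(sum(!filter_variants(vt)), 25)   # 5 metrics x 5 loci
})

test_that("trait simulation hits the target heritability exactly", {
  cfg <- sim_config(n = 2000, L = 100, n_qtl = 20, h2 = 0.73, seed = 17)
  G <- impute_missing(simulate_genotypes(cfg)$genotypes)
  tr <- simulate_trait(G, cfg)
  realized <- var(tr$genetic) / var(tr$phenotypes$value)
  expect_equal(unname(realized), 0.73, tolerance = 0.02)
  # h2 = 1: phenotype equals the genetic value
  cfg1 <- sim_config(n = 50, L = 30, n_qtl = 10, h2 = 1, seed = 18)
  G1 <- impute_missing(simulate_genotypes(cfg1)$genotypes)
  tr1 <- simulate_trait(G1, cfg1)
  expect_equal(tr1$phenotypes$value, unname(tr1$genetic))
  # permuting samples permutes phenotypes consistently (same effects)
  perm <- sample(nrow(G1))
  tr_perm <- simulate_trait(G1[perm, ], cfg1, effects = tr1$effects)
  expect_equal(tr_perm$phenotypes$value, tr1$phenotypes$value[perm])
})

test_that("environment simulation has the documented shape and exact linear shifts", {
  cfg <- sim_config(n = 10, L = 10, n_qtl = 3, n_env = 5, env_days = 60, seed = 19)
  env <- simulate_environments(cfg)
  expect_equal(dim(env$weather), c(5 * 60, 13))    # env, date, 11 variables
  expect_equal(colnames(env$weather), c("env", "date", env_var_names))
  expect_length(env$shifts, 5)
  # the shifts are an exact (noise-free) linear function of the generating
  # per-environment variable means: a linear model recovers them perfectly
  means <- rowsum(as.matrix(env$weather[env_var_names]),
                  env$weather$env) / 60
  gen <- c("tempmax", "solarradiation", "precip")
  fit <- lm(env$shifts ~ means[, gen[1]] + means[, gen[2]] + means[, gen[3]])
  expect_gt(summary(fit)$r.squared, 0.99)
  # identical weather series would force identical shifts (linearity)
  raw <- as.vector(means %*% env$coefficients$raw)
  expect_equal(unname((raw - env$coefficients$center) *
                        env$coefficients$scale),
               unname(env$shifts), tolerance = 1e-9)
})

test_that("multi-environment traits carry genetic + shift + scaled noise", {
  cfg <- sim_config(n = 300, L = 50, n_qtl = 10, h2 = 0.5, n_env = 3,
                    env_days = 30, env_sd = 1, seed = 23)
  G <- impute_missing(simulate_genotypes(cfg)$genotypes)
  et <- simulate_env_trait(G, cfg)
  expect_equal(nrow(et$phenotypes), 300 * 3)
  # per-environment mean differences track the generated shifts
  m <- as.vector(tapply(et$phenotypes$value, et$phenotypes$env, mean)[
    names(et$shifts)])
  expect_equal(unname(m - mean(m)),
               unname(et$shifts - mean(et$shifts)), tolerance = 0.3)
  # shift scale is env_sd x genetic SD
  expect_equal(sd(et$shifts), sd(et$genetic), tolerance = 0.35)
})

test_that("cross-population simulation matches the exhaustive F1 oracle", {
  cfg <- sim_config(L = 60, n_qtl = 12, h2 = 0.8, seed = 29)
  cp <- simulate_cross_population(20, 30, cfg)
  expect_equal(nrow(cp$plan), 600)
  expect_equal(nrow(cp$f1_genotypes), 600)
  expect_false(any(cp$panel == 1L))
  # every F1 equals the per-locus expected-dosage table lookup
  lookup <- function(a, b) (a + b) / 2
  for (k in sample(600, 25)) {
    pa <- cp$panel[cp$plan$female[k], ]
    pb <- cp$panel[cp$plan$male[k], ]
    expect_identical(unname(cp$f1_genotypes[k, ]),
                     unname(lookup(pa, pb)))
  }
  # F1 of identical parents reproduces the parent's genetic value
  self_plan <- data.frame(female = "F001", male = "F001")
  f1self <- suppressWarnings(f1_genotypes(cp$panel, self_plan))
  ag <- asNamespace("autogs")
  expect_equal(unname(ag$genetic_values(f1self, cp$effects)),
               unname(ag$genetic_values(cp$panel["F001", , drop = FALSE],
                                        cp$effects)))
  # ground-truth best cross equals the brute-force argmax of genetic values
  expect_equal(cp$truth$order[1], unname(which.max(cp$genetic)))
  expect_equal(cp$truth$best$female,
               cp$plan$female[which.max(cp$genetic)])
})

test_that("written fixtures re-read by genotype_io reproduce the objects", {
  cfg <- sim_config(n = 12, L = 8, n_qtl = 3, missing_rate = 0.1, seed = 37)
  sim <- simulate_genotypes(cfg)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$genotypes, sim$variants, vcf)
  rt <- read_vcf(vcf)
  expect_identical(rt$genotypes, sim$genotypes)

  tr <- simulate_trait(impute_missing(sim$genotypes), cfg)
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tr$phenotypes, csv, row.names = FALSE, quote = FALSE)
  ph <- read_phenotypes(csv)
  expect_equal(ph$value, tr$phenotypes$value)

  env <- simulate_environments(cfg)
  ecsv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(env$weather, ecsv, row.names = FALSE, quote = FALSE)
  expect_equal(read_env_csv(ecsv)[, env_var_names],
               env$weather[, env_var_names], tolerance = 1e-12,
               ignore_attr = TRUE)
})
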