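# Build a gs_weights object whose predictions are exactly the true
# additive genetic values (identity scalers + the true effect vector in a
# linear-SVM state). Used as the "true linear model" predictor in the
# parent-selection oracles.
true_linear_weights <- function(panel, effects) {
  L <- ncol(panel)
  w <- numeric(L)
  w[effects$qtl] <- effects$beta
  structure(list(
    spec = model_spec("SVM"),
    model_state = list(w = w, b = 0,
                       xs = list(mu = rep(0, L), sd = rep(1, L)),
                       ys = list(mu = 0, sd = 1)),
    encoding = list(kind = "dosage_vector", locus_map = colnames(panel),
                    pca = NULL, env_mode = "weekly", env_window = NULL,
                    env_features = NULL),
    training = list(seed = 1L), r_test = 1,
    version = as.character(utils::packageVersion("autogs"))),
    class = "gs_weights")
}

test_that("make_f1_genotype implements the expected-dosage cross of homozygotes", {
  expect_equal(make_f1_genotype(c(0, 2, 2), c(2, 2, 0)), c(1, 2, 1))
  p <- c(0, 2, 0, 2)
  expect_equal(make_f1_genotype(p, p), p)   # identical parents
  expect_warning(make_f1_genotype(c(1, 0), c(0, 0)), "heterozygous")
  expect_error(make_f1_genotype(c(0, 2), c(0, 2, 2)), "length")
})

test_that("f1_genotypes equals the exhaustive per-locus lookup on a 20x30 panel", {
  cfg <- sim_config(L = 40, n_qtl = 10, seed = 71)
  cp <- simulate_cross_population(20, 30, cfg)
  F1 <- cp$f1_genotypes
  expect_equal(nrow(F1), 600)
  brute <- t(vapply(seq_len(600), function(k)
    (cp$panel[cp$plan$female[k], ] + cp$panel[cp$plan$male[k], ]) / 2,
    numeric(ncol(cp$panel))))
  expect_equal(unname(F1), unname(brute))
  expect_error(f1_genotypes(cp$panel,
                            data.frame(female = "F001", male = "nope")),
               "unknown parent")
})

test_that("select_parents with the true model finds the brute-force argmax", {
  cfg <- sim_config(L = 60, n_qtl = 12, h2 = 0.8, seed = 73)
  cp <- simulate_cross_population(20, 30, cfg)
  w <- true_linear_weights(cp$panel, cp$effects)
  rk <- select_parents(cp$panel, cp$plan, w)
  # rank-1 pair equals the exhaustive argmax over all 600 true F1 values
  best <- which.max(cp$genetic)
  expect_equal(rk$female[1], cp$plan$female[best])
  expect_equal(rk$male[1], cp$plan$male[best])
  expect_equal(rk$rank, 1:600)
  expect_equal(sum(rk$top5), 5)
  # minimize reverses the ranking exactly (predictions are all distinct)
  rk_min <- select_parents(cp$panel, cp$plan, w, direction = "minimize")
  expect_equal(rk_min$prediction, rev(rk$prediction))
  # ranking is invariant under pair relabeling (ids only)
  panel2 <- cp$panel
  rownames(panel2) <- paste0("x", rownames(panel2))
  plan2 <- data.frame(female = paste0("x", cp$plan$female),
                      male = paste0("x", cp$plan$male))
  w2 <- true_linear_weights(panel2, cp$effects)
  rk2 <- select_parents(panel2, plan2, w2)
  expect_equal(rk2$prediction, rk$prediction)
  # single-pair plan: that pair is rank 1 and the whole top-5 set
  rk1 <- select_parents(cp$panel, cp$plan[1, ], w)
  expect_equal(rk1$rank, 1L)
  expect_true(all(rk1$top5))
  expect_error(select_parents(cp$panel, cp$plan[0, ], w), "empty")
})

test_that("pre-supplied F1 genotypes are honoured", {
  cfg <- sim_config(L = 30, n_qtl = 8, seed = 79)
  cp <- simulate_cross_population(5, 4, cfg)
  w <- true_linear_weights(cp$panel, cp$effects)
  rk_built <- select_parents(cp$panel, cp$plan, w)
  rk_given <- select_parents(NULL, cp$plan, w, f1_geno = cp$f1_genotypes)
  expect_equal(rk_given, rk_built)
  expect_error(select_parents(NULL, cp$plan, w,
                              f1_geno = cp$f1_genotypes[1:3, ]),
               "do not match")
})

test_that("run_train_predict equals run_train followed by run_predict byte-for-byte", {
  cfg <- sim_config(n = 60, L = 30, n_qtl = 8, h2 = 0.9,
                    missing_rate = 0.05, seed = 83)
  sim <- simulate_genotypes(cfg)
  tr <- simulate_trait(impute_missing(sim$genotypes), cfg)
  td <- withr::local_tempdir()
  vcf <- file.path(td, "g.vcf")
  phe <- file.path(td, "p.csv")
  write_vcf(sim$genotypes, sim$variants, vcf)
  utils::write.csv(tr$phenotypes, phe, row.names = FALSE, quote = FALSE)

  res1 <- run_train(vcf, phe, "SVM", file.path(td, "w1.agsw"), seed = 5)
  res2 <- run_predict(vcf, file.path(td, "w1.agsw"),
                      file.path(td, "pred_a.csv"))
  res3 <- run_train_predict(vcf, phe, "SVM", file.path(td, "w2.agsw"),
                            file.path(td, "pred_b.csv"), seed = 5)
  expect_identical(readLines(file.path(td, "pred_a.csv")),
                   readLines(file.path(td, "pred_b.csv")))
  # train-then-predict on the training VCF is self-consistent with r_test
  split <- split_811(60, 5)
  joined <- merge(res2$predictions, tr$phenotypes, by = "sample")
  r_all <- pearson_r(joined$prediction, joined$value)
  expect_gt(r_all, 0.8)
  # manifests exist and carry input hashes
  mf <- jsonlite::read_json(res1$manifest_path)
  expect_equal(mf$command, "train")
  expect_equal(mf$inputs$vcf$md5, unname(tools::md5sum(vcf)))
})

test_that("workflow runners propagate stage-named errors", {
  td <- withr::local_tempdir()
  expect_error(run_train(file.path(td, "missing.vcf"), "p.csv", "SVM",
                         file.path(td, "w.agsw")),
               "genotype_io")
  cfg <- sim_config(n = 30, L = 12, n_qtl = 4, seed = 89)
  sim <- simulate_genotypes(cfg)
  tr <- simulate_trait(impute_missing(sim$genotypes), cfg)
  vcf <- file.path(td, "g.vcf")
  phe <- file.path(td, "p.csv")
  write_vcf(sim$genotypes, sim$variants, vcf)
  utils::write.csv(tr$phenotypes, phe, row.names = FALSE, quote = FALSE)
  expect_error(run_train(vcf, phe, "EnvSE", file.path(td, "w.agsw")),
               "requires --env")
})

test_that("run_select_parents writes full ranking plus top-5 subset", {
  cfg <- sim_config(n = 40, L = 25, n_qtl = 6, h2 = 0.9, seed = 97)
  cp <- simulate_cross_population(6, 5, cfg)
  td <- withr::local_tempdir()
  pvcf <- file.path(td, "panel.vcf")
  write_vcf(cp$panel, cp$variants, pvcf)
  lines <- file.path(td, "lines.txt")
  writeLines(c("# inbred lines", paste0(cp$females, ",female"),
               paste0(cp$males, ",male")), lines)
  # train a quick model on the F1s themselves
  w <- gs_train(cp$f1_genotypes, cp$f1_phenotypes,
                model_spec("SVM", seed = 2))
  wp <- file.path(td, "w.agsw")
  save_weights(w, wp)
  out <- file.path(td, "rank.csv")
  res <- run_select_parents(pvcf, lines, wp, out)
  expect_equal(nrow(res$ranking), 30)
  top <- utils::read.csv(res$top5_csv)
  expect_equal(nrow(top), 5)
  expect_equal(top$rank, 1:5)
})
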