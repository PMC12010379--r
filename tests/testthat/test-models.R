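make_additive_fixture <- function(n = 64, L = 100, seed = 55, h2 = 0.9) {
  cfg <- sim_config(n = n, L = L, n_qtl = 15, h2 = h2, seed = seed)
  G <- impute_missing(simulate_genotypes(cfg)$genotypes)
  tr <- simulate_trait(G, cfg)
  list(G = G, y = tr$phenotypes$value, cfg = cfg, effects = tr$effects)
}

test_that("model_spec validates names and encoding compatibility", {
  err <- tryCatch(model_spec("BLUP"), error = conditionMessage)
  expect_match(err, "SVM.*XGBoost.*GBDT.*MLP.*RF.*DeepGS.*DLGWAS.*DNNGP.*SoyDNGP.*EnvSE")
  expect_error(model_spec("DLGWAS", encoding = "dosage_vector"),
               "requires encoding 'onehot_4xL'")
  expect_equal(model_spec("DNNGP")$encoding, "pca_150")
  # user hyper overrides the per-model default
  expect_equal(model_spec("DeepGS")$hyper$pool, 2)
  expect_equal(model_spec("DeepGS", hyper = list(pool = 4))$hyper$pool, 4)
})

test_that("seeded builds are deterministic: same spec + data -> identical predictions", {
  fx <- make_additive_fixture()
  X <- encode_dosage(fx$G)$tensor
  for (nm in c("RF", "XGBoost", "MLP")) {
    p <- lapply(1:2, function(i) {
      m <- build_model(model_spec(nm, seed = 7))
      m$fit(X, fx$y, config = gs_config(epochs = 15))
      m$predict(X)
    })
    expect_identical(p[[1]], p[[2]])
  }
})

test_that("every model beats the mean on a separable additive trait", {
  fx <- make_additive_fixture(n = 64, L = 100)
  vy <- var(fx$y)
  cfgq <- gs_config(epochs = 40)
  for (nm in c("SVM", "XGBoost", "GBDT", "MLP", "RF", "DeepGS", "DLGWAS",
               "DNNGP", "SoyDNGP")) {
    spec <- model_spec(nm, seed = 4)
    X <- switch(spec$encoding,
      dosage_vector = encode_dosage(fx$G)$tensor,
      onehot_4xL = encode_onehot_4xL(fx$G)$tensor,
      soy_3xSxS = encode_soy(fx$G)$tensor,
      pca_150 = suppressWarnings(
        apply_pca(fx$G, fit_pca(fx$G, 150))$tensor))
    m <- build_model(spec)
    m$fit(X, fx$y, config = cfgq)
    mse <- mean((m$predict(X) - fx$y)^2)
    expect_lt(mse, vy, label = paste(nm, "training MSE"))
  }
})

test_that("DeepGS contract: conv/pool/fc/relu/dropout(0.05), (batch, 1) output, eval determinism", {
  ag <- asNamespace("autogs")
  net <- ag$make_deepgs_net(model_spec("DeepGS"), c(5, 1, 60))
  types <- vapply(net$layers, function(l) l$type, character(1))
  expect_true(all(c("conv1d", "dense", "relu", "dropout") %in% types))
  drop_p <- net$layers[[which(types == "dropout")]]$p
  expect_equal(drop_p, 0.05)
  x <- array(rnorm(5 * 60), c(5, 1, 60))
  y1 <- net$forward(x, training = FALSE)
  expect_equal(dim(y1), c(5, 1))
  expect_identical(y1, net$forward(x, training = FALSE))
  # dropout is active only in training mode
  set.seed(1); t1 <- net$forward(x, training = TRUE)
  set.seed(2); t2 <- net$forward(x, training = TRUE)
  expect_false(identical(t1, t2))
})

test_that("DLGWAS contract: equal-length branches, additive merge, eval determinism", {
  ag <- asNamespace("autogs")
  x <- array(rnorm(4 * 4 * 50), c(4, 4, 50))
  set.seed(99)
  net <- ag$make_dlgwas_net(model_spec("DLGWAS"), c(4, 4, 50))
  y_full <- net$forward(x, FALSE)
  expect_equal(dim(y_full), c(4, 1))
  # branch outputs are cropped to a common length before the add-up merge
  expect_gte(min(net$l1, net$l2), net$lmin)
  expect_identical(y_full, net$forward(x, FALSE))
  # zeroing the large-kernel branch reproduces the single-branch network
  conv2 <- net$layers[[2]]
  conv2$W[] <- 0; conv2$b[] <- 0
  y_zeroed <- net$forward(x, FALSE)
  set.seed(99)
  ref <- ag$make_dlgwas_net(model_spec("DLGWAS"), c(4, 4, 50))
  adapter_out <- aperm(x, c(2, 3, 1))
  b1 <- ref$layers[[1]]$forward(adapter_out, FALSE)
  z <- b1[, seq_len(ref$lmin), , drop = FALSE]
  for (lay in ref$layers[3:length(ref$layers)]) z <- lay$forward(z, FALSE)
  expect_equal(y_zeroed, z, tolerance = 1e-12)
})

test_that("DNNGP contract: exactly three conv layers, one dropout, (batch, 1) output", {
  ag <- asNamespace("autogs")
  net <- ag$make_dnngp_net(model_spec("DNNGP"), c(7, 1, 150))
  types <- vapply(net$layers, function(l) l$type, character(1))
  expect_equal(sum(types == "conv1d"), 3)
  expect_equal(sum(types == "dropout"), 1)
  x <- array(rnorm(7 * 150), c(7, 1, 150))
  expect_equal(dim(net$forward(x, FALSE)), c(7, 1))
})

test_that("SoyDNGP contract: small S accepted, channel schedule independent of S", {
  ag <- asNamespace("autogs")
  spec <- model_spec("SoyDNGP", hyper = list(blocks = 4))
  sched <- function(S) {
    net <- ag$make_soydngp_net(spec, c(2, 3, S, S))
    x <- array(rnorm(2 * 3 * S * S), c(2, 3, S, S))
    out <- net$forward(x, FALSE)
    expect_equal(dim(out), c(2, 1))
    types <- vapply(net$layers, function(l) l$type, character(1))
    vapply(net$layers[types == "conv2d"], function(l) l$out_ch, numeric(1))
  }
  s8 <- sched(8)    # 4 blocks at S = 8 must propagate without shape errors
  s16 <- sched(16)
  expect_equal(s8, s16)          # doubling S leaves the channel schedule
  expect_equal(s8, c(16, 32, 64, 128))
  net <- ag$make_soydngp_net(spec, c(2, 3, 8, 8))
  x <- array(rnorm(2 * 3 * 64), c(2, 3, 8, 8))
  expect_identical(net$forward(x, FALSE), net$forward(x, FALSE))
})

test_that("EnvSE contract: 64-dim embedding, identity gating, environment sensitivity", {
  ag <- asNamespace("autogs")
  set.seed(12)
  net <- ag$make_envse_net(model_spec("EnvSE"), L = 60, n_env_feat = 22)
  # embedding layer maps env features to 64 dimensions
  expect_equal(ncol(net$layers[[length(net$layers) - 1]]$W), 64)
  x <- list(geno = array(rnorm(4 * 60), c(4, 1, 60)),
            env = matrix(rnorm(4 * 22), 4, 22))
  # gates pinned to 1 reproduce the genotype-only backbone exactly
  net$pin_gates <- TRUE
  expect_identical(net$forward(x, FALSE), net$forward_backbone(x$geno))
  net$pin_gates <- FALSE
  # same genotype, different environment -> different output;
  # identical environments -> identical outputs
  x2 <- list(geno = x$geno[c(1, 1, 1, 1), , , drop = FALSE],
             env = rbind(x$env[1, ], x$env[1, ], x$env[2, ], x$env[2, ]))
  out <- as.vector(net$forward(x2, FALSE))
  expect_equal(out[1], out[2])
  expect_equal(out[3], out[4])
  expect_false(isTRUE(all.equal(out[1], out[3])))
})

test_that("EnvSE training refuses unknown environment ids", {
  cfg <- sim_config(n = 30, L = 20, n_qtl = 5, h2 = 0.6, n_env = 2,
                    env_days = 14, seed = 9)
  G <- impute_missing(simulate_genotypes(cfg)$genotypes)
  et <- simulate_env_trait(G, cfg)
  ph <- et$phenotypes
  ph$env[1] <- "NOPE"
  expect_error(
    gs_train(G, ph, model_spec("EnvSE", seed = 1),
             gs_config(epochs = 2), env_data = et$weather),
    "unknown environment")
})

test_that("aggregate_env bins daily series as specified", {
  set.seed(3)
  series <- as.data.frame(matrix(rnorm(28 * 11, 10), 28, 11,
                                 dimnames = list(NULL, env_var_names)))
  expect_length(aggregate_env(series, "biweekly"), 22)   # 11 x 2 bins
  expect_length(aggregate_env(series, "daily"), 11 * 28)
  # weekly means equal a hand-computed 7-day average
  wk <- aggregate_env(series, "weekly")
  hand <- as.vector(sapply(env_var_names, function(v)
    c(mean(series[[v]][1:7]), mean(series[[v]][8:14]),
      mean(series[[v]][15:21]), mean(series[[v]][22:28]))))
  expect_equal(unname(wk), hand)
  # partial trailing bin averages its available days
  wk2 <- aggregate_env(series[1:10, ], "weekly")
  expect_equal(unname(wk2[2]), mean(series[[1]][8:10]))
  # constant series: all modes yield the same repeated values
  const <- as.data.frame(matrix(5, 28, 11,
                                dimnames = list(NULL, env_var_names)))
  expect_true(all(aggregate_env(const, "daily") == 5))
  expect_true(all(aggregate_env(const, "weekly") == 5))
  expect_true(all(aggregate_env(const, "biweekly") == 5))
})
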