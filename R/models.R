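#' @title The genomic-prediction model pool
#' @description Ten regressors behind one contract (`fit`, `predict`,
#'   `state`, `restore`): five classical ML models (SVM, XGBoost, GBDT, MLP,
#'   RF), four convolutional genomic-prediction architectures (DeepGS,
#'   DLGWAS, DNNGP, SoyDNGP) and an environment-gated CNN (EnvSE) that
#'   squeezes an 11-variable weather summary into a 64-dimensional embedding
#'   used to reweight convolutional feature maps. Each model is tied to a
#'   genotype encoding; [model_spec()] enforces the pairing.
#' @name model_pool
NULL

model_names <- c("SVM", "XGBoost", "GBDT", "MLP", "RF",
                 "DeepGS", "DLGWAS", "DNNGP", "SoyDNGP", "EnvSE")

model_encoding_table <- c(
  SVM = "dosage_vector", XGBoost = "dosage_vector", GBDT = "dosage_vector",
  MLP = "dosage_vector", RF = "dosage_vector", DeepGS = "dosage_vector",
  DLGWAS = "onehot_4xL", DNNGP = "pca_150", SoyDNGP = "soy_3xSxS",
  EnvSE = "dosage_vector")

#' Specify a genomic-prediction model
#'
#' @param name one of `SVM`, `XGBoost`, `GBDT`, `MLP`, `RF`, `DeepGS`,
#'   `DLGWAS`, `DNNGP`, `SoyDNGP`, `EnvSE`.
#' @param encoding genotype encoding kind; defaults to the encoding the
#'   model requires and must be compatible with it (ML models and DeepGS use
#'   `dosage_vector`; DLGWAS `onehot_4xL`; DNNGP `pca_150`; SoyDNGP
#'   `soy_3xSxS`; EnvSE `dosage_vector` plus environment features).
#' @param hyper named list of hyperparameter overrides (see the model
#'   builders' defaults in the source). User-supplied values win over the
#'   per-model defaults below.
#' @param seed integer seed driving every stochastic component of the model.
#' @details The CNN layer *types* follow the published architectures; exact
#'   widths, kernels and regularization are documented package defaults,
#'   calibrated once for desk-scale panels (hundreds of loci, a few
#'   thousand samples) and exposed as hyperparameters: DeepGS 8 filters,
#'   kernel 18, average-pool 2; DLGWAS kernels 4 and 20, 8 filters each;
#'   DNNGP three 1x1 convolutions (64, 32, 16 channels) on the 150
#'   principal components, weight decay 1; SoyDNGP one 3x3 VGG block at 16
#'   channels with 2x2 downsampling (deeper stacks via `blocks`); EnvSE a
#'   DeepGS-style backbone with a 64-unit environment embedding gating the
#'   conv channels.
#' @return a `model_spec` object.
#' @export
model_spec <- function(name, encoding = NULL, hyper = list(), seed = 1L) {
  if (!name %in% model_names)
    abort_stage("model_pool", paste0(
      "unknown model '", name, "'; valid names: ",
      paste(model_names, collapse = ", ")))
  required <- unname(model_encoding_table[name])
  if (is.null(encoding)) encoding <- required
  if (encoding != required)
    abort_stage("model_pool", sprintf(
      "model %s requires encoding '%s', got '%s'", name, required, encoding))
  defaults <- model_hyper_defaults[[name]] %||% list()
  for (k in names(defaults))
    if (is.null(hyper[[k]])) hyper[[k]] <- defaults[[k]]
  structure(list(name = name, encoding = encoding, hyper = hyper,
                 seed = as.integer(seed)), class = "model_spec")
}

# Desk-scale defaults calibrated on synthetic additive panels; every value
# can be overridden through model_spec(hyper = ...).
model_hyper_defaults <- list(
  DeepGS = list(pool = 2),
  DLGWAS = list(filters = 8, pool = 2),
  DNNGP = list(kernel = 1, weight_decay = 1),
  SoyDNGP = list(blocks = 1),
  EnvSE = list(pool = 2))

hp <- function(spec, key, default) spec$hyper[[key]] %||% default

new_regressor <- function(spec) {
  r <- new.env(parent = emptyenv())
  r$spec <- spec
  class(r) <- "gs_regressor"
  r
}

# ---- feature / response scaling helpers (train statistics only) --------

fit_col_scaler <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  s[!is.finite(s) | s < 1e-12] <- 1
  list(mu = mu, sd = s)
}

apply_col_scaler <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$sd, `/`)

fit_y_scaler <- function(y) {
  s <- stats::sd(y)
  list(mu = mean(y), sd = if (!is.finite(s) || s < 1e-12) 1 else s)
}

# ---- classical ML models ------------------------------------------------

# Linear epsilon-insensitive SVR trained on the primal objective with Adam.
build_svm <- function(spec) {
  r <- new_regressor(spec)
  r$fit <- function(X, y, Xval = NULL, yval = NULL, config = gs_config()) {
    set.seed(spec$seed)
    eps <- hp(spec, "epsilon", 0.1)
    lambda <- hp(spec, "lambda", 1e-4)
    iters <- hp(spec, "iters", 400)
    lr <- hp(spec, "lr", 0.05)
    r$xs <- fit_col_scaler(X); r$ys <- fit_y_scaler(y)
    Xs <- apply_col_scaler(X, r$xs)
    ys <- (y - r$ys$mu) / r$ys$sd
    p <- ncol(Xs)
    w <- rep(0, p); b <- 0
    mw <- rep(0, p); vw <- rep(0, p); mb <- vb <- 0
    best <- Inf; best_w <- w; best_b <- b
    has_val <- !is.null(Xval) && nrow(Xval) > 0
    if (has_val) {
      Xv <- apply_col_scaler(Xval, r$xs)
      yv <- (yval - r$ys$mu) / r$ys$sd
    }
    for (t in seq_len(iters)) {
      res <- as.vector(Xs %*% w) + b - ys
      act <- abs(res) > eps
      gr <- sign(res) * act
      gw <- as.vector(crossprod(Xs, gr)) / length(ys) + 2 * lambda * w
      gb <- mean(gr)
      mw <- 0.9 * mw + 0.1 * gw; vw <- 0.999 * vw + 0.001 * gw^2
      mb <- 0.9 * mb + 0.1 * gb; vb <- 0.999 * vb + 0.001 * gb^2
      bc1 <- 1 - 0.9^t; bc2 <- 1 - 0.999^t
      w <- w - lr * (mw / bc1) / (sqrt(vw / bc2) + 1e-8)
      b <- b - lr * (mb / bc1) / (sqrt(vb / bc2) + 1e-8)
      if (has_val && t %% 10 == 0) {
        vmse <- mean((as.vector(Xv %*% w) + b - yv)^2)
        if (vmse < best) { best <- vmse; best_w <- w; best_b <- b }
      }
    }
    if (has_val && is.finite(best)) { w <- best_w; b <- best_b }
    r$w <- w; r$b <- b
    invisible(r)
  }
  r$predict <- function(X) {
    Xs <- apply_col_scaler(X, r$xs)
    (as.vector(Xs %*% r$w) + r$b) * r$ys$sd + r$ys$mu
  }
  r$state <- function() list(w = r$w, b = r$b, xs = r$xs, ys = r$ys)
  r$restore <- function(s) { r$w <- s$w; r$b <- s$b; r$xs <- s$xs; r$ys <- s$ys }
  r
}

# Shared tree-ensemble machinery (C++ exact-greedy trees).
build_forest <- function(spec) {
  r <- new_regressor(spec)
  r$fit <- function(X, y, Xval = NULL, yval = NULL, config = gs_config()) {
    set.seed(spec$seed)
    ntree <- hp(spec, "num_trees", 200)
    mtry <- hp(spec, "mtry", max(1L, floor(ncol(X) / 3)))
    max_depth <- hp(spec, "max_depth", 15)
    min_node <- hp(spec, "min_node", 5)
    r$center <- mean(y)
    g <- -(y - r$center)
    h <- rep(1, length(y))
    r$trees <- vector("list", ntree)
    for (t in seq_len(ntree)) {
      rows <- sample.int(nrow(X), replace = TRUE) - 1L
      cols <- sample.int(ncol(X), mtry) - 1L
      r$trees[[t]] <- cpp_build_tree(X, g, h, rows, cols, max_depth,
                                     0, 0, min_node)
    }
    invisible(r)
  }
  r$predict <- function(X) {
    acc <- numeric(nrow(X))
    for (tr in r$trees) acc <- acc + cpp_predict_tree(tr, X)
    r$center + acc / length(r$trees)
  }
  r$state <- function() list(trees = r$trees, center = r$center)
  r$restore <- function(s) { r$trees <- s$trees; r$center <- s$center }
  r
}

# Gradient boosting on residuals; XGBoost-style adds second-order
# regularization (lambda), gamma pruning and row/column subsampling.
build_boost <- function(spec, regularized) {
  r <- new_regressor(spec)
  r$fit <- function(X, y, Xval = NULL, yval = NULL, config = gs_config()) {
    set.seed(spec$seed)
    rounds <- hp(spec, "num_rounds", 300)
    eta <- hp(spec, "eta", if (regularized) 0.1 else 0.05)
    max_depth <- hp(spec, "max_depth", if (regularized) 4 else 3)
    lambda <- if (regularized) hp(spec, "lambda", 1.0) else 0
    gamma <- if (regularized) hp(spec, "gamma", 0.0) else 0
    min_child <- hp(spec, "min_child_weight", if (regularized) 5 else 10)
    subsample <- if (regularized) hp(spec, "subsample", 0.8) else 1
    colsample <- if (regularized) hp(spec, "colsample", 0.8) else 1
    patience <- hp(spec, "patience", 20)
    n <- nrow(X); p <- ncol(X)
    r$center <- mean(y)
    pred <- rep(r$center, n)
    has_val <- !is.null(Xval) && nrow(Xval) > 0
    if (has_val) pv <- rep(r$center, nrow(Xval))
    trees <- vector("list", rounds)
    best_round <- 0L; best_val <- Inf; wait <- 0L
    for (t in seq_len(rounds)) {
      g <- pred - y              # d/dpred of 0.5*(pred-y)^2
      h <- rep(1, n)
      rows <- if (subsample < 1)
        sample.int(n, floor(subsample * n)) - 1L else seq_len(n) - 1L
      cols <- if (colsample < 1)
        sample.int(p, max(1L, floor(colsample * p))) - 1L else seq_len(p) - 1L
      tr <- cpp_build_tree(X, g, h, rows, cols, max_depth, lambda, gamma,
                           min_child)
      trees[[t]] <- tr
      pred <- pred + eta * cpp_predict_tree(tr, X)
      if (has_val) {
        pv <- pv + eta * cpp_predict_tree(tr, Xval)
        vmse <- mean((pv - yval)^2)
        if (vmse < best_val - 1e-12) {
          best_val <- vmse; best_round <- t; wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= patience) break
        }
      } else best_round <- t
    }
    r$trees <- trees[seq_len(best_round)]
    r$eta <- eta
    invisible(r)
  }
  r$predict <- function(X) {
    acc <- numeric(nrow(X))
    for (tr in r$trees) acc <- acc + cpp_predict_tree(tr, X)
    r$center + r$eta * acc
  }
  r$state <- function() list(trees = r$trees, center = r$center, eta = r$eta)
  r$restore <- function(s) {
    r$trees <- s$trees; r$center <- s$center; r$eta <- s$eta
  }
  r
}

# ---- neural-network models ---------------------------------------------

# Wraps an nn_sequential (or custom net) with train-set x/y standardization
# and the Adam/MSE early-stopping loop.
build_nn_regressor <- function(spec, make_net, reshape_x,
                               scale_x = TRUE) {
  r <- new_regressor(spec)
  r$fit <- function(X, y, Xval = NULL, yval = NULL, config = gs_config()) {
    set.seed(spec$seed)
    if (scale_x) {
      r$xs <- fit_col_scaler(flatten2d(X))
      X <- unflatten(apply_col_scaler(flatten2d(X), r$xs), dim(X))
      if (!is.null(Xval) && input_n(Xval) > 0)
        Xval <- unflatten(apply_col_scaler(flatten2d(Xval), r$xs), dim(Xval))
    }
    r$ys <- fit_y_scaler(y)
    ys <- (y - r$ys$mu) / r$ys$sd
    yvs <- if (!is.null(yval)) (yval - r$ys$mu) / r$ys$sd
    r$net <- make_net(spec, dim(X))
    hist <- nn_fit(r$net, reshape_x(X), ys,
                   if (!is.null(Xval) && input_n(Xval) > 0) reshape_x(Xval),
                   yvs,
                   batch_size = config$batch_size, epochs = config$epochs,
                   patience = config$patience, lr = config$lr,
                   weight_decay = hp(spec, "weight_decay",
                                     config$weight_decay %||% 0),
                   seed = spec$seed)
    r$history <- hist
    r$in_dim <- dim(X)
    invisible(r)
  }
  r$predict <- function(X) {
    if (scale_x)
      X <- unflatten(apply_col_scaler(flatten2d(X), r$xs), dim(X))
    p <- as.vector(r$net$forward(reshape_x(X), training = FALSE))
    p * r$ys$sd + r$ys$mu
  }
  r$state <- function() list(net = nn_get_state(r$net), xs = r$xs,
                             ys = r$ys, in_dim = r$in_dim,
                             history = r$history)
  r$restore <- function(s) {
    r$xs <- s$xs; r$ys <- s$ys; r$in_dim <- s$in_dim; r$history <- s$history
    set.seed(spec$seed)
    dummy <- s$in_dim
    r$net <- make_net(spec, dummy)
    nn_set_state(r$net, s$net)
  }
  r
}

flatten2d <- function(X) {
  d <- dim(X)
  matrix(X, d[1], prod(d[-1]))
}

unflatten <- function(M, d) array(M, d)

as_conv1d <- function(X) {
  if (length(dim(X)) == 3) return(X)
  array(X, c(nrow(X), 1, ncol(X)))
}

make_mlp_net <- function(spec, d) {
  hidden <- hp(spec, "hidden", c(64, 32))
  dropout <- hp(spec, "dropout", 0.1)
  L <- prod(d[-1])
  layers <- list()
  inf <- L
  for (hsz in hidden) {
    layers <- c(layers, list(nn_dense(inf, hsz), nn_relu(),
                             nn_dropout(dropout)))
    inf <- hsz
  }
  nn_sequential(c(layers, list(nn_dense(inf, 1))))
}

# DeepGS: conv -> pool -> fully connected -> ReLU -> dropout(0.05) -> output
make_deepgs_net <- function(spec, d) {
  filters <- hp(spec, "filters", 8)
  kernel <- hp(spec, "kernel", 18)
  pool <- hp(spec, "pool", 4)
  fc <- hp(spec, "fc", 32)
  dropout <- hp(spec, "dropout", 0.05)
  L <- d[length(d)]
  Lout <- (L - kernel + 1) %/% pool
  nn_sequential(list(
    nn_batch_to_last(), nn_conv1d(1, filters, kernel), nn_relu(),
    nn_pool1d(pool, hp(spec, "pool_type", "avg")), nn_flatten(),
    nn_dense(filters * Lout, fc),
    nn_relu(), nn_dropout(dropout), nn_dense(fc, 1)))
}

# DNNGP: exactly three conv layers on the 150-vector, then FC, one dropout.
make_dnngp_net <- function(spec, d) {
  ch <- hp(spec, "channels", c(64, 32, 16))
  stopifnot(length(ch) == 3)
  dropout <- hp(spec, "dropout", 0.1)
  fc <- hp(spec, "fc", 64)
  kw <- hp(spec, "kernel", 3)
  pd <- (kw - 1) %/% 2
  k <- d[length(d)]
  nn_sequential(list(
    nn_batch_to_last(), nn_conv1d(1, ch[1], kw, pad = pd), nn_relu(),
    nn_conv1d(ch[1], ch[2], kw, pad = pd), nn_relu(),
    nn_conv1d(ch[2], ch[3], kw, pad = pd), nn_relu(),
    nn_dropout(dropout), nn_flatten(),
    nn_dense(ch[3] * k, fc), nn_relu(), nn_dense(fc, 1)))
}

# SoyDNGP: VGG-style 3x3 blocks with channel doubling and 2x2 pooling on
# the (3, S, S) tensor; pooling is skipped once the map is 1 pixel wide.
make_soydngp_net <- function(spec, d) {
  base <- hp(spec, "base_channels", 16)
  nblocks <- hp(spec, "blocks", 4)
  fc <- hp(spec, "fc", 64)
  S <- d[3]
  layers <- list(nn_batch_to_last())
  inc <- d[2]; size <- S
  ch <- base
  for (b in seq_len(nblocks)) {
    layers <- c(layers, list(nn_conv2d(inc, ch, 3, pad = 1), nn_relu()))
    if (size >= 2) {
      layers <- c(layers, list(nn_pool2d(2, hp(spec, "pool_type", "avg"))))
      size <- size %/% 2
    }
    inc <- ch
    if (b < nblocks) ch <- ch * 2
  }
  nn_sequential(c(layers, list(
    nn_flatten(), nn_dense(inc * size * size, fc), nn_relu(),
    nn_dense(fc, 1))))
}

#' Build a regressor from a model specification
#'
#' Returns an object exposing `fit(X, y, Xval, yval, config)`,
#' `predict(X)`, `state()` and `restore(state)`. `X` is the tensor of the
#' spec's encoding (`EnvSE` takes `list(geno = , env = )`). All stochastic
#' components (initialization, bagging, shuffling, dropout) are seeded from
#' `spec$seed`, so two builds fitted on the same data give identical
#' predictions.
#'
#' @param spec a [model_spec()].
#' @return a `gs_regressor` environment.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  switch(spec$name,
    SVM = build_svm(spec),
    RF = build_forest(spec),
    GBDT = build_boost(spec, regularized = FALSE),
    XGBoost = build_boost(spec, regularized = TRUE),
    MLP = build_nn_regressor(spec, make_mlp_net, identity),
    DeepGS = build_nn_regressor(spec, make_deepgs_net, as_conv1d),
    DNNGP = build_nn_regressor(spec, make_dnngp_net, as_conv1d),
    DLGWAS = build_nn_regressor(spec, make_dlgwas_net, identity,
                                scale_x = FALSE),
    SoyDNGP = build_nn_regressor(spec, make_soydngp_net, identity,
                                 scale_x = FALSE),
    EnvSE = build_envse(spec))
}
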