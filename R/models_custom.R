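# DLGWAS: two parallel 1-D conv branches at different kernel scales on the
# (4, L) one-hot input, merged by elementwise addition (outputs cropped to a
# common length), then a fully connected head. EnvSE: a DeepGS-style CNN on
# the dosage vector whose conv feature maps are reweighted channel-wise by
# sigmoid gates computed from a 64-dimensional environment embedding
# (squeeze-and-excitation style). Both use the engine's channel-first,
# batch-last convolutional layout internally.

make_dlgwas_net <- function(spec, d) {
  k1 <- hp(spec, "kernel_small", 4)
  k2 <- hp(spec, "kernel_large", 20)
  filters <- hp(spec, "filters", 16)
  pool <- hp(spec, "pool", 4)
  fc <- hp(spec, "fc", 64)
  C <- d[2]; L <- d[3]
  adapter <- nn_batch_to_last()
  conv1 <- nn_conv1d(C, filters, k1, pad = (k1 - 1) %/% 2)
  conv2 <- nn_conv1d(C, filters, k2, pad = (k2 - 1) %/% 2)
  conv1$skip_input_grad <- TRUE
  conv2$skip_input_grad <- TRUE
  lmin <- min(L + 2 * ((k1 - 1) %/% 2) - k1,
              L + 2 * ((k2 - 1) %/% 2) - k2) + 1
  head <- list(nn_relu(), nn_pool1d(pool, hp(spec, "pool_type", "avg")),
               nn_flatten(),
               nn_dense(filters * (lmin %/% pool), fc), nn_relu(),
               nn_dense(fc, 1))
  net <- new.env(parent = emptyenv())
  net$layers <- c(list(conv1, conv2), head)
  net$lmin <- lmin
  net$forward <- function(x, training = FALSE) {
    xa <- adapter$forward(x, training)
    b1 <- conv1$forward(xa, training)
    b2 <- conv2$forward(xa, training)
    net$l1 <- dim(b1)[2]; net$l2 <- dim(b2)[2]
    z <- b1[, seq_len(net$lmin), , drop = FALSE] +
      b2[, seq_len(net$lmin), , drop = FALSE]
    for (lay in head) z <- lay$forward(z, training)
    z
  }
  net$backward <- function(dy) {
    for (lay in rev(head)) dy <- lay$backward(dy)
    pad_to <- function(dz, len) {
      if (dim(dz)[2] == len) return(dz)
      out <- array(0, c(dim(dz)[1], len, dim(dz)[3]))
      out[, seq_len(dim(dz)[2]), ] <- dz
      out
    }
    conv1$backward(pad_to(dy, net$l1))
    conv2$backward(pad_to(dy, net$l2))
    invisible(NULL)
  }
  net
}

make_envse_net <- function(spec, L, n_env_feat) {
  filters <- hp(spec, "filters", 8)
  kernel <- hp(spec, "kernel", 18)
  pool <- hp(spec, "pool", 4)
  fc <- hp(spec, "fc", 32)
  embed <- hp(spec, "env_embed", 64)
  Lc <- L - kernel + 1
  adapter <- nn_batch_to_last()
  conv <- nn_conv1d(1, filters, kernel)
  conv$skip_input_grad <- TRUE
  relu_a <- nn_relu()
  head <- list(nn_pool1d(pool, hp(spec, "pool_type", "avg")), nn_flatten(),
               nn_dense(filters * (Lc %/% pool), fc), nn_relu(),
               nn_dense(fc, 1))
  env_d1 <- nn_dense(n_env_feat, embed)
  env_relu <- nn_relu()
  env_d2 <- nn_dense(embed, filters)
  net <- new.env(parent = emptyenv())
  net$layers <- c(list(conv), head, list(env_d1, env_d2))
  net$filters <- filters
  net$pin_gates <- FALSE
  gate_expand <- function(g, Tn) {
    # (B, C) gates -> (C, T*B) matching the flattened feature maps
    t(g)[, rep(seq_len(nrow(g)), each = Tn), drop = FALSE]
  }
  net$forward <- function(x, training = FALSE) {
    a <- relu_a$forward(conv$forward(adapter$forward(x$geno, training),
                                     training), training)
    dC <- dim(a); B <- dC[3]; Tn <- dC[2]
    if (net$pin_gates) {
      g <- matrix(1, B, net$filters)
    } else {
      e <- env_relu$forward(env_d1$forward(x$env, training), training)
      z <- env_d2$forward(e, training)
      g <- 1 / (1 + exp(-z))
    }
    net$a <- a; net$g <- g; net$Tn <- Tn
    gm <- gate_expand(g, Tn)
    out <- array(matrix(a, dC[1]) * gm, dC)
    for (lay in head) out <- lay$forward(out, training)
    out
  }
  net$backward <- function(dy) {
    for (lay in rev(head)) dy <- lay$backward(dy)
    dC <- dim(net$a)
    gm <- gate_expand(net$g, net$Tn)
    da <- array(matrix(dy, dC[1]) * gm, dC)
    s <- dy * net$a                                   # (C, T, B)
    dg <- t(colSums(aperm(s, c(2, 1, 3))))            # (B, C)
    conv$backward(relu_a$backward(da))
    if (!net$pin_gates) {
      dz <- dg * net$g * (1 - net$g)
      env_d1$backward(env_relu$backward(env_d2$backward(dz)))
    } else {
      # keep optimizer state shape-consistent when gates are pinned
      for (lay in list(env_d1, env_d2)) {
        lay$dW <- lay$W * 0
        lay$db <- lay$b * 0
      }
    }
    invisible(NULL)
  }
  # genotype-only view with identical weights (gates forced to 1)
  net$forward_backbone <- function(geno) {
    a <- relu_a$forward(conv$forward(adapter$forward(geno, FALSE), FALSE),
                        FALSE)
    out <- a
    for (lay in head) out <- lay$forward(out, FALSE)
    out
  }
  net
}

build_envse <- function(spec) {
  r <- new_regressor(spec)
  r$fit <- function(X, y, Xval = NULL, yval = NULL, config = gs_config()) {
    stopifnot(is.list(X), all(c("geno", "env") %in% names(X)))
    set.seed(spec$seed)
    r$xs <- fit_col_scaler(X$geno)
    r$es <- fit_col_scaler(X$env)
    r$ys <- fit_y_scaler(y)
    prep <- function(Z) list(
      geno = as_conv1d(apply_col_scaler(Z$geno, r$xs)),
      env = apply_col_scaler(Z$env, r$es))
    ys <- (y - r$ys$mu) / r$ys$sd
    has_val <- !is.null(Xval) && nrow(Xval$geno) > 0
    r$net <- make_envse_net(spec, ncol(X$geno), ncol(X$env))
    r$history <- nn_fit(r$net, prep(X), ys,
                        if (has_val) prep(Xval),
                        if (has_val) (yval - r$ys$mu) / r$ys$sd,
                        batch_size = config$batch_size,
                        epochs = config$epochs, patience = config$patience,
                        lr = config$lr,
                        weight_decay = hp(spec, "weight_decay",
                                          config$weight_decay %||% 0),
                        seed = spec$seed)
    r$in_dim <- c(ncol(X$geno), ncol(X$env))
    invisible(r)
  }
  r$predict <- function(X) {
    xp <- list(geno = as_conv1d(apply_col_scaler(X$geno, r$xs)),
               env = apply_col_scaler(X$env, r$es))
    as.vector(r$net$forward(xp, training = FALSE)) * r$ys$sd + r$ys$mu
  }
  r$state <- function() list(net = nn_get_state(r$net), xs = r$xs,
                             es = r$es, ys = r$ys, in_dim = r$in_dim,
                             history = r$history)
  r$restore <- function(s) {
    r$xs <- s$xs; r$es <- s$es; r$ys <- s$ys
    r$in_dim <- s$in_dim; r$history <- s$history
    set.seed(spec$seed)
    r$net <- make_envse_net(spec, s$in_dim[1], s$in_dim[2])
    nn_set_state(r$net, s$net)
  }
  r
}
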