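# Minimal feed-forward neural-network engine: explicit layer objects
# (environments) with forward/backward passes, im2col-based 1-D and 2-D
# convolutions, max-pooling, dropout and an Adam optimizer.
#
# Layout convention: dense layers use (batch, features). Convolutional
# layers run channel-first with the batch LAST — conv1d (C, L, B), conv2d
# (C, H, W, B) — so that im2col is a plain dim-reassignment and each conv is
# a single BLAS crossprod with no transposes. nn_batch_to_last adapts the
# public batch-first tensors at the network boundary; nn_flatten returns to
# (batch, features) for the dense head. All randomness (init, shuffling,
# dropout) flows through R's RNG so seeded training is bit-reproducible.

new_layer <- function(type, param_names = character(0)) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$param_names <- param_names
  e$skip_input_grad <- FALSE
  e
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

nn_dense <- function(in_f, out_f) {
  l <- new_layer("dense", c("W", "b"))
  l$W <- he_init(in_f, out_f, in_f)
  l$b <- rep(0, out_f)
  l$forward <- function(x, training = FALSE) {
    l$x <- x
    sweep(x %*% l$W, 2, l$b, `+`)
  }
  l$backward <- function(dy) {
    l$dW <- crossprod(l$x, dy)
    l$db <- colSums(dy)
    if (l$skip_input_grad) NULL else dy %*% t(l$W)
  }
  l
}

nn_relu <- function() {
  l <- new_layer("relu")
  l$forward <- function(x, training = FALSE) {
    l$mask <- x > 0
    x * l$mask
  }
  l$backward <- function(dy) dy * l$mask
  l
}

nn_dropout <- function(p) {
  l <- new_layer("dropout")
  l$p <- p
  l$forward <- function(x, training = FALSE) {
    if (!training || l$p <= 0) {
      l$mask <- NULL
      return(x)
    }
    l$mask <- (array(stats::runif(length(x)), dim(x) %||% length(x)) >= l$p) /
      (1 - l$p)
    x * l$mask
  }
  l$backward <- function(dy) if (is.null(l$mask)) dy else dy * l$mask
  l
}

# (B, d1, d2, ...) -> (d1, d2, ..., B): boundary adapter into the
# channel-first/batch-last convolutional layout.
nn_batch_to_last <- function() {
  l <- new_layer("batch_to_last")
  l$forward <- function(x, training = FALSE) {
    nd <- length(dim(x))
    aperm(x, c(2:nd, 1))
  }
  l$backward <- function(dy) {
    if (is.null(dy)) return(NULL)
    nd <- length(dim(dy))
    aperm(dy, c(nd, seq_len(nd - 1)))
  }
  l
}

# (d1, ..., B) -> (B, features) for the dense head.
nn_flatten <- function() {
  l <- new_layer("flatten")
  l$forward <- function(x, training = FALSE) {
    l$in_dim <- dim(x)
    B <- l$in_dim[length(l$in_dim)]
    t(matrix(x, prod(l$in_dim[-length(l$in_dim)]), B))
  }
  l$backward <- function(dy) array(t(dy), l$in_dim)
  l
}

# im2col index matrix over a (C, L) plane: column t holds the flat indices
# of the receptive field of output position t.
im2col_idx_1d <- function(C, Lp, kernel, Lout) {
  base <- outer(seq_len(C), (seq_len(kernel) - 1) * C, `+`)  # (C, k)
  idx <- outer(as.vector(base), (seq_len(Lout) - 1) * C, `+`)
  dim(idx) <- c(C * kernel, Lout)
  idx
}

nn_conv1d <- function(in_ch, out_ch, kernel, pad = 0) {
  l <- new_layer("conv1d", c("W", "b"))
  l$in_ch <- in_ch; l$out_ch <- out_ch; l$kernel <- kernel; l$pad <- pad
  l$W <- he_init(in_ch * kernel, out_ch, in_ch * kernel)
  l$b <- rep(0, out_ch)
  l$forward <- function(x, training = FALSE) {
    d <- dim(x); C <- d[1]; L <- d[2]; B <- d[3]
    stopifnot(C == l$in_ch)
    Lp <- L + 2 * l$pad
    Lout <- Lp - l$kernel + 1
    if (Lout < 1) abort_stage("model_pool", sprintf(
      "conv1d: input length %d too short for kernel %d", L, l$kernel))
    if (is.null(l$idx) || !identical(l$idx_key, c(C, Lp, Lout))) {
      l$idx <- as.vector(im2col_idx_1d(C, Lp, l$kernel, Lout))
      l$idx_key <- c(C, Lp, Lout)
      l$upos <- sort(unique(l$idx))
    }
    xf <- if (l$pad > 0) {
      xp <- array(0, c(C, Lp, B))
      xp[, (l$pad + 1):(l$pad + L), ] <- x
      matrix(xp, C * Lp, B)
    } else matrix(x, C * Lp, B)
    cols <- xf[l$idx, , drop = FALSE]            # (C*k*Lout, B)
    dim(cols) <- c(C * l$kernel, Lout * B)       # columns: t fastest, then b
    Y <- crossprod(l$W, cols) + l$b              # (OC, Lout*B); b recycles
    l$cols <- cols; l$B <- B; l$L <- L; l$Lout <- Lout; l$Lp <- Lp
    array(Y, c(l$out_ch, Lout, B))
  }
  l$backward <- function(dy) {
    B <- l$B; Lout <- l$Lout; C <- l$in_ch
    dYm <- matrix(dy, l$out_ch, Lout * B)
    l$dW <- tcrossprod(l$cols, dYm)              # (C*k, OC)
    l$db <- rowSums(dYm)
    if (l$skip_input_grad) return(NULL)
    dcols <- l$W %*% dYm                         # (C*k, Lout*B)
    dim(dcols) <- c(C * l$kernel * Lout, B)
    acc <- rowsum(dcols, group = l$idx)
    dxf <- matrix(0, C * l$Lp, B)
    dxf[l$upos, ] <- acc
    dxp <- array(dxf, c(C, l$Lp, B))
    if (l$pad > 0) dxp[, (l$pad + 1):(l$pad + l$L), , drop = FALSE] else dxp
  }
  l
}

im2col_idx_2d <- function(C, Hp, Wp, k, Hout, Wout) {
  patch <- as.vector(outer(outer(seq_len(C), (seq_len(k) - 1) * C, `+`),
                           (seq_len(k) - 1) * C * Hp, `+`))   # C*k*k offsets
  pos <- as.vector(outer((seq_len(Hout) - 1) * C,
                         (seq_len(Wout) - 1) * C * Hp, `+`))  # Hout*Wout
  idx <- outer(patch, pos, `+`)
  dim(idx) <- c(C * k * k, Hout * Wout)
  idx
}

nn_conv2d <- function(in_ch, out_ch, kernel = 3, pad = 1) {
  l <- new_layer("conv2d", c("W", "b"))
  l$in_ch <- in_ch; l$out_ch <- out_ch; l$kernel <- kernel; l$pad <- pad
  l$W <- he_init(in_ch * kernel^2, out_ch, in_ch * kernel^2)
  l$b <- rep(0, out_ch)
  l$forward <- function(x, training = FALSE) {
    d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
    stopifnot(C == l$in_ch)
    Hp <- H + 2 * l$pad; Wp <- W + 2 * l$pad
    Hout <- Hp - l$kernel + 1; Wout <- Wp - l$kernel + 1
    if (Hout < 1 || Wout < 1) abort_stage("model_pool", sprintf(
      "conv2d: input %dx%d too small for kernel %d", H, W, l$kernel))
    if (is.null(l$idx) || !identical(l$idx_key, c(C, Hp, Wp))) {
      l$idx <- as.vector(im2col_idx_2d(C, Hp, Wp, l$kernel, Hout, Wout))
      l$idx_key <- c(C, Hp, Wp)
      l$upos <- sort(unique(l$idx))
    }
    xf <- if (l$pad > 0) {
      xp <- array(0, c(C, Hp, Wp, B))
      xp[, (l$pad + 1):(l$pad + H), (l$pad + 1):(l$pad + W), ] <- x
      matrix(xp, C * Hp * Wp, B)
    } else matrix(x, C * Hp * Wp, B)
    P <- Hout * Wout
    cols <- xf[l$idx, , drop = FALSE]
    dim(cols) <- c(C * l$kernel^2, P * B)
    Y <- crossprod(l$W, cols) + l$b
    l$cols <- cols; l$B <- B; l$H <- H; l$W_in <- W
    l$Hp <- Hp; l$Wp <- Wp; l$Hout <- Hout; l$Wout <- Wout
    array(Y, c(l$out_ch, Hout, Wout, B))
  }
  l$backward <- function(dy) {
    B <- l$B; P <- l$Hout * l$Wout; C <- l$in_ch
    dYm <- matrix(dy, l$out_ch, P * B)
    l$dW <- tcrossprod(l$cols, dYm)
    l$db <- rowSums(dYm)
    if (l$skip_input_grad) return(NULL)
    dcols <- l$W %*% dYm
    dim(dcols) <- c(C * l$kernel^2 * P, B)
    acc <- rowsum(dcols, group = l$idx)
    dxf <- matrix(0, C * l$Hp * l$Wp, B)
    dxf[l$upos, ] <- acc
    dxp <- array(dxf, c(C, l$Hp, l$Wp, B))
    if (l$pad > 0)
      dxp[, (l$pad + 1):(l$pad + l$H), (l$pad + 1):(l$pad + l$W_in), ,
          drop = FALSE]
    else dxp
  }
  l
}

nn_maxpool1d <- function(size) {
  l <- new_layer("maxpool1d")
  l$size <- size
  l$forward <- function(x, training = FALSE) {
    d <- dim(x); C <- d[1]; L <- d[2]; B <- d[3]
    s <- l$size
    Lout <- L %/% s
    xr <- x[, seq_len(Lout * s), , drop = FALSE]
    dim(xr) <- c(C, s, Lout, B)
    best <- xr[, 1, , , drop = TRUE]
    dim(best) <- c(C, Lout, B)
    arg <- array(1L, c(C, Lout, B))
    if (s > 1) for (i in 2:s) {
      cand <- xr[, i, , , drop = TRUE]
      dim(cand) <- c(C, Lout, B)
      upd <- cand > best
      best[upd] <- cand[upd]
      arg[upd] <- i
    }
    l$arg <- arg; l$in_dim <- d; l$Lout <- Lout
    best
  }
  l$backward <- function(dy) {
    d <- l$in_dim; C <- d[1]; B <- d[3]
    s <- l$size; Lout <- l$Lout
    n <- C * Lout * B
    cc <- rep_len(seq_len(C), n)
    tt <- rep_len(rep(seq_len(Lout), each = C), n)
    bb <- rep(seq_len(B), each = C * Lout)
    flat <- cc + C * (as.vector(l$arg) - 1) + C * s * (tt - 1) +
      C * s * Lout * (bb - 1)
    dz <- numeric(C * s * Lout * B)
    dz[flat] <- as.vector(dy)
    out <- array(0, d)
    out[, seq_len(Lout * s), ] <- array(dz, c(C, Lout * s, B))
    out
  }
  l
}

nn_avgpool1d <- function(size) {
  l <- new_layer("avgpool1d")
  l$size <- size
  l$forward <- function(x, training = FALSE) {
    d <- dim(x); C <- d[1]; L <- d[2]; B <- d[3]
    s <- l$size
    Lout <- L %/% s
    xr <- x[, seq_len(Lout * s), , drop = FALSE]
    dim(xr) <- c(C, s, Lout, B)
    acc <- xr[, 1, , , drop = TRUE]
    dim(acc) <- c(C, Lout, B)
    if (s > 1) for (i in 2:s) {
      cand <- xr[, i, , , drop = TRUE]
      dim(cand) <- c(C, Lout, B)
      acc <- acc + cand
    }
    l$in_dim <- d; l$Lout <- Lout
    acc / s
  }
  l$backward <- function(dy) {
    d <- l$in_dim; C <- d[1]; B <- d[3]; s <- l$size
    dz <- array(0, c(C, s, l$Lout, B))
    for (i in seq_len(s)) dz[, i, , ] <- dy / s
    out <- array(0, d)
    out[, seq_len(l$Lout * s), ] <- array(dz, c(C, l$Lout * s, B))
    out
  }
  l
}

nn_pool1d <- function(size, type = c("avg", "max")) {
  type <- match.arg(type)
  if (type == "max") nn_maxpool1d(size) else nn_avgpool1d(size)
}

nn_avgpool2d <- function(size = 2) {
  l <- new_layer("avgpool2d")
  l$size <- size
  l$forward <- function(x, training = FALSE) {
    d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
    s <- l$size
    Hout <- H %/% s; Wout <- W %/% s
    xr <- x[, seq_len(Hout * s), seq_len(Wout * s), , drop = FALSE]
    dim(xr) <- c(C, s, Hout, s, Wout, B)
    acc <- NULL
    for (i in seq_len(s)) for (j in seq_len(s)) {
      cand <- xr[, i, , j, , , drop = TRUE]
      dim(cand) <- c(C, Hout, Wout, B)
      acc <- if (is.null(acc)) cand else acc + cand
    }
    l$in_dim <- d; l$Hout <- Hout; l$Wout <- Wout
    acc / (s * s)
  }
  l$backward <- function(dy) {
    d <- l$in_dim; C <- d[1]; B <- d[4]; s <- l$size
    dz <- array(0, c(C, s, l$Hout, s, l$Wout, B))
    g <- dy / (s * s)
    for (i in seq_len(s)) for (j in seq_len(s)) dz[, i, , j, , ] <- g
    out <- array(0, d)
    out[, seq_len(l$Hout * s), seq_len(l$Wout * s), ] <-
      array(dz, c(C, l$Hout * s, l$Wout * s, B))
    out
  }
  l
}

nn_pool2d <- function(size, type = c("avg", "max")) {
  type <- match.arg(type)
  if (type == "max") nn_maxpool2d(size) else nn_avgpool2d(size)
}

nn_maxpool2d <- function(size = 2) {
  l <- new_layer("maxpool2d")
  l$size <- size
  l$forward <- function(x, training = FALSE) {
    d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
    s <- l$size
    Hout <- H %/% s; Wout <- W %/% s
    xr <- x[, seq_len(Hout * s), seq_len(Wout * s), , drop = FALSE]
    dim(xr) <- c(C, s, Hout, s, Wout, B)
    best <- NULL; arg <- NULL
    for (i in seq_len(s)) for (j in seq_len(s)) {
      cand <- xr[, i, , j, , , drop = TRUE]
      dim(cand) <- c(C, Hout, Wout, B)
      code <- (j - 1L) * s + i
      if (is.null(best)) {
        best <- cand; arg <- array(code, c(C, Hout, Wout, B))
      } else {
        upd <- cand > best
        best[upd] <- cand[upd]
        arg[upd] <- code
      }
    }
    l$arg <- arg; l$in_dim <- d; l$Hout <- Hout; l$Wout <- Wout
    best
  }
  l$backward <- function(dy) {
    d <- l$in_dim; C <- d[1]; B <- d[4]; s <- l$size
    Hout <- l$Hout; Wout <- l$Wout
    n <- C * Hout * Wout * B
    cc <- rep_len(seq_len(C), n)
    hh <- rep_len(rep(seq_len(Hout), each = C), n)
    ww <- rep_len(rep(seq_len(Wout), each = C * Hout), n)
    bb <- rep(seq_len(B), each = C * Hout * Wout)
    code <- as.vector(l$arg)
    i <- ((code - 1L) %% s) + 1L
    j <- ((code - 1L) %/% s) + 1L
    flat <- cc + C * (i - 1) + C * s * (hh - 1) + C * s * Hout * (j - 1) +
      C * s * Hout * s * (ww - 1) + C * s * Hout * s * Wout * (bb - 1)
    dz <- numeric(C * s * Hout * s * Wout * B)
    dz[flat] <- as.vector(dy)
    out <- array(0, d)
    out[, seq_len(Hout * s), seq_len(Wout * s), ] <-
      array(dz, c(C, Hout * s, Wout * s, B))
    out
  }
  l
}

# ---- sequential container ----------------------------------------------

nn_sequential <- function(layers) {
  # input gradients are never needed before the first parametric layer
  for (lay in layers) {
    if (length(lay$param_names) > 0) {
      lay$skip_input_grad <- TRUE
      break
    }
  }
  net <- new.env(parent = emptyenv())
  net$layers <- layers
  net$forward <- function(x, training = FALSE) {
    for (lay in net$layers) x <- lay$forward(x, training)
    x
  }
  net$backward <- function(dy) {
    for (lay in rev(net$layers)) {
      dy <- lay$backward(dy)
      if (is.null(dy)) break
    }
    invisible(dy)
  }
  net
}

nn_param_layers <- function(net) {
  Filter(function(l) length(l$param_names) > 0, net$layers)
}

nn_get_state <- function(net) {
  lapply(nn_param_layers(net), function(l) {
    s <- lapply(l$param_names, function(p) l[[p]])
    names(s) <- l$param_names
    s
  })
}

nn_set_state <- function(net, state) {
  pl <- nn_param_layers(net)
  stopifnot(length(pl) == length(state))
  for (i in seq_along(pl))
    for (p in pl[[i]]$param_names) pl[[i]][[p]] <- state[[i]][[p]]
  invisible(net)
}

# ---- Adam --------------------------------------------------------------

adam_new <- function(net, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weight_decay = 0) {
  opt <- new.env(parent = emptyenv())
  opt$lr <- lr; opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$weight_decay <- weight_decay
  opt$t <- 0L
  opt$layers <- nn_param_layers(net)
  opt$m <- lapply(opt$layers, function(l)
    lapply(stats::setNames(l$param_names, l$param_names),
           function(p) {
             d <- dim(l[[p]])
             if (is.null(d)) numeric(length(l[[p]])) else array(0, d)
           }))
  opt$v <- opt$m
  opt
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(opt$layers)) {
    l <- opt$layers[[i]]
    for (p in l$param_names) {
      gr <- l[[paste0("d", p)]]
      opt$m[[i]][[p]] <- opt$beta1 * opt$m[[i]][[p]] + (1 - opt$beta1) * gr
      opt$v[[i]][[p]] <- opt$beta2 * opt$v[[i]][[p]] + (1 - opt$beta2) * gr^2
      upd <- opt$lr * (opt$m[[i]][[p]] / bc1) /
        (sqrt(opt$v[[i]][[p]] / bc2) + opt$eps)
      # decoupled L2 on weight matrices only (never biases)
      if (opt$weight_decay > 0 && p == "W")
        upd <- upd + opt$lr * opt$weight_decay * l[[p]]
      l[[p]] <- l[[p]] - upd
    }
  }
  invisible(opt)
}

# ---- generic training loop ---------------------------------------------

slice_input <- function(x, idx) {
  if (is.list(x)) return(lapply(x, slice_input, idx = idx))
  nd <- length(dim(x) %||% 1L)
  switch(as.character(nd),
         "1" = x[idx],
         "2" = x[idx, , drop = FALSE],
         "3" = x[idx, , , drop = FALSE],
         "4" = x[idx, , , , drop = FALSE],
         abort_stage("model_pool", "unsupported tensor rank"))
}

input_n <- function(x) {
  if (is.list(x)) return(input_n(x[[1]]))
  (dim(x) %||% length(x))[1]
}

# Mini-batch Adam/MSE training with early stopping on validation MSE.
# net must expose forward(x, training) and backward(dy); y is pre-scaled by
# the caller. Restores the best-validation weights before returning.
nn_fit <- function(net, X, y, Xval = NULL, yval = NULL,
                   batch_size = 64, epochs = 200, patience = 20,
                   lr = 1e-3, weight_decay = 0, seed = 1L) {
  set.seed(seed)
  n <- input_n(X)
  batch_size <- min(batch_size, n)
  opt <- adam_new(net, lr = lr, weight_decay = weight_decay)
  best_val <- Inf; best_state <- nn_get_state(net); wait <- 0L
  train_loss <- numeric(0); val_loss <- numeric(0)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      xb <- slice_input(X, idx)
      yb <- y[idx]
      pred <- net$forward(xb, training = TRUE)
      r <- as.vector(pred) - yb
      loss <- mean(r^2)
      if (!is.finite(loss)) abort_stage("training_eval", sprintf(
        "non-finite training loss at epoch %d; try a lower learning rate", ep))
      ep_loss <- ep_loss + loss; nb <- nb + 1L
      net$backward(matrix(2 * r / length(r), ncol = 1))
      adam_step(opt)
    }
    train_loss <- c(train_loss, ep_loss / nb)
    if (!is.null(Xval) && input_n(Xval) > 0) {
      pv <- as.vector(net$forward(Xval, training = FALSE))
      vl <- mean((pv - yval)^2)
      val_loss <- c(val_loss, vl)
      if (vl < best_val - 1e-9) {
        best_val <- vl
        best_state <- nn_get_state(net)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  }
  if (!is.null(Xval) && is.finite(best_val)) nn_set_state(net, best_state)
  list(train_loss = train_loss, val_loss = val_loss,
       epochs_run = length(train_loss))
}
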