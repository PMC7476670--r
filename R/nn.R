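# Minimal neural-network engine on BLAS matrix ops.
#
# Tensors are arrays with dim c(N, H, W, C). Convolution is im2col + GEMM;
# index maps are cached per input geometry in a per-layer environment (shared
# by reference, so functional copies of a layer reuse the cache). All
# backward passes are exact and covered by finite-difference tests.
#
# Leaf layers: list(kind, par = named list of arrays, buf = named list,
# hyper fields). Composites: kind "seq" (layers) and "res" (main, shortcut,
# post-add ReLU). net_forward returns the updated node because batchnorm
# running statistics change during training.

nn_conv <- function(in_ch, out_ch, k, stride = 1, pad = 0, bias = FALSE) {
  fan_in <- k * k * in_ch
  par <- list(W = matrix(stats::rnorm(fan_in * out_ch, 0, sqrt(2 / fan_in)),
                         fan_in, out_ch))
  if (bias) par$b <- numeric(out_ch)
  list(kind = "conv", par = par, k = k, stride = stride, pad = pad,
       in_ch = in_ch, out_ch = out_ch, env = new.env(parent = emptyenv()))
}

nn_bn <- function(ch, momentum = 0.1, eps = 1e-5) {
  list(kind = "bn", par = list(gamma = rep(1, ch), beta = rep(0, ch)),
       buf = list(rmean = rep(0, ch), rvar = rep(1, ch)),
       momentum = momentum, eps = eps, ch = ch)
}

nn_relu <- function() list(kind = "relu")

nn_maxpool <- function(k, stride = k, pad = 0)
  list(kind = "maxpool", k = k, stride = stride, pad = pad,
       env = new.env(parent = emptyenv()))

nn_gap <- function() list(kind = "gap")

nn_linear <- function(in_dim, out_dim) {
  list(kind = "linear",
       par = list(W = matrix(stats::rnorm(in_dim * out_dim, 0,
                                          sqrt(2 / in_dim)), in_dim, out_dim),
                  b = numeric(out_dim)))
}

nn_seq <- function(...) list(kind = "seq", layers = list(...))

nn_res <- function(main, shortcut = NULL)
  list(kind = "res", main = main, shortcut = shortcut)

# -- geometry helpers -------------------------------------------------------

pad_nhwc <- function(x, p, value = 0) {
  if (p == 0) return(x)
  d <- dim(x)
  xp <- array(value, c(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4]))
  xp[, (p + 1):(p + d[2]), (p + 1):(p + d[3]), ] <- x
  xp
}

# Index matrices are laid out so im2col gathers flatten straight into the
# GEMM operand without aperm: P x KKC for conv (output position fastest),
# PC x KK for pooling.
conv_idx <- function(env, Hp, Wp, C, k, s, OH, OW) {
  key <- paste("c", Hp, Wp, C, k, s, sep = "_")
  if (!is.null(env[[key]])) return(env[[key]])
  kh <- rep(seq_len(k), times = k * C)
  kw <- rep(rep(seq_len(k), each = k), times = C)
  cc <- rep(seq_len(C), each = k * k)
  base <- kh + Hp * (kw - 1) + Hp * Wp * (cc - 1)
  oh0 <- (seq_len(OH) - 1) * s
  ow0 <- (seq_len(OW) - 1) * s
  off <- rep(oh0, times = OW) + Hp * rep(ow0, each = OH)
  idx <- outer(off, base, "+")          # P x KKC
  env[[key]] <- idx
  idx
}

# Sparse scatter operator for the conv backward pass: maps the (P*KKC)
# im2col columns back onto the padded input pixels with summation over
# overlaps, as one sparse GEMM.
conv_scatter <- function(env, idx, Hp, Wp, C, k, s) {
  key <- paste("s", Hp, Wp, C, k, s, sep = "_")
  if (!is.null(env[[key]])) return(env[[key]])
  iv <- as.vector(idx)
  S <- Matrix::sparseMatrix(i = seq_along(iv), j = iv, x = 1,
                            dims = c(length(iv), Hp * Wp * C))
  env[[key]] <- S
  S
}

pool_idx <- function(env, Hp, Wp, C, k, s, OH, OW) {
  key <- paste("p", Hp, Wp, C, k, s, sep = "_")
  if (!is.null(env[[key]])) return(env[[key]])
  kh <- rep(seq_len(k), times = k)
  kw <- rep(seq_len(k), each = k)
  base <- kh + Hp * (kw - 1)
  oh0 <- (seq_len(OH) - 1) * s
  ow0 <- (seq_len(OW) - 1) * s
  off <- rep(rep(oh0, times = OW), times = C) +
    Hp * rep(rep(ow0, each = OH), times = C) +
    Hp * Wp * rep(seq_len(C) - 1, each = OH * OW)
  idx <- outer(off, base, "+")          # PC x KK
  env[[key]] <- idx
  idx
}

# -- leaf forward/backward --------------------------------------------------

conv_fwd <- function(layer, x) {
  d <- dim(x); N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  k <- layer$k; s <- layer$stride; p <- layer$pad
  OH <- (H + 2 * p - k) %/% s + 1
  OW <- (W + 2 * p - k) %/% s + 1
  xp <- pad_nhwc(x, p)
  Hp <- H + 2 * p; Wp <- W + 2 * p
  idx <- conv_idx(layer$env, Hp, Wp, C, k, s, OH, OW)
  P <- nrow(idx); KKC <- ncol(idx)
  Xm <- matrix(xp, N, Hp * Wp * C)
  M <- Xm[, as.vector(idx), drop = FALSE]   # N x (P*KKC), position fastest
  dim(M) <- c(N * P, KKC)
  Y <- M %*% layer$par$W
  if (!is.null(layer$par$b))
    Y <- Y + rep(layer$par$b, each = nrow(Y))
  out <- Y
  dim(out) <- c(N, OH, OW, ncol(layer$par$W))
  list(out = out,
       cache = list(M = M, idx = idx, N = N, Hp = Hp, Wp = Wp, C = C,
                    H = H, W = W, P = P, KKC = KKC, OH = OH, OW = OW))
}

conv_bwd <- function(layer, cache, dout) {
  N <- cache$N; P <- cache$P; KKC <- cache$KKC
  dYm <- matrix(dout, N * P, dim(dout)[4])
  grads <- list(W = crossprod(cache$M, dYm))
  if (!is.null(layer$par$b)) grads$b <- colSums(dYm)
  dM <- dYm %*% t(layer$par$W)              # (N*P) x KKC
  dim(dM) <- c(N, P * KKC)                  # columns ordered (P, KKC)
  S <- conv_scatter(layer$env, cache$idx, cache$Hp, cache$Wp, cache$C,
                    layer$k, layer$stride)
  dXp <- as.matrix(dM %*% S)
  dXp <- array(dXp, c(N, cache$Hp, cache$Wp, cache$C))
  p <- layer$pad
  dx <- if (p > 0)
    dXp[, (p + 1):(p + cache$H), (p + 1):(p + cache$W), , drop = FALSE]
  else dXp
  list(dx = dx, grads = grads)
}

bn_fwd <- function(layer, x, train) {
  d <- dim(x)
  m <- x
  dim(m) <- c(prod(d[1:3]), d[4])           # (N*H*W) x C
  nr <- nrow(m)
  if (train) {
    mu <- colMeans(m)
    v <- colMeans(m * m) - mu^2
    layer$buf$rmean <- (1 - layer$momentum) * layer$buf$rmean +
      layer$momentum * mu
    layer$buf$rvar <- (1 - layer$momentum) * layer$buf$rvar +
      layer$momentum * v
  } else {
    mu <- layer$buf$rmean
    v <- layer$buf$rvar
  }
  istd <- 1 / sqrt(v + layer$eps)
  xhat <- m * rep(istd, each = nr) - rep(mu * istd, each = nr)
  y <- xhat * rep(layer$par$gamma, each = nr) +
    rep(layer$par$beta, each = nr)
  dim(y) <- d
  list(out = y, layer = layer,
       cache = list(xhat = xhat, istd = istd, d = d, train = train))
}

bn_bwd <- function(layer, cache, dout) {
  d <- cache$d
  dy <- dout
  dim(dy) <- c(prod(d[1:3]), d[4])
  nr <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * rep(layer$par$gamma, each = nr)
  if (cache$train) {
    dx <- (dxhat - rep(colMeans(dxhat), each = nr) -
             cache$xhat * rep(colMeans(dxhat * cache$xhat), each = nr)) *
      rep(cache$istd, each = nr)
  } else {
    dx <- dxhat * rep(cache$istd, each = nr)
  }
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

maxpool_fwd <- function(layer, x) {
  d <- dim(x); N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  k <- layer$k; s <- layer$stride; p <- layer$pad
  OH <- (H + 2 * p - k) %/% s + 1
  OW <- (W + 2 * p - k) %/% s + 1
  xp <- pad_nhwc(x, p, value = -1e30)
  Hp <- H + 2 * p; Wp <- W + 2 * p
  idx <- pool_idx(layer$env, Hp, Wp, C, k, s, OH, OW)
  PC <- nrow(idx); KK <- ncol(idx)
  Xm <- matrix(xp, N, Hp * Wp * C)
  cols <- Xm[, as.vector(idx), drop = FALSE]
  dim(cols) <- c(N, PC, KK)
  mx <- matrix(cols[, , 1], N, PC)
  arg <- matrix(1L, N, PC)
  for (r in seq_len(KK)[-1]) {
    cr <- matrix(cols[, , r], N, PC)
    sel <- cr > mx
    mx[sel] <- cr[sel]
    arg[sel] <- r
  }
  list(out = array(mx, c(N, OH, OW, C)),
       cache = list(arg = arg, idx = idx, N = N, Hp = Hp, Wp = Wp, C = C,
                    H = H, W = W, KK = KK, PC = PC))
}

maxpool_bwd <- function(layer, cache, dout) {
  N <- cache$N; PC <- cache$PC
  dYm <- matrix(dout, N, PC)
  dXp <- matrix(0, N, cache$Hp * cache$Wp * cache$C)
  for (r in seq_len(cache$KK)) {
    cr <- cache$idx[, r]
    dXp[, cr] <- dXp[, cr] + dYm * (cache$arg == r)
  }
  dXp <- array(dXp, c(N, cache$Hp, cache$Wp, cache$C))
  p <- layer$pad
  dx <- if (p > 0)
    dXp[, (p + 1):(p + cache$H), (p + 1):(p + cache$W), , drop = FALSE]
  else dXp
  list(dx = dx)
}

gap_fwd <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1], d[2] * d[3], d[4])
  out <- matrix(0, d[1], d[4])
  for (c in seq_len(d[4]))
    out[, c] <- rowMeans(matrix(x[, , c], d[1], d[2] * d[3]))
  list(out = out, cache = d)
}

gap_bwd <- function(cache, dout) {
  d <- cache
  scale <- 1 / (d[2] * d[3])
  dx <- array(0, d)
  for (c in seq_len(d[4]))
    dx[, , , c] <- array(rep(dout[, c] * scale, d[2] * d[3]), d[1:3])
  list(dx = dx)
}

linear_fwd <- function(layer, x) {
  y <- x %*% layer$par$W
  y <- sweep(y, 2, layer$par$b, "+")
  list(out = y, cache = x)
}

linear_bwd <- function(layer, cache, dout) {
  list(dx = dout %*% t(layer$par$W),
       grads = list(W = crossprod(cache, dout), b = colSums(dout)))
}

# -- generic forward / backward over node trees -----------------------------

net_forward <- function(node, x, train = FALSE) {
  switch(node$kind,
    seq = {
      caches <- vector("list", length(node$layers))
      for (i in seq_along(node$layers)) {
        r <- net_forward(node$layers[[i]], x, train)
        x <- r$out
        caches[[i]] <- r$cache
        node$layers[[i]] <- r$node
      }
      list(out = x, cache = caches, node = node)
    },
    res = {
      rm_ <- net_forward(node$main, x, train)
      node$main <- rm_$node
      if (!is.null(node$shortcut)) {
        rs <- net_forward(node$shortcut, x, train)
        node$shortcut <- rs$node
        sc <- rs$out
        sc_cache <- rs$cache
      } else {
        sc <- x
        sc_cache <- NULL
      }
      s <- rm_$out + sc
      act <- relu_fwd(s)
      list(out = act$out,
           cache = list(main = rm_$cache, shortcut = sc_cache,
                        mask = act$cache),
           node = node)
    },
    conv = { r <- conv_fwd(node, x); list(out = r$out, cache = r$cache, node = node) },
    bn = { r <- bn_fwd(node, x, train); list(out = r$out, cache = r$cache, node = r$layer) },
    relu = { r <- relu_fwd(x); list(out = r$out, cache = r$cache, node = node) },
    maxpool = { r <- maxpool_fwd(node, x); list(out = r$out, cache = r$cache, node = node) },
    gap = { r <- gap_fwd(x); list(out = r$out, cache = r$cache, node = node) },
    linear = { r <- linear_fwd(node, x); list(out = r$out, cache = r$cache, node = node) },
    stop("unknown node kind: ", node$kind))
}

net_backward <- function(node, cache, dout) {
  switch(node$kind,
    seq = {
      n <- length(node$layers)
      grads <- vector("list", n)
      for (i in rev(seq_len(n))) {
        r <- net_backward(node$layers[[i]], cache[[i]], dout)
        dout <- r$dx
        grads[i] <- list(r$grads)   # keep NULL grads as placeholders
      }
      list(dx = dout, grads = grads)
    },
    res = {
      ds <- dout * cache$mask
      rmain <- net_backward(node$main, cache$main, ds)
      if (!is.null(node$shortcut)) {
        rsc <- net_backward(node$shortcut, cache$shortcut, ds)
        dx <- rmain$dx + rsc$dx
        g <- list(main = rmain$grads, shortcut = rsc$grads)
      } else {
        dx <- rmain$dx + ds
        g <- list(main = rmain$grads, shortcut = NULL)
      }
      list(dx = dx, grads = g)
    },
    conv = { r <- conv_bwd(node, cache, dout); list(dx = r$dx, grads = r$grads) },
    bn = { r <- bn_bwd(node, cache, dout); list(dx = r$dx, grads = r$grads) },
    relu = list(dx = dout * cache, grads = NULL),
    maxpool = { r <- maxpool_bwd(node, cache, dout); list(dx = r$dx, grads = NULL) },
    gap = { r <- gap_bwd(cache, dout); list(dx = r$dx, grads = NULL) },
    linear = { r <- linear_bwd(node, cache, dout); list(dx = r$dx, grads = r$grads) },
    stop("unknown node kind: ", node$kind))
}

# -- SGD with momentum and L2 weight decay ----------------------------------

sgd_state <- function(node) {
  switch(node$kind,
    seq = lapply(node$layers, sgd_state),
    res = list(main = sgd_state(node$main),
               shortcut = if (!is.null(node$shortcut))
                 sgd_state(node$shortcut)),
    if (!is.null(node$par)) lapply(node$par, function(p) p * 0))
}

sgd_step <- function(node, grads, state, lr, momentum = 0.9, wd = 5e-4) {
  switch(node$kind,
    seq = {
      for (i in seq_along(node$layers)) {
        r <- sgd_step(node$layers[[i]], grads[[i]], state[[i]],
                      lr, momentum, wd)
        node$layers[[i]] <- r$node
        state[i] <- list(r$state)   # param-free layers have NULL state
      }
      list(node = node, state = state)
    },
    res = {
      rm_ <- sgd_step(node$main, grads$main, state$main, lr, momentum, wd)
      node$main <- rm_$node
      state$main <- rm_$state
      if (!is.null(node$shortcut)) {
        rs <- sgd_step(node$shortcut, grads$shortcut, state$shortcut,
                       lr, momentum, wd)
        node$shortcut <- rs$node
        state$shortcut <- rs$state
      }
      list(node = node, state = state)
    },
    {
      if (!is.null(node$par)) {
        for (nm in names(node$par)) {
          g <- grads[[nm]] + wd * node$par[[nm]]
          state[[nm]] <- momentum * state[[nm]] + g
          node$par[[nm]] <- node$par[[nm]] - lr * state[[nm]]
        }
      }
      list(node = node, state = state)
    })
}

# -- losses -----------------------------------------------------------------

# Weighted two-class softmax cross-entropy.
# logits: N x 2 (column 1 = NEG, column 2 = POS); y: integer 1/2 column
# index; w: c(w_neg, w_pos). Loss = sum(w_y * -log p_y) / sum(w_y).
softmax_ce_weighted <- function(logits, y, w) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  wi <- w[y]
  idx <- cbind(seq_along(y), y)
  loss <- -sum(wi * log(pmax(p[idx], 1e-12))) / sum(wi)
  dlog <- p
  dlog[idx] <- dlog[idx] - 1
  dlog <- dlog * wi / sum(wi)
  list(loss = loss, dlogits = dlog, probs = p)
}

sigmoid <- function(z) 1 / (1 + exp(-z))
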