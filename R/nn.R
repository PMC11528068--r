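# Minimal CNN engine in base R. Data layout: arrays of dim (H, W, C, N).
# Layers are plain lists; forward passes thread updated layer state (batch
# norm running moments) functionally, backward passes return gradients with
# the same structure as the parameters. Everything is deterministic given
# the RNG state, which is what makes seeded training reproducible on CPU.

he_init <- function(dims, fan_in) array(rnorm(prod(dims)) * sqrt(2 / fan_in), dims)

nn_conv <- function(kh, kw, c_in, filters, stride = 1L, pad = 0L) {
  list(type = "conv", kh = kh, kw = kw, stride = as.integer(stride),
       pad = as.integer(pad),
       W = he_init(c(kh, kw, c_in, filters), kh * kw * c_in),
       b = numeric(filters),
       vW = array(0, c(kh, kw, c_in, filters)), vb = numeric(filters))
}

nn_bn <- function(channels, momentum = 0.9, eps = 1e-5) {
  list(type = "bn", gamma = rep(1, channels), beta = numeric(channels),
       rm = numeric(channels), rv = rep(1, channels),
       momentum = momentum, eps = eps,
       vgamma = numeric(channels), vbeta = numeric(channels))
}

nn_relu <- function() list(type = "relu")
nn_maxpool <- function(k = 2L, stride = 2L, pad = 0L)
  list(type = "maxpool", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad))
nn_gap <- function() list(type = "gap")
nn_flatten <- function() list(type = "flatten")

nn_dense <- function(d_in, d_out) {
  list(type = "dense", W = matrix(rnorm(d_out * d_in) * sqrt(2 / d_in), d_out, d_in),
       b = numeric(d_out), vW = matrix(0, d_out, d_in), vb = numeric(d_out))
}

# ---- im2col convolution -----------------------------------------------------

im2col <- function(X, kh, kw, stride, pad, pad_value = 0) {
  d <- dim(X); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  Ho <- (H + 2L * pad - kh) %/% stride + 1L
  Wo <- (W + 2L * pad - kw) %/% stride + 1L
  if (pad > 0) {
    Xp <- array(pad_value, c(H + 2L * pad, W + 2L * pad, C, N))
    Xp[pad + seq_len(H), pad + seq_len(W), , ] <- X
  } else Xp <- X
  cols <- matrix(0, kh * kw * C, Ho * Wo * N)
  for (kj in seq_len(kw)) for (ki in seq_len(kh)) {
    rs <- seq(ki, by = stride, length.out = Ho)
    cs <- seq(kj, by = stride, length.out = Wo)
    patch <- Xp[rs, cs, , , drop = FALSE]
    rows <- (seq_len(C) - 1L) * (kh * kw) + (kj - 1L) * kh + ki
    cols[rows, ] <- matrix(aperm(patch, c(3, 1, 2, 4)), nrow = C)
  }
  list(cols = cols, Ho = Ho, Wo = Wo, dims = d)
}

col2im <- function(dcols, dims, kh, kw, stride, pad, Ho, Wo) {
  H <- dims[1]; W <- dims[2]; C <- dims[3]; N <- dims[4]
  dXp <- array(0, c(H + 2L * pad, W + 2L * pad, C, N))
  for (kj in seq_len(kw)) for (ki in seq_len(kh)) {
    rows <- (seq_len(C) - 1L) * (kh * kw) + (kj - 1L) * kh + ki
    patch <- aperm(array(dcols[rows, , drop = FALSE], c(C, Ho, Wo, N)),
                   c(2, 3, 1, 4))
    rs <- seq(ki, by = stride, length.out = Ho)
    cs <- seq(kj, by = stride, length.out = Wo)
    dXp[rs, cs, , ] <- dXp[rs, cs, , , drop = FALSE] + patch
  }
  if (pad > 0)
    dXp[pad + seq_len(H), pad + seq_len(W), , , drop = FALSE]
  else dXp
}

conv_forward <- function(layer, X) {
  ic <- im2col(X, layer$kh, layer$kw, layer$stride, layer$pad)
  Wmat <- matrix(layer$W, layer$kh * layer$kw * dim(layer$W)[3],
                 dim(layer$W)[4])
  out <- crossprod(Wmat, ic$cols) + layer$b
  f <- dim(layer$W)[4]
  out <- aperm(array(out, c(f, ic$Ho, ic$Wo, ic$dims[4])), c(2, 3, 1, 4))
  list(out = out, cache = ic)
}

conv_backward <- function(layer, cache, dout) {
  f <- dim(layer$W)[4]
  dmat <- matrix(aperm(dout, c(3, 1, 2, 4)), nrow = f)
  dW <- array(tcrossprod(cache$cols, dmat), dim(layer$W))
  db <- rowSums(dmat)
  Wmat <- matrix(layer$W, layer$kh * layer$kw * dim(layer$W)[3], f)
  dcols <- Wmat %*% dmat
  dx <- col2im(dcols, cache$dims, layer$kh, layer$kw, layer$stride,
               layer$pad, cache$Ho, cache$Wo)
  list(dx = dx, grads = list(W = dW, b = db))
}

# ---- batch norm (per channel over H, W, N) ----------------------------------

bc_channel <- function(v, d) aperm(array(v, c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))

bn_forward <- function(layer, X, training) {
  d <- dim(X); C <- d[3]; n <- d[1] * d[2] * d[4]
  Xm <- matrix(aperm(X, c(1, 2, 4, 3)), ncol = C)
  if (training) {
    mu <- colMeans(Xm)
    va <- colMeans(Xm^2) - mu^2
    layer$rm <- layer$momentum * layer$rm + (1 - layer$momentum) * mu
    layer$rv <- layer$momentum * layer$rv + (1 - layer$momentum) * va
  } else {
    mu <- layer$rm; va <- layer$rv
  }
  ivar <- 1 / sqrt(va + layer$eps)
  xhat <- (X - bc_channel(mu, d)) * bc_channel(ivar, d)
  out <- bc_channel(layer$gamma, d) * xhat + bc_channel(layer$beta, d)
  list(out = out, cache = list(xhat = xhat, ivar = ivar, n = n, d = d),
       layer = layer)
}

bn_backward <- function(layer, cache, dout) {
  d <- cache$d; C <- d[3]; n <- cache$n
  xhat <- cache$xhat
  dm <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = C)
  xm <- matrix(aperm(xhat, c(1, 2, 4, 3)), ncol = C)
  dgamma <- colSums(dm * xm)
  dbeta <- colSums(dm)
  coef <- layer$gamma * cache$ivar / n
  dx <- bc_channel(coef, d) *
    (n * dout - bc_channel(dbeta, d) - xhat * bc_channel(dgamma, d))
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# ---- pooling / activations --------------------------------------------------

maxpool_forward <- function(layer, X) {
  d <- dim(X); k <- layer$k; s <- layer$stride; p <- layer$pad
  Ho <- (d[1] + 2L * p - k) %/% s + 1L
  Wo <- (d[2] + 2L * p - k) %/% s + 1L
  if (p > 0) {
    Xp <- array(-Inf, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
    Xp[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- X
  } else Xp <- X
  out <- array(-Inf, c(Ho, Wo, d[3], d[4]))
  amax <- array(0L, c(Ho, Wo, d[3], d[4]))
  code <- 0L
  for (kj in seq_len(k)) for (ki in seq_len(k)) {
    code <- code + 1L
    rs <- seq(ki, by = s, length.out = Ho)
    cs <- seq(kj, by = s, length.out = Wo)
    patch <- Xp[rs, cs, , , drop = FALSE]
    upd <- patch > out
    out[upd] <- patch[upd]
    amax[upd] <- code
  }
  list(out = out, cache = list(amax = amax, d = d, Ho = Ho, Wo = Wo))
}

maxpool_backward <- function(layer, cache, dout) {
  d <- cache$d; k <- layer$k; s <- layer$stride; p <- layer$pad
  dXp <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  code <- 0L
  for (kj in seq_len(k)) for (ki in seq_len(k)) {
    code <- code + 1L
    rs <- seq(ki, by = s, length.out = cache$Ho)
    cs <- seq(kj, by = s, length.out = cache$Wo)
    contrib <- dout * (cache$amax == code)
    dXp[rs, cs, , ] <- dXp[rs, cs, , , drop = FALSE] + contrib
  }
  dx <- if (p > 0) dXp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE]
        else dXp
  list(dx = dx, grads = NULL)
}

relu_forward <- function(X) list(out = pmax(X, 0), cache = X > 0)
relu_backward <- function(cache, dout) dout * cache

gap_forward <- function(X) {
  d <- dim(X)
  out <- matrix(colMeans(matrix(X, d[1] * d[2], d[3] * d[4])), d[3], d[4])
  list(out = out, cache = d)
}
gap_backward <- function(cache, dout) {
  d <- cache
  g <- array(rep(as.numeric(dout), each = d[1] * d[2]) / (d[1] * d[2]), d)
  g
}

flatten_forward <- function(X) {
  d <- dim(X)
  list(out = matrix(X, prod(d[1:3]), d[4]), cache = d)
}
flatten_backward <- function(cache, dout) array(dout, cache)

dense_forward <- function(layer, X) list(out = layer$W %*% X + layer$b, cache = X)
dense_backward <- function(layer, cache, dout) {
  list(dx = crossprod(layer$W, dout),
       grads = list(W = tcrossprod(dout, cache), b = rowSums(dout)))
}

# ---- model composition ------------------------------------------------------

layer_forward <- function(layer, X, training) {
  switch(layer$type,
    conv = c(conv_forward(layer, X), list(layer = layer)),
    bn = bn_forward(layer, X, training),
    relu = c(relu_forward(X), list(layer = layer)),
    maxpool = c(maxpool_forward(layer, X), list(layer = layer)),
    gap = c(gap_forward(X), list(layer = layer)),
    flatten = c(flatten_forward(X), list(layer = layer)),
    dense = c(dense_forward(layer, X), list(layer = layer)),
    bottleneck = bottleneck_forward(layer, X, training),
    stop_sf("unknown layer type: ", layer$type))
}

layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    conv = conv_backward(layer, cache, dout),
    bn = bn_backward(layer, cache, dout),
    relu = list(dx = relu_backward(cache, dout), grads = NULL),
    maxpool = maxpool_backward(layer, cache, dout),
    gap = list(dx = gap_backward(cache, dout), grads = NULL),
    flatten = list(dx = flatten_backward(cache, dout), grads = NULL),
    dense = dense_backward(layer, cache, dout),
    bottleneck = bottleneck_backward(layer, cache, dout))
}

forward_layers <- function(layers, X, training) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], X, training)
    X <- r$out
    caches[[i]] <- r$cache
    layers[[i]] <- r$layer
  }
  list(out = X, caches = caches, layers = layers)
}

backward_layers <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], dout)
    dout <- r$dx
    grads[i] <- list(r$grads)     # keep NULL placeholders for param-free layers
  }
  list(dx = dout, grads = grads)
}

# ---- residual bottleneck unit (1x1 -> 3x3 -> 1x1 with skip) -----------------

nn_bottleneck <- function(c_in, c_mid, c_out, stride = 1L) {
  main <- list(nn_conv(1L, 1L, c_in, c_mid, stride = stride), nn_bn(c_mid), nn_relu(),
               nn_conv(3L, 3L, c_mid, c_mid, pad = 1L), nn_bn(c_mid), nn_relu(),
               nn_conv(1L, 1L, c_mid, c_out), nn_bn(c_out))
  shortcut <- if (c_in != c_out || stride != 1L)
    list(nn_conv(1L, 1L, c_in, c_out, stride = stride), nn_bn(c_out))
  else NULL
  list(type = "bottleneck", main = main, shortcut = shortcut)
}

bottleneck_forward <- function(layer, X, training) {
  fm <- forward_layers(layer$main, X, training)
  layer$main <- fm$layers
  if (is.null(layer$shortcut)) {
    sout <- X; scache <- NULL
  } else {
    fs <- forward_layers(layer$shortcut, X, training)
    layer$shortcut <- fs$layers
    sout <- fs$out; scache <- fs$caches
  }
  pre <- fm$out + sout
  r <- relu_forward(pre)
  list(out = r$out,
       cache = list(main = fm$caches, shortcut = scache, relu = r$cache),
       layer = layer)
}

bottleneck_backward <- function(layer, cache, dout) {
  dpre <- relu_backward(cache$relu, dout)
  bm <- backward_layers(layer$main, cache$main, dpre)
  if (is.null(layer$shortcut)) {
    dx <- bm$dx + dpre
    grads <- list(main = bm$grads, shortcut = NULL)
  } else {
    bs <- backward_layers(layer$shortcut, cache$shortcut, dpre)
    dx <- bm$dx + bs$dx
    grads <- list(main = bm$grads, shortcut = bs$grads)
  }
  list(dx = dx, grads = grads)
}

# ---- SGD with momentum + L2 weight decay ------------------------------------

sgd_update_layer <- function(layer, grads, lr, momentum, wd) {
  if (is.null(grads)) return(layer)
  if (layer$type == "bottleneck") {
    for (i in seq_along(layer$main))
      layer$main[[i]] <- sgd_update_layer(layer$main[[i]], grads$main[[i]],
                                          lr, momentum, wd)
    if (!is.null(layer$shortcut))
      for (i in seq_along(layer$shortcut))
        layer$shortcut[[i]] <- sgd_update_layer(layer$shortcut[[i]],
                                                grads$shortcut[[i]],
                                                lr, momentum, wd)
    return(layer)
  }
  if (layer$type %in% c("conv", "dense")) {
    layer$vW <- momentum * layer$vW - lr * (grads$W + wd * layer$W)
    layer$W <- layer$W + layer$vW
    layer$vb <- momentum * layer$vb - lr * grads$b
    layer$b <- layer$b + layer$vb
  } else if (layer$type == "bn") {
    layer$vgamma <- momentum * layer$vgamma - lr * grads$gamma
    layer$gamma <- layer$gamma + layer$vgamma
    layer$vbeta <- momentum * layer$vbeta - lr * grads$beta
    layer$beta <- layer$beta + layer$vbeta
  }
  layer
}

sgd_update <- function(layers, grads, lr, momentum, wd) {
  for (i in seq_along(layers))
    layers[[i]] <- sgd_update_layer(layers[[i]], grads[[i]], lr, momentum, wd)
  layers
}

softmax_cols <- function(z) {
  z <- z - matrix(apply(z, 2, max), nrow(z), ncol(z), byrow = TRUE)
  e <- exp(z)
  e / matrix(colSums(e), nrow(z), ncol(z), byrow = TRUE)
}

# ---- architectures ----------------------------------------------------------

# Desk-scale profile: two conv-bn-relu-pool blocks, flatten, softmax head(s).
# The head dense layers are created lazily once the flattened size is known.
build_small_cnn_trunk <- function(c_in) {
  list(nn_conv(3L, 3L, c_in, 8L, pad = 1L), nn_bn(8L), nn_relu(), nn_maxpool(),
       nn_conv(3L, 3L, 8L, 16L, pad = 1L), nn_bn(16L), nn_relu(), nn_maxpool(),
       nn_flatten())
}

# ResNet50-style trunk: 7x7/2 stem, 3x3/2 max pool, bottleneck groups of
# 3/4/6/3 units, global average pool. Full contract, smoke-tested only at
# desk scale (training it in pure R is out of test budget).
build_resnet50_trunk <- function(c_in) {
  layers <- list(nn_conv(7L, 7L, c_in, 64L, stride = 2L, pad = 3L),
                 nn_bn(64L), nn_relu(), nn_maxpool(3L, 2L, 1L))
  groups <- list(c(64L, 256L, 3L, 1L), c(128L, 512L, 4L, 2L),
                 c(256L, 1024L, 6L, 2L), c(512L, 2048L, 3L, 2L))
  ch <- 64L
  for (g in groups) {
    c_mid <- g[1]; c_out <- g[2]; n_units <- g[3]; stride1 <- g[4]
    for (u in seq_len(n_units)) {
      layers <- c(layers, list(nn_bottleneck(ch, c_mid, c_out,
                                             stride = if (u == 1L) stride1 else 1L)))
      ch <- c_out
    }
  }
  c(layers, list(nn_gap()))
}

trunk_out_dim <- function(layers, input_dim) {
  X <- array(0, c(input_dim, 1L))
  out <- forward_layers(layers, X, training = FALSE)$out
  nrow(out)
}
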