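# Minimal reverse-mode neural-network core.
#
# Layers are environments holding parameters, gradients and forward caches;
# nn_forward()/nn_backward() dispatch on $type. Convolutional tensors use
# dim (H, W, C, N); vector activations are N x d matrices. Everything is
# sized for scalp-map inputs (9 x 9 spatial planes, 62-node graphs), where
# plain matrix code on 1 CPU is entirely adequate.

new_layer <- function(type, params = list(), ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- params
  e$grads <- lapply(params, function(p) p * 0)
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(paste0("nn_", type), "nn_layer")
  e
}

he_init <- function(n, fan_in) stats::rnorm(n, sd = sqrt(2 / fan_in))
glorot_init <- function(n, fan_in, fan_out) stats::rnorm(n, sd = sqrt(2 / (fan_in + fan_out)))

# ---- conv2d -----------------------------------------------------------------

layer_conv2d <- function(in_ch, out_ch, k, stride = 1L, pad = 0L, bias = TRUE) {
  W <- matrix(he_init(out_ch * k * k * in_ch, k * k * in_ch), out_ch, k * k * in_ch)
  params <- list(W = W)
  if (bias) params$b <- numeric(out_ch)
  new_layer("conv2d", params,
            in_ch = in_ch, out_ch = out_ch, k = as.integer(k),
            stride = as.integer(stride), pad = as.integer(pad),
            has_bias = bias, idx_cache = NULL, idx_key = "")
}

pad_hw <- function(x, p, value = 0) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(value, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  out[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), , ] <- x
  out
}

# im2col index matrix for one (Hp x Wp x C) volume: rows are patch elements
# (kernel row fastest, then kernel col, then channel), columns are output
# positions (output row fastest).
conv_idx <- function(Hp, Wp, C, k, s, oh, ow) {
  pe <- expand.grid(a = 0:(k - 1L), b = 0:(k - 1L), cc = 0:(C - 1L))
  po <- expand.grid(i = 0:(oh - 1L), j = 0:(ow - 1L))
  outer(pe$a, po$i * s, "+") +
    (outer(pe$b, po$j * s, "+") + matrix(pe$cc, nrow(pe), nrow(po)) * Wp) * Hp + 1L
}

forward_conv2d <- function(l, x, train) {
  d <- dim(x); H <- d[1]; W_ <- d[2]; C <- d[3]; N <- d[4]
  if (C != l$in_ch) abort(sprintf("conv2d expects %d channels, got %d", l$in_ch, C), "invalid_data")
  xp <- pad_hw(x, l$pad)
  Hp <- H + 2L * l$pad; Wp <- W_ + 2L * l$pad
  oh <- (Hp - l$k) %/% l$stride + 1L
  ow <- (Wp - l$k) %/% l$stride + 1L
  if (oh < 1L || ow < 1L) abort("conv2d spatial collapse below 1x1", "invalid_config")
  key <- paste(H, W_, C, N)
  if (is.null(l$geom)) l$geom <- list()
  if (is.null(l$geom[[key]])) {
    idx <- conv_idx(Hp, Wp, C, l$k, l$stride, oh, ow)
    offs <- (0:(N - 1L)) * (Hp * Wp * C)
    idx_full <- rep(as.vector(idx), N) + rep(offs, each = length(idx))
    l$geom[[key]] <- list(
      idx_full = idx_full,
      scatter = Matrix::sparseMatrix(i = idx_full, j = seq_along(idx_full),
                                     x = 1, dims = c(Hp * Wp * C * N, length(idx_full))),
      dims = list(H = H, W = W_, Hp = Hp, Wp = Wp, oh = oh, ow = ow, N = N))
  }
  l$scatter <- l$geom[[key]]$scatter
  l$idx_full <- l$geom[[key]]$idx_full
  l$dims <- l$geom[[key]]$dims
  dm <- l$dims
  cols <- matrix(xp[l$idx_full], l$k * l$k * C)
  y <- l$params$W %*% cols
  if (l$has_bias) y <- y + l$params$b
  l$cache <- list(cols = cols)
  aperm(array(y, c(l$out_ch, dm$oh, dm$ow, dm$N)), c(2, 3, 1, 4))
}

backward_conv2d <- function(l, dout) {
  dm <- l$dims
  dym <- matrix(aperm(dout, c(3, 1, 2, 4)), l$out_ch)
  l$grads$W <- l$grads$W + tcrossprod(dym, l$cache$cols)
  if (l$has_bias) l$grads$b <- l$grads$b + rowSums(dym)
  dcols <- crossprod(l$params$W, dym)
  # col2im as one sparse scatter-sum (precomputed per geometry)
  dxp <- array(as.numeric(l$scatter %*% as.vector(dcols)),
               c(dm$Hp, dm$Wp, l$in_ch, dm$N))
  p <- l$pad
  if (p > 0L) dxp <- dxp[(p + 1L):(p + dm$H), (p + 1L):(p + dm$W), , , drop = FALSE]
  dxp
}

# ---- batch norm (2d) --------------------------------------------------------

layer_bn2d <- function(ch, momentum = 0.1, eps = 1e-5) {
  new_layer("bn2d", list(gamma = rep(1, ch), beta = numeric(ch)),
            ch = ch, momentum = momentum, eps = eps,
            running_mean = numeric(ch), running_var = rep(1, ch))
}

ch_sums <- function(x, HW, C, N) rowSums(matrix(colSums(matrix(x, HW, C * N)), C, N))

forward_bn2d <- function(l, x, train) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]; m <- HW * N
  if (train) {
    mu <- ch_sums(x, HW, C, N) / m
    v <- ch_sums(x * x, HW, C, N) / m - mu^2
    l$running_mean <- (1 - l$momentum) * l$running_mean + l$momentum * mu
    l$running_var <- (1 - l$momentum) * l$running_var + l$momentum * v
  } else {
    mu <- l$running_mean
    v <- l$running_var
  }
  ivar <- 1 / sqrt(v + l$eps)
  xhat <- (x - rep(mu, each = HW)) * rep(ivar, each = HW)
  l$cache <- list(xhat = xhat, ivar = ivar, HW = HW, C = C, N = N, m = m, train = train)
  xhat * rep(l$params$gamma, each = HW) + rep(l$params$beta, each = HW)
}

backward_bn2d <- function(l, dout) {
  cc <- l$cache; HW <- cc$HW; C <- cc$C; N <- cc$N; m <- cc$m
  dgamma <- ch_sums(dout * cc$xhat, HW, C, N)
  dbeta <- ch_sums(dout, HW, C, N)
  l$grads$gamma <- l$grads$gamma + dgamma
  l$grads$beta <- l$grads$beta + dbeta
  gi <- rep(l$params$gamma * cc$ivar, each = HW)
  if (cc$train) {
    gi * (dout - rep(dbeta / m, each = HW) - cc$xhat * rep(dgamma / m, each = HW))
  } else {
    gi * dout
  }
}

# ---- elementwise ------------------------------------------------------------

layer_relu <- function() new_layer("relu")
forward_relu <- function(l, x, train) {
  l$cache <- x > 0
  x * l$cache
}
backward_relu <- function(l, dout) dout * l$cache

layer_elu <- function() new_layer("elu")
forward_elu <- function(l, x, train) {
  pos <- x > 0
  y <- x * pos + (exp(pmin(x, 0)) - 1) * !pos
  l$cache <- list(pos = pos, y = y)
  y
}
backward_elu <- function(l, dout) dout * (l$cache$pos + (l$cache$y + 1) * !l$cache$pos)

layer_dropout <- function(rate) new_layer("dropout", rate = rate, stream = NULL)
forward_dropout <- function(l, x, train) {
  if (!train || l$rate <= 0) {
    l$cache <- NULL
    return(x)
  }
  draw <- function() (stats::runif(length(x)) >= l$rate) / (1 - l$rate)
  mask <- if (is.null(l$stream)) draw() else with_stream(l$stream, draw())
  l$cache <- mask
  x * mask
}
backward_dropout <- function(l, dout) if (is.null(l$cache)) dout else dout * l$cache

# Gradient reversal: identity forward, gradient scaled by -lambda backward.
layer_grl <- function(lambda = 1) new_layer("grl", lambda = lambda)
forward_grl <- function(l, x, train) x
backward_grl <- function(l, dout) -l$lambda * dout

# ---- pooling ----------------------------------------------------------------

layer_maxpool <- function(k, stride, pad = 0L) {
  new_layer("maxpool", k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad), idx_key = "")
}

forward_maxpool <- function(l, x, train) {
  d <- dim(x); H <- d[1]; W_ <- d[2]; C <- d[3]; N <- d[4]
  xp <- pad_hw(x, l$pad, value = -Inf)
  Hp <- H + 2L * l$pad; Wp <- W_ + 2L * l$pad
  oh <- (Hp - l$k) %/% l$stride + 1L
  ow <- (Wp - l$k) %/% l$stride + 1L
  key <- paste(H, W_, C, N)
  if (is.null(l$geom)) l$geom <- list()
  if (is.null(l$geom[[key]])) {
    idx <- conv_idx(Hp, Wp, 1L, l$k, l$stride, oh, ow)
    offs <- (0:(C * N - 1L)) * (Hp * Wp)
    l$geom[[key]] <- list(
      idx_full = rep(as.vector(idx), C * N) + rep(offs, each = length(idx)),
      dims = list(oh = oh, ow = ow, C = C, N = N, np = Hp * Wp * C * N,
                  H = H, W = W_))
  }
  l$idx_full <- l$geom[[key]]$idx_full
  l$dims <- l$geom[[key]]$dims
  dm <- l$dims
  cols <- matrix(xp[l$idx_full], l$k * l$k)
  am <- max.col(t(cols), ties.method = "first")
  sel <- cbind(am, seq_along(am))
  l$cache <- list(src = matrix(l$idx_full, l$k * l$k)[sel])
  array(cols[sel], c(dm$oh, dm$ow, dm$C, dm$N))
}

backward_maxpool <- function(l, dout) {
  dm <- l$dims
  acc <- rowsum(as.vector(dout), l$cache$src)
  dxp <- numeric(dm$np)
  dxp[as.integer(rownames(acc))] <- acc
  p <- l$pad
  H <- dm$H; W_ <- dm$W
  dxp <- array(dxp, c(H + 2L * p, W_ + 2L * p, dm$C, dm$N))
  if (p > 0L) dxp <- dxp[(p + 1L):(p + H), (p + 1L):(p + W_), , , drop = FALSE]
  dxp
}

layer_gap <- function() new_layer("gap")
forward_gap <- function(l, x, train) {
  d <- dim(x)
  l$cache <- d
  t(matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4]))
}
backward_gap <- function(l, dout) {
  d <- l$cache; HW <- d[1] * d[2]
  array(rep(as.vector(t(dout)) / HW, each = HW), d)
}

# ---- dense ------------------------------------------------------------------

layer_linear <- function(in_dim, out_dim, bias = TRUE) {
  W <- matrix(glorot_init(out_dim * in_dim, in_dim, out_dim), out_dim, in_dim)
  params <- list(W = W)
  if (bias) params$b <- numeric(out_dim)
  new_layer("linear", params, in_dim = in_dim, out_dim = out_dim, has_bias = bias)
}

forward_linear <- function(l, x, train) {
  l$cache <- x
  y <- tcrossprod(x, l$params$W)
  if (l$has_bias) y <- sweep(y, 2L, l$params$b, "+")
  y
}
backward_linear <- function(l, dout) {
  l$grads$W <- l$grads$W + crossprod(dout, l$cache)
  if (l$has_bias) l$grads$b <- l$grads$b + colSums(dout)
  dout %*% l$params$W
}

# ---- graph attention layer --------------------------------------------------

# Single-head graph attention: e_ij = LeakyReLU(a^T [W h_i || W h_j]) over the
# self-looped neighbourhood, row-softmax to attention weights, attention-
# weighted aggregation of transformed neighbours, then nonlinearity sigma.
layer_gal <- function(in_dim, out_dim, mask, slope = 0.2, sigma = c("elu", "identity")) {
  sigma <- match.arg(sigma)
  # dense padded-neighbour table: nb[i, d] is the d-th neighbour of node i
  # (self-loops guarantee degree >= 1); padm flags real vs padding slots
  nn <- nrow(mask)
  deg <- rowSums(mask)
  D <- max(deg)
  if (!isTRUE(all(mask == t(mask)))) abort("gal mask must be symmetric", "invalid_data")
  nb <- matrix(1L, nn, D)
  padm <- matrix(0, nn, D)
  for (i in seq_len(nn)) {
    nbi <- which(mask[i, ])
    nb[i, seq_along(nbi)] <- nbi
    padm[i, seq_along(nbi)] <- 1
  }
  # revpos[j, d]: position of node j in the neighbour list of its d-th
  # neighbour (defined because the mask is symmetric); lets the backward
  # pass use pure gathers instead of grouped scatter-sums
  revpos <- matrix(1L, nn, D)
  for (j in seq_len(nn)) {
    for (d in seq_len(D)) {
      if (padm[j, d] == 1) {
        i <- nb[j, d]
        revpos[j, d] <- which(nb[i, ] == j & padm[i, ] == 1)
      }
    }
  }
  new_layer("gal",
            list(W = matrix(glorot_init(out_dim * in_dim, in_dim, out_dim), out_dim, in_dim),
                 a1 = glorot_init(out_dim, out_dim, 1),
                 a2 = glorot_init(out_dim, out_dim, 1)),
            in_dim = in_dim, out_dim = out_dim, mask = mask,
            nb = nb, padm = padm, revpos = revpos, deg_max = D, n_nodes = nn,
            slope = slope, sigma = sigma, bgeom = list())
}

gal_sigma <- function(sigma, s) {
  if (sigma == "identity") return(list(y = s, dfac = 1 + 0 * s))
  pos <- s > 0
  y <- s * pos + (exp(pmin(s, 0)) - 1) * !pos
  list(y = y, dfac = pos + (y + 1) * !pos)
}

forward_gal <- function(l, x, train) {
  d <- dim(x); nn <- d[1]; N <- d[3]
  if (d[2] != l$in_dim) abort("gal input dimension mismatch", "invalid_data")
  if (nn != l$n_nodes) abort("gal node-count mismatch", "invalid_data")
  key <- as.character(N)
  if (is.null(l$bgeom[[key]])) {
    rr <- rep(seq_len(nn), N)
    l$bgeom[[key]] <- list(
      NB = l$nb[rr, , drop = FALSE] + rep((0:(N - 1L)) * nn, each = nn),
      PADM = l$padm[rr, , drop = FALSE],
      REVPOS = l$revpos[rr, , drop = FALSE])
  }
  NB <- l$bgeom[[key]]$NB
  PADM <- l$bgeom[[key]]$PADM
  D <- l$deg_max
  # rows ordered node-fastest, then sample
  Hmat <- matrix(aperm(x, c(1, 3, 2)), nn * N, l$in_dim)
  Z <- tcrossprod(Hmat, l$params$W)
  u <- drop(Z %*% l$params$a1)
  v <- drop(Z %*% l$params$a2)
  P <- matrix(v[NB], nn * N, D) + u          # e_ij logits before LeakyReLU
  pos <- P > 0
  E <- P * (pos + l$slope * !pos)
  E[PADM == 0] <- -1e30
  m <- E[, 1]
  if (D > 1) for (dd in 2:D) m <- pmax(m, E[, dd])
  A <- exp(E - m) * PADM
  A <- A / rowSums(A)
  S <- matrix(0, nn * N, l$out_dim)
  for (dd in seq_len(D)) S <- S + A[, dd] * Z[NB[, dd], , drop = FALSE]
  sg <- gal_sigma(l$sigma, S)
  l$cache <- list(Hmat = Hmat, Z = Z, A = A, pos = pos, dfac = sg$dfac,
                  NB = NB, PADM = PADM, REVPOS = l$bgeom[[key]]$REVPOS,
                  nn = nn, N = N)
  aperm(array(sg$y, c(nn, N, l$out_dim)), c(1, 3, 2))
}

backward_gal <- function(l, dout) {
  cc <- l$cache
  nn <- cc$nn; N <- cc$N; D <- l$deg_max
  dS <- matrix(aperm(dout, c(1, 3, 2)), nn * N, l$out_dim) * cc$dfac
  dA <- matrix(0, nn * N, D)
  dZ <- matrix(0, nn * N, l$out_dim)
  for (dd in seq_len(D)) {
    dA[, dd] <- rowSums(dS * cc$Z[cc$NB[, dd], , drop = FALSE])
    # dZ_j += sum_i alpha_ij dS_i, gathered through the reverse tables
    w <- cc$A[cbind(cc$NB[, dd], cc$REVPOS[, dd])] * cc$PADM[, dd]
    dZ <- dZ + w * dS[cc$NB[, dd], , drop = FALSE]
  }
  rs <- rowSums(dA * cc$A)
  dE <- cc$A * (dA - rs)
  dP <- dE * (cc$pos + l$slope * !cc$pos)
  dP[cc$PADM == 0] <- 0
  du <- rowSums(dP)
  dv <- numeric(nn * N)
  for (dd in seq_len(D)) {
    dv <- dv + dP[cbind(cc$NB[, dd], cc$REVPOS[, dd])] * cc$PADM[, dd]
  }
  dZ <- dZ + outer(du, l$params$a1) + outer(dv, l$params$a2)
  l$grads$a1 <- l$grads$a1 + drop(crossprod(cc$Z, du))
  l$grads$a2 <- l$grads$a2 + drop(crossprod(cc$Z, dv))
  l$grads$W <- l$grads$W + crossprod(dZ, cc$Hmat)
  dH <- dZ %*% l$params$W
  aperm(array(dH, c(nn, N, l$in_dim)), c(1, 3, 2))
}

# Reconstruct dense per-sample attention matrices (nn x nn) from the padded
# cache; used by tests and diagnostics.
gal_attention <- function(l) {
  cc <- l$cache
  lapply(seq_len(cc$N), function(s) {
    rows <- (s - 1L) * cc$nn + seq_len(cc$nn)
    A <- matrix(0, cc$nn, cc$nn)
    for (dd in seq_len(l$deg_max)) {
      real <- l$padm[, dd] == 1
      A[cbind(seq_len(cc$nn), l$nb[, dd])[real, , drop = FALSE]] <-
        cc$A[rows, dd][real]
    }
    A
  })
}

# Node readout: mean over nodes -> N x d, or flatten -> N x (nodes * d).
layer_node_readout <- function(kind = c("mean", "flatten")) {
  new_layer("node_readout", kind = match.arg(kind))
}
forward_node_readout <- function(l, x, train) {
  d <- dim(x)
  l$cache <- d
  if (l$kind == "mean") {
    t(matrix(colMeans(matrix(x, d[1], d[2] * d[3])), d[2], d[3]))
  } else {
    matrix(x, d[1] * d[2], d[3]) |> t()
  }
}
backward_node_readout <- function(l, dout) {
  d <- l$cache
  if (l$kind == "mean") {
    array(rep(as.vector(t(dout)) / d[1], each = d[1]), d)
  } else {
    array(t(dout), d)
  }
}

# ---- residual basic block ---------------------------------------------------

# Two 3x3 conv/BN stages with mid ReLU on the main path; shortcut is identity
# when shapes match, a stride-matched 1x1 conv + BN projection otherwise
# ("standard"), or the printed 3x3 -> 1x1 -> BN composition ("printed").
layer_basic_block <- function(in_ch, out_ch, stride = 1L,
                              shortcut = c("standard", "printed")) {
  shortcut <- match.arg(shortcut)
  main <- list(
    layer_conv2d(in_ch, out_ch, 3L, stride = stride, pad = 1L, bias = FALSE),
    layer_bn2d(out_ch),
    layer_relu(),
    layer_conv2d(out_ch, out_ch, 3L, stride = 1L, pad = 1L, bias = FALSE),
    layer_bn2d(out_ch)
  )
  sc <- if (shortcut == "printed") {
    list(layer_conv2d(in_ch, out_ch, 3L, stride = stride, pad = 1L, bias = FALSE),
         layer_conv2d(out_ch, out_ch, 1L, stride = 1L, pad = 0L, bias = FALSE),
         layer_bn2d(out_ch))
  } else if (in_ch != out_ch || stride != 1L) {
    list(layer_conv2d(in_ch, out_ch, 1L, stride = stride, pad = 0L, bias = FALSE),
         layer_bn2d(out_ch))
  } else {
    NULL
  }
  new_layer("basic_block", main = main, shortcut = sc)
}

forward_basic_block <- function(l, x, train) {
  xm <- seq_forward(l$main, x, train)
  xs <- if (is.null(l$shortcut)) x else seq_forward(l$shortcut, x, train)
  s <- xm + xs
  l$cache <- s > 0
  s * l$cache
}
backward_basic_block <- function(l, dout) {
  ds <- dout * l$cache
  dx <- seq_backward(l$main, ds)
  if (is.null(l$shortcut)) dx + ds else dx + seq_backward(l$shortcut, ds)
}

# ---- dispatch, sequencing, optimisation -------------------------------------

nn_forward <- function(l, x, train = FALSE) {
  switch(l$type,
         conv2d = forward_conv2d(l, x, train),
         bn2d = forward_bn2d(l, x, train),
         relu = forward_relu(l, x, train),
         elu = forward_elu(l, x, train),
         dropout = forward_dropout(l, x, train),
         grl = forward_grl(l, x, train),
         maxpool = forward_maxpool(l, x, train),
         gap = forward_gap(l, x, train),
         linear = forward_linear(l, x, train),
         gal = forward_gal(l, x, train),
         node_readout = forward_node_readout(l, x, train),
         basic_block = forward_basic_block(l, x, train),
         abort(paste0("unknown layer type ", l$type), "invalid_config"))
}

nn_backward <- function(l, dout) {
  switch(l$type,
         conv2d = backward_conv2d(l, dout),
         bn2d = backward_bn2d(l, dout),
         relu = backward_relu(l, dout),
         elu = backward_elu(l, dout),
         dropout = backward_dropout(l, dout),
         grl = backward_grl(l, dout),
         maxpool = backward_maxpool(l, dout),
         gap = backward_gap(l, dout),
         linear = backward_linear(l, dout),
         gal = backward_gal(l, dout),
         node_readout = backward_node_readout(l, dout),
         basic_block = backward_basic_block(l, dout),
         abort(paste0("unknown layer type ", l$type), "invalid_config"))
}

seq_forward <- function(layers, x, train = FALSE) {
  for (l in layers) x <- nn_forward(l, x, train)
  x
}

seq_backward <- function(layers, dout) {
  for (l in rev(layers)) dout <- nn_backward(l, dout)
  dout
}

# Flatten nested layer containers to the layers that own parameters.
collect_layers <- function(x) {
  if (is.environment(x)) {
    inner <- list()
    if (!is.null(x$main)) inner <- c(inner, collect_layers(x$main), collect_layers(x$shortcut))
    c(list(x), inner)
  } else if (is.list(x)) {
    do.call(c, c(lapply(x, collect_layers), list(list())))
  } else {
    list()
  }
}

nn_zero_grads <- function(layers) {
  for (l in layers) l$grads <- lapply(l$params, function(p) p * 0)
  invisible(NULL)
}

# Adam with bias correction; optimiser state lives on the layer environments.
adam_step <- function(layers, t, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in layers) {
    if (!length(l$params)) next
    if (is.null(l$adam_m)) {
      l$adam_m <- lapply(l$params, function(p) p * 0)
      l$adam_v <- lapply(l$params, function(p) p * 0)
    }
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      l$adam_m[[nm]] <- beta1 * l$adam_m[[nm]] + (1 - beta1) * g
      l$adam_v[[nm]] <- beta2 * l$adam_v[[nm]] + (1 - beta2) * g * g
      mhat <- l$adam_m[[nm]] / (1 - beta1^t)
      vhat <- l$adam_v[[nm]] / (1 - beta2^t)
      l$params[[nm]] <- l$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(NULL)
}

# Softmax cross-entropy head utility: returns probabilities, mean loss over
# rows weighted by `w`, and the logits gradient.
softmax_ce <- function(logits, labels = NULL, w = NULL) {
  z <- logits - apply(logits, 1L, max)
  p <- exp(z)
  p <- p / rowSums(p)
  out <- list(probs = p)
  if (!is.null(labels)) {
    n <- nrow(p)
    if (is.null(w)) w <- rep(1 / n, n)
    sel <- cbind(seq_len(n), labels + 1L)
    out$loss <- -sum(w * log(pmax(p[sel], 1e-12)))
    g <- p
    g[sel] <- g[sel] - 1
    out$dlogits <- g * w
  }
  out
}
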