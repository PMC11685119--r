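# Independent oracles and small fixture builders shared across tests.

# Dense brute-force evaluation of one graph attention layer, written directly
# from the defining equations (transform, pairwise LeakyReLU logits over the
# self-looped neighbourhood, row softmax, weighted aggregation, nonlinearity).
# Deliberately loop-based and independent of the package's implementation.
gal_oracle <- function(H, A, W, a1, a2, slope = 0.2, sigma = "elu") {
  n <- nrow(H)
  dout <- nrow(W)
  Z <- H %*% t(W)
  out <- matrix(NA_real_, n, dout)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    e <- numeric(length(nb))
    for (q in seq_along(nb)) {
      j <- nb[q]
      pre <- sum(a1 * Z[i, ]) + sum(a2 * Z[j, ])
      e[q] <- if (pre > 0) pre else slope * pre
    }
    al <- exp(e - max(e))
    al <- al / sum(al)
    s <- rep(0, dout)
    for (q in seq_along(nb)) s <- s + al[q] * Z[nb[q], ]
    out[i, ] <- if (sigma == "identity") s else ifelse(s > 0, s, exp(s) - 1)
  }
  out
}

# Attention weights only (for the row-sum and neighbourhood checks).
gal_oracle_alpha <- function(H, A, W, a1, a2, slope = 0.2) {
  n <- nrow(H)
  Z <- H %*% t(W)
  al <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    e <- vapply(nb, function(j) {
      pre <- sum(a1 * Z[i, ]) + sum(a2 * Z[j, ])
      if (pre > 0) pre else slope * pre
    }, 0)
    w <- exp(e - max(e))
    al[i, nb] <- w / sum(w)
  }
  al
}

# FFT band-power fraction of a signal in [lo, hi) Hz.
band_power_fraction <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- (0:(n - 1)) * fs / n
  keep <- (f >= lo & f < hi) | (f > fs - hi & f <= fs - lo)
  sum(p[keep]) / sum(p[-1])  # exclude DC
}

# Random small graph with self-loops, for attention-layer property tests.
random_graph <- function(n, p_edge = 0.5) {
  A <- matrix(stats::rbinom(n * n, 1, p_edge), n)
  A <- pmax(A, t(A))
  diag(A) <- 1
  A
}

# White-noise recording over the packaged layout.
noise_recording <- function(n_samples, fs = 200, sd = 1, label = 0L) {
  lay <- electrode_layout()
  raw_recording(matrix(stats::rnorm(62 * n_samples, sd = sd), 62), fs, lay$names,
                subject_id = "S01", trial_id = "t1", label = label)
}

# Numerical gradient of f at x (central differences), elementwise over x.
num_grad <- function(f, x, eps = 1e-4) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Small labeled (maps, nodes, labels) batch with a class-dependent mean shift
# on class-specific electrodes; linearly separable for moderate shift.
make_toy_batch <- function(n_per_class, K = 2, shift = 2, seed = 1) {
  set.seed(seed)
  lay <- electrode_layout()
  n <- n_per_class * K
  labels <- rep(0:(K - 1), each = n_per_class)
  nodes <- array(rnorm(62 * 5 * n, sd = 0.5), c(62, 5, n))
  for (i in seq_len(n)) {
    picks <- (labels[i] * 10 + 1):(labels[i] * 10 + 10)
    nodes[picks, , i] <- nodes[picks, , i] + shift
  }
  maps <- array(0, c(lay$H, lay$W, 5, n))
  rc <- cbind(lay$grid[, "row"] + 1L, lay$grid[, "col"] + 1L)
  for (i in seq_len(n)) for (b in 1:5) {
    plane <- matrix(0, lay$H, lay$W)
    plane[rc] <- nodes[, b, i]
    maps[, , b, i] <- plane
  }
  list(maps = maps, nodes = nodes, labels = labels)
}

# Small-width extractor configuration used by the training unit tests.
tiny_satfem <- function(dropout = 0, ...) {
  satfem_config(gat_dims = c(8), conv1_out = 4, widths = c(4, 8), blocks = c(1, 1),
                dropout = dropout, ...)
}
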