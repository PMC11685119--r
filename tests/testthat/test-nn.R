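# The layer library is exercised through eegadapt's internal constructors.
lns <- asNamespace("eegadapt")

test_that("graph attention layer matches the dense brute-force oracle", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(2:6, 1)
    din <- sample(2:4, 1)
    dout <- sample(2:5, 1)
    A <- random_graph(n)
    H <- matrix(rnorm(n * din), n)
    gal <- lns$layer_gal(din, dout, mask = A > 0, sigma = "elu")
    got <- lns$nn_forward(gal, array(H, c(n, din, 1)), train = FALSE)[, , 1]
    want <- gal_oracle(H, A, gal$params$W, gal$params$a1, gal$params$a2)
    expect_equal(matrix(got, n), want, tolerance = 1e-6)
  }
})

test_that("attention rows are a probability distribution over the neighbourhood", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    A <- random_graph(n)
    H <- matrix(rnorm(n * 3), n)
    gal <- lns$layer_gal(3, 4, mask = A > 0)
    lns$nn_forward(gal, array(H, c(n, 3, 1)), train = FALSE)
    alpha <- lns$gal_attention(gal)[[1]]
    expect_equal(rowSums(alpha), rep(1, n), tolerance = 1e-6)
    expect_true(all(alpha[A == 0] == 0))
    want <- gal_oracle_alpha(H, A, gal$params$W, gal$params$a1, gal$params$a2)
    expect_equal(alpha, want, tolerance = 1e-8)
  }
})

test_that("attention degenerates correctly on symmetric and single-node graphs", {
  # two identical nodes, fully connected: uniform attention by symmetry
  gal <- lns$layer_gal(3, 4, mask = matrix(TRUE, 2, 2))
  h <- c(0.3, -1, 2)
  lns$nn_forward(gal, array(rbind(h, h), c(2, 3, 1)), train = FALSE)
  expect_equal(lns$gal_attention(gal)[[1]], matrix(0.5, 2, 2))

  # a single self-looped node: alpha = 1 and h' = sigma(W h)
  gal1 <- lns$layer_gal(3, 4, mask = matrix(TRUE, 1, 1), sigma = "elu")
  out <- lns$nn_forward(gal1, array(h, c(1, 3, 1)), train = FALSE)
  expect_equal(lns$gal_attention(gal1)[[1]], matrix(1, 1, 1))
  s <- drop(gal1$params$W %*% h)
  expect_equal(as.vector(out), ifelse(s > 0, s, exp(s) - 1), tolerance = 1e-12)
})

test_that("layer backward passes agree with central finite differences", {
  set.seed(9)
  check_layer <- function(layer, x, tol = 1e-5) {
    y <- lns$nn_forward(layer, x, train = TRUE)
    dout <- array(rnorm(length(y)), dim(y) %||% length(y))
    if (is.null(dim(y))) dim(dout) <- NULL
    lns$nn_zero_grads(list(layer))
    dx <- lns$nn_backward(layer, dout)
    f <- function(xv) {
      xx <- x
      xx[] <- xv
      sum(lns$nn_forward(layer, xx, train = TRUE) * dout)
    }
    expect_equal(as.vector(dx), as.vector(num_grad(f, as.vector(x))), tolerance = tol)
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a

  check_layer(lns$layer_conv2d(2, 3, 3, stride = 2, pad = 1), array(rnorm(5 * 5 * 2 * 2), c(5, 5, 2, 2)))
  check_layer(lns$layer_bn2d(3), array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2)), tol = 1e-4)
  check_layer(lns$layer_linear(4, 3), matrix(rnorm(8), 2))
  check_layer(lns$layer_gal(3, 4, mask = random_graph(5) > 0), array(rnorm(5 * 3 * 2), c(5, 3, 2)), tol = 1e-4)
  check_layer(lns$layer_basic_block(2, 3, stride = 2), array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2)), tol = 1e-4)

  # parameter gradients of a conv layer, same oracle
  conv <- lns$layer_conv2d(1, 2, 3, pad = 1)
  x <- array(rnorm(16), c(4, 4, 1, 1))
  y <- lns$nn_forward(conv, x, TRUE)
  dout <- array(rnorm(length(y)), dim(y))
  lns$nn_zero_grads(list(conv))
  lns$nn_backward(conv, dout)
  fW <- function(wv) {
    conv$params$W[] <- wv
    sum(lns$nn_forward(conv, x, TRUE) * dout)
  }
  W0 <- as.vector(conv$params$W)
  expect_equal(as.vector(conv$grads$W), as.vector(num_grad(fW, W0)), tolerance = 1e-5)
})

test_that("stem convolution follows the printed shape arithmetic 9x9 -> 6x6 -> 3x3", {
  set.seed(13)
  conv1 <- lns$layer_conv2d(5, 64, 7, stride = 2, pad = 4, bias = FALSE)
  x <- array(rnorm(9 * 9 * 5 * 2), c(9, 9, 5, 2))
  c1 <- lns$nn_forward(conv1, x, FALSE)
  expect_equal(dim(c1), c(6, 6, 64, 2))
  pool <- lns$layer_maxpool(3, 2, 1)
  p1 <- lns$nn_forward(pool, c1, FALSE)
  expect_equal(dim(p1), c(3, 3, 64, 2))
})

test_that("stem output is non-negative and zero inputs stay zero at inference", {
  lay_stack <- local({
    set.seed(3)
    list(lns$layer_conv2d(5, 8, 7, stride = 2, pad = 4, bias = FALSE),
         lns$layer_bn2d(8), lns$layer_relu(), lns$layer_maxpool(3, 2, 1))
  })
  zero <- array(0, c(9, 9, 5, 1))
  # inference with zero running mean/bias: BN(0) = 0, ReLU(0) = 0
  out0 <- lns$seq_forward(lay_stack, zero, train = FALSE)
  expect_equal(max(abs(out0)), 0)
  set.seed(4)
  out <- lns$seq_forward(lay_stack, array(rnorm(9 * 9 * 5 * 2), c(9, 9, 5, 2)), train = TRUE)
  expect_true(all(out >= 0))
})

test_that("basic block with zeroed weights reduces to ReLU(x), and stays non-negative", {
  set.seed(21)
  blk <- lns$layer_basic_block(3, 3, stride = 1)  # identity shortcut
  for (l in lns$collect_layers(blk$main)) {
    for (nm in names(l$params)) l$params[[nm]][] <- 0
  }
  x <- array(rnorm(3 * 3 * 3 * 2), c(3, 3, 3, 2))
  out <- lns$nn_forward(blk, x, train = FALSE)
  expect_equal(out, x * (x > 0))

  blk2 <- lns$layer_basic_block(3, 5, stride = 2)  # projection shortcut
  out2 <- lns$nn_forward(blk2, x, train = TRUE)
  expect_true(all(out2 >= 0))
  expect_equal(dim(out2), c(2, 2, 5, 2))
})

test_that("printed-formula shortcut is available and differs from the standard one", {
  set.seed(31)
  x <- array(rnorm(3 * 3 * 4), c(3, 3, 4, 1))
  std <- lns$layer_basic_block(4, 4, stride = 1, shortcut = "standard")
  expect_null(std$shortcut)
  pr <- lns$layer_basic_block(4, 4, stride = 1, shortcut = "printed")
  expect_length(pr$shortcut, 3)  # 3x3 conv, 1x1 conv, BN
  out <- lns$nn_forward(pr, x, train = TRUE)
  expect_equal(dim(out), dim(x))
})

test_that("residual branch maps 5x9x9 to a 512-vector deterministically", {
  lay <- electrode_layout()
  set.seed(6)
  vals <- matrix(rnorm(310), 62, 5)
  map <- build_activity_map(vals, lay)
  v1 <- resnet_branch_forward(map, satfem_config(), seed = 2)
  v2 <- resnet_branch_forward(map, satfem_config(), seed = 2)
  expect_length(v1, 512)
  expect_identical(v1, v2)
  # zero input equals the forward of an explicit zero tensor
  z <- map
  z$tensor[] <- 0
  expect_identical(resnet_branch_forward(z, satfem_config(), seed = 2),
                   resnet_branch_forward(build_activity_map(matrix(0, 62, 5), lay),
                                         satfem_config(), seed = 2))
})

test_that("graph branch readout lengths follow the config and mean-pool is permutation-invariant", {
  lay <- electrode_layout()
  A <- build_adjacency(lay, "knn", 4)
  set.seed(8)
  vals <- matrix(rnorm(310), 62, 5)
  g <- build_topology_graph(vals, lay, A)
  vm <- gat_branch_forward(g, satfem_config(gat_dims = c(16, 16), gat_readout = "mean"), seed = 3)
  expect_length(vm, 16)
  vf <- gat_branch_forward(g, satfem_config(gat_dims = c(16, 16), gat_readout = "flatten"), seed = 3)
  expect_length(vf, 16 * 62)

  # permuting nodes together with the adjacency leaves the mean readout unchanged
  p <- sample(62)
  gp <- g
  gp$node_features <- vals[p, ]
  gp$adjacency <- A[p, p]
  vp <- gat_branch_forward(gp, satfem_config(gat_dims = c(16, 16)), seed = 3)
  expect_equal(vp, vm, tolerance = 1e-10)
})

test_that("fusion concatenates losslessly, activity branch first", {
  x1 <- matrix(1:6 / 10, 2, 3)
  x2 <- matrix(7:10 / 10, 2, 2)
  y <- fuse_features(x1, x2)
  expect_equal(dim(y), c(2, 5))
  expect_identical(y[, 1:3], x1)
  expect_identical(y[, 4:5], x2)
  expect_identical(fuse_features(x1, matrix(0, 2, 0)), x1)
  expect_error(fuse_features(1:3, x2), class = "eegadapt_invalid_data")
})
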