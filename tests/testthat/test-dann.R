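lns <- asNamespace("eegadapt")

test_that("gradient reversal is the identity forward and scales gradients by -lambda", {
  x <- matrix(rnorm(6), 2)
  expect_identical(grl(x, 1), x)
  expect_identical(grl(x, 0), x)
  expect_error(grl(x, -1), class = "eegadapt_invalid_parameter")

  # small network: linear -> GRL -> linear; scalar loss = sum of output.
  set.seed(44)
  l1 <- lns$layer_linear(3, 2)
  l2 <- lns$layer_linear(2, 1)
  x0 <- matrix(rnorm(3), 1)
  fwd <- function(xv) {
    sum(lns$nn_forward(l2, lns$nn_forward(l1, matrix(xv, 1), FALSE), FALSE))
  }
  fd <- num_grad(fwd, as.vector(x0))   # gradient of the lambda-free control
  for (lam in c(0, 0.5, 1)) {
    g <- lns$layer_grl(lam)
    h <- lns$nn_forward(l1, x0, FALSE)
    out <- lns$nn_forward(l2, lns$nn_forward(g, h, FALSE), FALSE)
    expect_equal(sum(out), fwd(as.vector(x0)))  # forward unchanged by lambda
    lns$nn_zero_grads(list(l1, l2))
    dx <- lns$nn_backward(l1, lns$nn_backward(g, lns$nn_backward(l2, matrix(1, 1, 1))))
    expect_equal(as.vector(dx), -lam * fd, tolerance = 1e-4)
  }
  # lambda = 0.5 gradient is exactly half the lambda = 1 gradient
  gr <- function(lam) {
    g <- lns$layer_grl(lam)
    lns$nn_forward(l2, lns$nn_forward(g, lns$nn_forward(l1, x0, FALSE), FALSE), FALSE)
    lns$nn_zero_grads(list(l1, l2))
    lns$nn_backward(l1, lns$nn_backward(g, lns$nn_backward(l2, matrix(1, 1, 1))))
  }
  expect_equal(gr(0.5), gr(1) / 2, tolerance = 1e-12)
  expect_equal(gr(0), gr(1) * 0)
})

test_that("both heads emit probability distributions; lambda never alters forward values", {
  toy <- make_toy_batch(3, K = 3, seed = 5)
  m <- dann_model(3, tiny_satfem(), seed = 7)
  out <- dann_forward(m, toy$maps, toy$nodes, train = FALSE)
  expect_equal(rowSums(out$y_probs), rep(1, 9), tolerance = 1e-6)
  expect_equal(rowSums(out$d_probs), rep(1, 9), tolerance = 1e-6)

  m$grl$lambda <- 1
  out1 <- dann_forward(m, toy$maps, toy$nodes, train = FALSE)
  expect_identical(out$y_probs, out1$y_probs)
  expect_identical(out$d_probs, out1$d_probs)

  # zero-weight heads give uniform distributions
  for (l in lns$collect_layers(m$emotion)) for (nm in names(l$params)) l$params[[nm]][] <- 0
  for (l in lns$collect_layers(m$domain)) for (nm in names(l$params)) l$params[[nm]][] <- 0
  out0 <- dann_forward(m, toy$maps, toy$nodes, train = FALSE)
  expect_equal(out0$y_probs, matrix(1 / 3, 9, 3), tolerance = 1e-12)
  expect_equal(out0$d_probs, matrix(1 / 2, 9, 2), tolerance = 1e-12)
})

test_that("loss breakdown matches hand-computed cross-entropies and the printed objective", {
  toy <- make_toy_batch(1, K = 2, seed = 9)        # 2 source samples
  tgt <- make_toy_batch(1, K = 2, seed = 10)
  tgt_unlab <- list(maps = tgt$maps, nodes = tgt$nodes)
  m <- dann_model(2, tiny_satfem(), seed = 3)

  fs <- dann_forward(m, toy$maps, toy$nodes, FALSE)
  ft <- dann_forward(m, tgt$maps, tgt$nodes, FALSE)
  le_hand <- -mean(log(fs$y_probs[cbind(1:2, toy$labels + 1)]))
  ld_hand <- -mean(log(c(fs$d_probs[, 1], ft$d_probs[, 2])))

  lb <- total_loss(m, toy, tgt_unlab, lambda = 0.7)
  expect_equal(lb$L_emotion, le_hand, tolerance = 1e-10)
  expect_equal(lb$L_domain, ld_hand, tolerance = 1e-10)
  expect_equal(lb$E_total, le_hand - 0.7 * ld_hand, tolerance = 1e-10)

  # lambda = 0 collapses the objective to the emotion loss
  expect_equal(total_loss(m, toy, tgt_unlab, lambda = 0)$E_total, le_hand, tolerance = 1e-12)

  # emotion labels on target samples are a protocol violation
  expect_error(total_loss(m, toy, tgt, lambda = 1), class = "eegadapt_protocol_violation")
  expect_error(dann_train(m, toy, tgt, dann_config(epochs = 1, batch = 4)),
               class = "eegadapt_protocol_violation")
})

test_that("confident correct predictions drive the cross-entropy losses toward zero", {
  labels <- c(0L, 1L, 1L, 0L)
  logits <- matrix(0, 4, 2)
  logits[cbind(1:4, labels + 1)] <- 30       # near-one-hot after softmax
  sm <- lns$softmax_ce(logits, labels)
  expect_lt(sm$loss, 1e-10)
  expect_equal(rowSums(sm$probs), rep(1, 4), tolerance = 1e-12)
  # and the gradient at a perfect prediction is (numerically) zero
  expect_lt(max(abs(sm$dlogits)), 1e-10)
})

test_that("lambda = 0 adversarial training equals the supervised control step for step", {
  toy <- make_toy_batch(8, K = 2, seed = 21)       # 16 source samples
  tgt <- make_toy_batch(4, K = 2, seed = 22)
  tgt_unlab <- list(maps = tgt$maps, nodes = tgt$nodes)

  m1 <- dann_model(2, tiny_satfem(), seed = 5)
  dann_train(m1, toy, tgt_unlab,
             dann_config(epochs = 3, batch = 8, lambda_schedule = "constant",
                         lambda_max = 0, seed = 5), use_dann = TRUE)
  # control: same seed, no domain objective; batch 4 = the source half-batch
  m2 <- dann_model(2, tiny_satfem(), seed = 5)
  dann_train(m2, toy, NULL, dann_config(epochs = 3, batch = 4, seed = 5),
             use_dann = FALSE)
  expect_equal(m1$history$L_emotion, m2$history$L_emotion, tolerance = 0)
  expect_equal(m1$history$source_acc, m2$history$source_acc)
  # extractor + emotion parameters identical after training
  # (batch-norm running statistics legitimately differ: the adversarial run
  # also forwards target batches; trainable parameters must be identical)
  drop_running <- function(p) lapply(p, function(l) l[setdiff(names(l), c(".rm", ".rv"))])
  p1 <- drop_running(lns$get_model_params(m1))
  p2 <- drop_running(lns$get_model_params(m2))
  n_ext <- length(lns$model_layers(m1, "extractor"))
  expect_equal(p1[seq_len(n_ext)], p2[seq_len(n_ext)], tolerance = 0)
})

test_that("training is bitwise reproducible under a fixed seed", {
  toy <- make_toy_batch(6, K = 2, seed = 31)
  tgt <- make_toy_batch(3, K = 2, seed = 32)
  tgt_unlab <- list(maps = tgt$maps, nodes = tgt$nodes)
  run <- function() {
    m <- dann_model(2, tiny_satfem(dropout = 0.3), seed = 9)
    dann_train(m, toy, tgt_unlab, dann_config(epochs = 2, batch = 8, seed = 9))
    list(h = m$history, p = dann_predict(m, tgt_unlab)$probs)
  }
  r1 <- run()
  r2 <- run()
  expect_identical(r1$h, r2$h)
  expect_identical(r1$p, r2$p)
})

test_that("a separable source with no shift is fit to high accuracy without adaptation", {
  toy <- make_toy_batch(12, K = 2, shift = 3, seed = 41)
  m <- dann_model(2, tiny_satfem(), seed = 2)
  dann_train(m, toy, NULL, dann_config(epochs = 40, batch = 8, lr = 2e-3, seed = 2),
             use_dann = FALSE)
  expect_gte(tail(m$history$source_acc, 1), 0.95)
  expect_lt(tail(m$history$L_emotion, 1), m$history$L_emotion[1])
})

test_that("alternating optimisation also trains and keeps losses finite", {
  toy <- make_toy_batch(6, K = 2, shift = 3, seed = 51)
  tgt <- make_toy_batch(3, K = 2, seed = 52)
  m <- dann_model(2, tiny_satfem(), seed = 4)
  dann_train(m, toy, list(maps = tgt$maps, nodes = tgt$nodes),
             dann_config(epochs = 10, batch = 8, mode = "alternating", seed = 4))
  expect_true(all(is.finite(m$history$L_emotion)))
  expect_true(all(is.finite(m$history$L_domain)))
  expect_gt(tail(m$history$source_acc, 1), 0.5)
})

test_that("empty domains and invalid configs are rejected", {
  toy <- make_toy_batch(2, K = 2)
  m <- dann_model(2, tiny_satfem(), seed = 1)
  empty <- list(maps = toy$maps[, , , 0, drop = FALSE],
                nodes = toy$nodes[, , 0, drop = FALSE], labels = integer())
  expect_error(dann_train(m, empty, NULL, dann_config(epochs = 1, batch = 4)),
               class = "eegadapt_invalid_data")
  expect_error(dann_config(batch = 7), class = "eegadapt_invalid_config")
  expect_error(dann_config(lr = 0), class = "eegadapt_invalid_config")
  expect_error(satfem_config(use_activity = FALSE, use_topology = FALSE),
               class = "eegadapt_invalid_config")
})
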