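#' Gradient reversal (forward identity)
#'
#' The forward map of the gradient-reversal operation is the identity; during
#' backpropagation the gradient through it is multiplied by `-lambda`. The
#' training loop realises the backward half via the internal reversal layer;
#' this function documents and exposes the forward contract.
#'
#' @param x any numeric array.
#' @param lambda non-negative reversal coefficient.
#' @return `x`, unchanged.
#' @export
#' @examples
#' identical(grl(matrix(1:4, 2), 0.5), matrix(1:4, 2))
grl <- function(x, lambda = 1) {
  if (lambda < 0) abort("lambda must be non-negative", "invalid_parameter")
  x
}

#' Training configuration
#'
#' Defaults follow the published training recipe: Adam, learning rate 5e-4,
#' batch size 64 (half source, half target per adversarial step), dropout 0.7
#' on the fused feature.
#'
#' @param epochs training epochs (default 100).
#' @param batch total batch size; must be even when the domain head is used.
#' @param lr Adam learning rate.
#' @param lambda_schedule `"ramp"` for `2 / (1 + exp(-10 p)) - 1` over
#'   training progress `p`, or `"constant"`.
#' @param lambda_max scale of the reversal coefficient (constant value, or
#'   ramp asymptote).
#' @param mode `"grl_joint"` (single pass through a gradient-reversal layer)
#'   or `"alternating"` (explicit feature/classifier then domain-classifier
#'   updates).
#' @param seed base seed; every internal stream (init, shuffling, dropout)
#'   derives from it.
#' @return a `dann_config` list.
#' @export
dann_config <- function(epochs = 100L, batch = 64L, lr = 5e-4,
                        lambda_schedule = c("ramp", "constant"), lambda_max = 1,
                        mode = c("grl_joint", "alternating"), seed = 1L) {
  if (lr <= 0) abort("learning rate must be positive", "invalid_config")
  if (batch %% 2L != 0L) abort("batch size must be even (half source, half target)", "invalid_config")
  structure(list(epochs = as.integer(epochs), batch = as.integer(batch), lr = lr,
                 lambda_schedule = match.arg(lambda_schedule),
                 lambda_max = lambda_max, mode = match.arg(mode),
                 seed = as.integer(seed)),
            class = "dann_config")
}

#' Build the full domain-adversarial model
#'
#' SATFEM feature extractor, a single fully connected K-way emotion head, and
#' a 2-layer MLP domain head behind a gradient-reversal layer.
#'
#' @param n_classes number of emotion classes K.
#' @param cfg a [satfem_config()].
#' @param adjacency electrode adjacency (defaults to 4-nn on the packaged
#'   layout).
#' @param in_size activity-map side length.
#' @param domain_hidden width of the domain head's hidden layer.
#' @param seed init seed; extractor and each head use derived streams, so the
#'   extractor's initial weights do not depend on whether a domain head is
#'   attached.
#' @return a `dann_model` environment.
#' @export
dann_model <- function(n_classes, cfg = satfem_config(), adjacency = NULL,
                       in_size = 9L, domain_hidden = 64L, seed = 1L) {
  m <- new.env(parent = emptyenv())
  m$n_classes <- as.integer(n_classes)
  m$satfem <- satfem_build(cfg, adjacency = adjacency, in_size = in_size, seed = seed)
  with_stream(rng_stream(derive_seed(seed, "init", "emotion")), {
    m$emotion <- list(layer_linear(m$satfem$fused_dim, n_classes))
  })
  with_stream(rng_stream(derive_seed(seed, "init", "domain")), {
    m$domain <- list(layer_linear(m$satfem$fused_dim, domain_hidden),
                     layer_relu(),
                     layer_linear(domain_hidden, 2L))
  })
  m$grl <- layer_grl(lambda = 0)
  m$seed <- as.integer(seed)
  class(m) <- "dann_model"
  m
}

#' @export
print.dann_model <- function(x, ...) {
  cat(sprintf("<dann_model> fused dim %d (activity %d + topology %d), %d classes\n",
              x$satfem$fused_dim, x$satfem$act_dim, x$satfem$top_dim, x$n_classes))
  invisible(x)
}

model_layers <- function(m, which = c("all", "extractor", "domain")) {
  which <- match.arg(which)
  ext <- c(satfem_layers(m$satfem), list(m$satfem$dropout), collect_layers(m$emotion))
  dom <- collect_layers(m$domain)
  switch(which, all = c(ext, dom), extractor = ext, domain = dom)
}

#' Forward pass of the full model
#'
#' @param m a [dann_model()].
#' @param maps activity-map tensor `(H, W, 5, N)`.
#' @param nodes node-feature array `(62, 5, N)`.
#' @param train logical; training mode (batch statistics, dropout).
#' @return list with `H` (fused features), `y_probs` (N x K emotion
#'   probabilities), `d_probs` (N x 2 domain probabilities).
#' @export
dann_forward <- function(m, maps, nodes, train = FALSE) {
  H <- satfem_forward(m$satfem, maps, nodes, train)
  y <- softmax_ce(seq_forward(m$emotion, H, train))$probs
  d <- softmax_ce(seq_forward(m$domain, nn_forward(m$grl, H, train), train))$probs
  list(H = H, y_probs = y, d_probs = d)
}

#' Loss breakdown at the current parameters
#'
#' Emotion loss is the mean cross-entropy over the labeled source batch;
#' domain loss is the mean cross-entropy over source and target together.
#' `E_total = L_emotion - lambda * L_domain` is the printed adversarial
#' objective; joint gradient-reversal training optimises
#' `L_emotion + L_domain` with the `-lambda` factor realised in the reversal
#' layer.
#'
#' @param m a [dann_model()].
#' @param source list with `maps`, `nodes`, `labels` (0-based).
#' @param target optional list with `maps`, `nodes`; must carry no emotion
#'   labels.
#' @param lambda reversal coefficient used in `E_total`.
#' @return list `E_total`, `L_emotion`, `L_domain`.
#' @export
total_loss <- function(m, source, target = NULL, lambda = 0) {
  if (!is.null(target) && !is.null(target$labels) && any(!is.na(target$labels))) {
    abort("target-domain samples must not carry emotion labels", "protocol_violation")
  }
  fs <- dann_forward(m, source$maps, source$nodes, train = FALSE)
  ns <- nrow(fs$y_probs)
  le <- -mean(log(pmax(fs$y_probs[cbind(seq_len(ns), source$labels + 1L)], 1e-12)))
  dp <- fs$d_probs[, 1L]
  if (!is.null(target)) {
    ft <- dann_forward(m, target$maps, target$nodes, train = FALSE)
    dp <- c(dp, ft$d_probs[, 2L])
  }
  ld <- -mean(log(pmax(dp, 1e-12)))
  list(E_total = le - lambda * ld, L_emotion = le, L_domain = ld)
}

lambda_at <- function(cfg, p) {
  if (cfg$lambda_schedule == "constant") cfg$lambda_max
  else cfg$lambda_max * (2 / (1 + exp(-10 * p)) - 1)
}

take_batch <- function(data, idx) {
  list(maps = data$maps[, , , idx, drop = FALSE],
       nodes = data$nodes[, , idx, drop = FALSE],
       labels = data$labels[idx])
}

#' Train a domain-adversarial model
#'
#' Joint mode performs one optimiser step per batch: the labeled source
#' half-batch drives the emotion loss and the source half of the domain loss,
#' the unlabeled target half-batch drives the target half of the domain loss,
#' and the gradient-reversal layer flips (and scales by `lambda`) the domain
#' gradient entering the feature extractor. Alternating mode instead performs
#' an extractor/emotion update (with reversed domain gradient, domain head
#' frozen) followed by a domain-head-only update. With `use_dann = FALSE`
#' (or no target data) training is plain supervised learning of the extractor
#' and emotion head.
#'
#' All randomness (shuffling, dropout) is drawn from streams derived from
#' `cfg$seed`; source-side streams are not advanced by target-side draws, so
#' a `lambda = 0` run is step-for-step identical to a supervised control.
#'
#' @param m a [dann_model()].
#' @param source list with `maps` `(H,W,5,N)`, `nodes` `(62,5,N)`, `labels`.
#' @param target optional unlabeled list with `maps`, `nodes` (emotion labels
#'   must be absent or NA).
#' @param cfg a [dann_config()].
#' @param use_dann logical; FALSE drops the domain objective entirely.
#' @return the trained model, invisibly carrying `$history`, a data.frame of
#'   per-epoch `L_emotion`, `L_domain`, `E_total`, `lambda`, `source_acc`,
#'   `domain_acc`.
#' @export
dann_train <- function(m, source, target = NULL, cfg = dann_config(),
                       use_dann = !is.null(target)) {
  ns_all <- length(source$labels)
  if (ns_all == 0L) abort("empty source domain", "invalid_data")
  if (use_dann) {
    if (is.null(target)) abort("use_dann = TRUE requires target data", "invalid_data")
    if (!is.null(target$labels) && any(!is.na(target$labels))) {
      abort("target-domain samples must not carry emotion labels", "protocol_violation")
    }
    nt_all <- dim(target$nodes)[3]
    if (nt_all == 0L) abort("empty target domain", "invalid_data")
  }
  str_bs <- rng_stream(derive_seed(cfg$seed, "batch", "source"))
  str_bt <- rng_stream(derive_seed(cfg$seed, "batch", "target"))
  str_ds <- rng_stream(derive_seed(cfg$seed, "dropout", "source"))
  str_dt <- rng_stream(derive_seed(cfg$seed, "dropout", "target"))

  half <- if (use_dann) cfg$batch %/% 2L else cfg$batch
  steps_per_epoch <- max(1L, ceiling(ns_all / half))
  total_steps <- cfg$epochs * steps_per_epoch
  all_layers <- model_layers(m, "all")
  ext_layers <- model_layers(m, "extractor")
  dom_layers <- model_layers(m, "domain")
  history <- vector("list", cfg$epochs)
  t_adam <- 0L
  step_global <- 0L

  for (epoch in seq_len(cfg$epochs)) {
    ord_s <- with_stream(str_bs, sample.int(ns_all))
    if (use_dann) {
      ord_t <- with_stream(str_bt, sample.int(nt_all, steps_per_epoch * (cfg$batch - half),
                                              replace = nt_all < steps_per_epoch * (cfg$batch - half)))
    }
    ep <- list(le = 0, ld = 0, n = 0L, y_ok = 0L, y_n = 0L, d_ok = 0L, d_n = 0L, lam = 0)
    for (s in seq_len(steps_per_epoch)) {
      step_global <- step_global + 1L
      lam <- if (use_dann) lambda_at(cfg, step_global / total_steps) else 0
      m$grl$lambda <- lam
      i0 <- (s - 1L) * half + 1L
      idx_s <- ord_s[i0:min(i0 + half - 1L, ns_all)]
      bs <- take_batch(source, idx_s)
      nsb <- length(idx_s)
      ntb <- if (use_dann) cfg$batch - half else 0L
      denom <- nsb + ntb

      nn_zero_grads(all_layers)
      # source half: emotion loss + source share of the domain loss
      m$satfem$dropout$stream <- str_ds
      Hs <- satfem_forward(m$satfem, bs$maps, bs$nodes, train = TRUE)
      sm <- softmax_ce(seq_forward(m$emotion, Hs, TRUE), bs$labels)
      dH <- seq_backward(m$emotion, sm$dlogits)
      if (use_dann) {
        smd <- softmax_ce(seq_forward(m$domain, nn_forward(m$grl, Hs, TRUE), TRUE),
                          rep(0L, nsb), w = rep(1 / denom, nsb))
        dH <- dH + nn_backward(m$grl, seq_backward(m$domain, smd$dlogits))
      }
      satfem_backward(m$satfem, dH)
      if (!is.finite(sm$loss)) abort("NaN/Inf emotion loss; training aborted", "numerical")

      ld_step <- 0
      if (use_dann) {
        idx_t <- ord_t[((s - 1L) * ntb + 1L):(s * ntb)]
        bt <- take_batch(target, idx_t)
        m$satfem$dropout$stream <- str_dt
        Ht <- satfem_forward(m$satfem, bt$maps, bt$nodes, train = TRUE)
        smt <- softmax_ce(seq_forward(m$domain, nn_forward(m$grl, Ht, TRUE), TRUE),
                          rep(1L, ntb), w = rep(1 / denom, ntb))
        satfem_backward(m$satfem, nn_backward(m$grl, seq_backward(m$domain, smt$dlogits)))
        ld_step <- smd$loss + smt$loss
        ep$d_ok <- ep$d_ok + sum(smd$probs[, 1L] > 0.5) + sum(smt$probs[, 2L] > 0.5)
        ep$d_n <- ep$d_n + denom
        if (!is.finite(ld_step)) abort("NaN/Inf domain loss; training aborted", "numerical")
      }

      t_adam <- t_adam + 1L
      if (cfg$mode == "grl_joint" || !use_dann) {
        adam_step(all_layers, t_adam, cfg$lr)
      } else {
        # alternating: the pass above updates extractor + emotion head only …
        adam_step(ext_layers, t_adam, cfg$lr)
        # … then a separate domain-classifier-only pass/update
        nn_zero_grads(dom_layers)
        m$satfem$dropout$stream <- str_ds
        Hs2 <- satfem_forward(m$satfem, bs$maps, bs$nodes, train = TRUE)
        sd2 <- softmax_ce(seq_forward(m$domain, Hs2, TRUE), rep(0L, nsb),
                          w = rep(1 / denom, nsb))
        seq_backward(m$domain, sd2$dlogits)
        m$satfem$dropout$stream <- str_dt
        Ht2 <- satfem_forward(m$satfem, bt$maps, bt$nodes, train = TRUE)
        st2 <- softmax_ce(seq_forward(m$domain, Ht2, TRUE), rep(1L, ntb),
                          w = rep(1 / denom, ntb))
        seq_backward(m$domain, st2$dlogits)
        adam_step(dom_layers, t_adam, cfg$lr)
      }

      ep$le <- ep$le + sm$loss
      ep$ld <- ep$ld + ld_step
      ep$lam <- ep$lam + lam
      ep$n <- ep$n + 1L
      ep$y_ok <- ep$y_ok + sum(max.col(sm$probs) - 1L == bs$labels)
      ep$y_n <- ep$y_n + nsb
    }
    history[[epoch]] <- data.frame(
      epoch = epoch,
      L_emotion = ep$le / ep$n,
      L_domain = if (use_dann) ep$ld / ep$n else NA_real_,
      E_total = ep$le / ep$n - (ep$lam / ep$n) * (if (use_dann) ep$ld / ep$n else 0),
      lambda = ep$lam / ep$n,
      source_acc = ep$y_ok / ep$y_n,
      domain_acc = if (use_dann) ep$d_ok / ep$d_n else NA_real_
    )
  }
  m$satfem$dropout$stream <- NULL
  m$history <- do.call(rbind, history)
  invisible(m)
}

#' Predict emotion classes
#'
#' Evaluation-mode forward pass (running batch-norm statistics, no dropout).
#'
#' @param m a trained [dann_model()].
#' @param data list with `maps`, `nodes`.
#' @return list with `labels` (0-based predictions) and `probs`.
#' @export
dann_predict <- function(m, data) {
  H <- satfem_forward(m$satfem, data$maps, data$nodes, train = FALSE)
  p <- softmax_ce(seq_forward(m$emotion, H, FALSE))$probs
  list(labels = max.col(p) - 1L, probs = p)
}

#' Domain-classification accuracy on held-out data
#'
#' Diagnostic for domain confusion: accuracy of the trained domain head at
#' telling source from target features (0.5 is chance, i.e. full confusion).
#'
#' @param m a trained [dann_model()].
#' @param source,target lists with `maps`, `nodes`.
#' @return scalar accuracy in `[0, 1]`.
#' @export
domain_accuracy <- function(m, source, target) {
  fs <- dann_forward(m, source$maps, source$nodes, FALSE)
  ft <- dann_forward(m, target$maps, target$nodes, FALSE)
  (sum(fs$d_probs[, 1L] > 0.5) + sum(ft$d_probs[, 2L] > 0.5)) /
    (nrow(fs$d_probs) + nrow(ft$d_probs))
}

# ---- checkpointing ----------------------------------------------------------

get_model_params <- function(m) {
  lapply(model_layers(m, "all"), function(l) {
    c(l$params, if (l$type == "bn2d") list(.rm = l$running_mean, .rv = l$running_var))
  })
}

set_model_params <- function(m, params) {
  layers <- model_layers(m, "all")
  if (length(layers) != length(params)) abort("checkpoint/model structure mismatch", "invalid_data")
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    p <- params[[i]]
    if (l$type == "bn2d") {
      l$running_mean <- p$.rm
      l$running_var <- p$.rv
      p$.rm <- NULL
      p$.rv <- NULL
    }
    l$params <- p
  }
  invisible(m)
}
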