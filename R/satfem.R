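#' SATFEM configuration
#'
#' Declarative configuration of the dual-branch spatial feature extractor:
#' a graph-attention branch over the electrode topology graph and a modified
#' residual CNN branch over the scalp activity map, fused by concatenation
#' (activity branch first).
#'
#' @param gat_dims per-layer output widths of the stacked graph attention
#'   layers (input width is the 5 bands); default `c(32, 32)`.
#' @param gat_readout `"mean"` (node mean pool) or `"flatten"`.
#' @param gat_slope LeakyReLU negative slope inside the attention logits.
#' @param gat_sigma output nonlinearity of each attention layer.
#' @param conv1_out,widths,blocks stem width, the four stage widths and
#'   blocks per stage of the residual branch. Defaults follow an 8-block
#'   BasicBlock network (64, 128, 256, 512) with a 7x7 stride-2 pad-4
#'   bias-free stem and 3x3 stride-2 pad-1 max pooling.
#' @param shortcut `"standard"` (identity when shapes match, 1x1 projection
#'   otherwise) or `"printed"` (3x3 then 1x1 conv + BN on every shortcut).
#' @param dropout dropout rate applied to the fused feature (default 0.7).
#' @param use_activity,use_topology branch switches (at least one TRUE);
#'   disabling a branch yields the single-branch ablation extractors.
#' @return a `satfem_config` list.
#' @export
satfem_config <- function(gat_dims = c(32, 32), gat_readout = c("mean", "flatten"),
                          gat_slope = 0.2, gat_sigma = "elu",
                          conv1_out = 64, widths = c(64, 128, 256, 512),
                          blocks = c(2, 2, 2, 2),
                          shortcut = c("standard", "printed"),
                          dropout = 0.7,
                          use_activity = TRUE, use_topology = TRUE) {
  if (!use_activity && !use_topology) abort("at least one branch must be enabled", "invalid_config")
  if (length(widths) != length(blocks)) abort("widths/blocks length mismatch", "invalid_config")
  structure(list(
    gat_dims = gat_dims, gat_readout = match.arg(gat_readout),
    gat_slope = gat_slope, gat_sigma = gat_sigma,
    conv1_out = conv1_out, widths = widths, blocks = blocks,
    shortcut = match.arg(shortcut), dropout = dropout,
    use_activity = use_activity, use_topology = use_topology
  ), class = "satfem_config")
}

# Spatial size tracking so stride-2 stage entries degrade to stride 1 once
# the map is too small to halve (a 9x9 input is 3x3 after the stem).
conv_out_size <- function(n, k, s, p) (n + 2L * p - k) %/% s + 1L

build_resnet_branch <- function(cfg, in_ch = 5L, in_size = 9L) {
  layers <- list(
    layer_conv2d(in_ch, cfg$conv1_out, 7L, stride = 2L, pad = 4L, bias = FALSE),
    layer_bn2d(cfg$conv1_out),
    layer_relu(),
    layer_maxpool(3L, 2L, 1L)
  )
  size <- conv_out_size(conv_out_size(in_size, 7L, 2L, 4L), 3L, 2L, 1L)
  prev <- cfg$conv1_out
  for (s in seq_along(cfg$widths)) {
    for (b in seq_len(cfg$blocks[s])) {
      stride <- if (s > 1L && b == 1L && size > 3L) 2L else 1L
      layers[[length(layers) + 1L]] <-
        layer_basic_block(prev, cfg$widths[s], stride = stride, shortcut = cfg$shortcut)
      size <- conv_out_size(size, 3L, stride, 1L)
      prev <- cfg$widths[s]
    }
  }
  layers[[length(layers) + 1L]] <- layer_gap()
  list(layers = layers, out_dim = prev)
}

build_gat_branch <- function(cfg, mask, in_dim = 5L, n_nodes = 62L) {
  layers <- list()
  prev <- in_dim
  for (d in cfg$gat_dims) {
    layers[[length(layers) + 1L]] <-
      layer_gal(prev, d, mask, slope = cfg$gat_slope,
                sigma = if (cfg$gat_sigma == "identity") "identity" else "elu")
    prev <- d
  }
  layers[[length(layers) + 1L]] <- layer_node_readout(cfg$gat_readout)
  out_dim <- if (cfg$gat_readout == "mean") prev else prev * n_nodes
  list(layers = layers, out_dim = out_dim)
}

#' Build a SATFEM feature extractor
#'
#' Instantiates the dual-branch extractor for a given adjacency. Parameter
#' initialisation is drawn from seeds derived per component, so the activity
#' and topology branches are reproducible independently of each other.
#'
#' @param cfg a [satfem_config()].
#' @param adjacency electrode adjacency from [build_adjacency()].
#' @param in_size spatial side length of the activity map (default 9).
#' @param seed integer seed for parameter initialisation.
#' @return a `satfem` model environment with fields `resnet`, `gat`,
#'   `dropout`, `act_dim`, `top_dim`, `fused_dim`.
#' @export
satfem_build <- function(cfg = satfem_config(), adjacency = NULL,
                         in_size = 9L, seed = 1L) {
  m <- new.env(parent = emptyenv())
  m$cfg <- cfg
  if (cfg$use_topology && is.null(adjacency)) {
    adjacency <- build_adjacency(electrode_layout(), "knn", 4)
  }
  m$act_dim <- 0L
  m$top_dim <- 0L
  if (cfg$use_activity) {
    with_stream(rng_stream(derive_seed(seed, "init", "resnet")), {
      br <- build_resnet_branch(cfg, in_size = in_size)
      m$resnet <- br$layers
      m$act_dim <- br$out_dim
    })
  }
  if (cfg$use_topology) {
    with_stream(rng_stream(derive_seed(seed, "init", "gat")), {
      br <- build_gat_branch(cfg, mask = adjacency > 0, n_nodes = nrow(adjacency))
      m$gat <- br$layers
      m$top_dim <- br$out_dim
    })
  }
  m$fused_dim <- m$act_dim + m$top_dim
  m$dropout <- layer_dropout(cfg$dropout)
  class(m) <- "satfem"
  m
}

#' Fuse branch outputs
#'
#' Concatenation fusion, activity branch first; either input may be an
#' empty (zero-column) matrix for single-branch ablations.
#'
#' @param x1 activity-branch feature matrix (N x d1).
#' @param x2 topology-branch feature matrix (N x d2).
#' @return N x (d1 + d2) matrix.
#' @export
fuse_features <- function(x1, x2) {
  if (is.null(dim(x1)) || is.null(dim(x2))) abort("fuse expects matrices", "invalid_data")
  cbind(x1, x2)
}

# Forward the extractor: maps (H,W,5,N), nodes (62,5,N) -> fused N x D.
satfem_forward <- function(m, maps, nodes, train = FALSE) {
  n <- if (m$cfg$use_activity) dim(maps)[4] else dim(nodes)[3]
  x1 <- if (m$cfg$use_activity) seq_forward(m$resnet, maps, train) else matrix(0, n, 0)
  x2 <- if (m$cfg$use_topology) seq_forward(m$gat, nodes, train) else matrix(0, n, 0)
  h <- fuse_features(x1, x2)
  nn_forward(m$dropout, h, train)
}

# Backward through dropout, split at the fusion boundary, then each branch.
satfem_backward <- function(m, dH) {
  dh <- nn_backward(m$dropout, dH)
  if (m$cfg$use_activity) {
    seq_backward(m$resnet, dh[, seq_len(m$act_dim), drop = FALSE])
  }
  if (m$cfg$use_topology) {
    seq_backward(m$gat, dh[, m$act_dim + seq_len(m$top_dim), drop = FALSE])
  }
  invisible(NULL)
}

satfem_layers <- function(m) {
  c(if (!is.null(m$resnet)) collect_layers(m$resnet) else list(),
    if (!is.null(m$gat)) collect_layers(m$gat) else list())
}

#' Run the graph-attention branch on one topology graph
#'
#' Convenience single-sample wrapper used for inspection and testing of the
#' attention stack outside a full model.
#'
#' @param graph a `topology_graph` from [build_topology_graph()].
#' @param cfg a [satfem_config()].
#' @param seed init seed.
#' @return the readout feature vector.
#' @export
gat_branch_forward <- function(graph, cfg = satfem_config(), seed = 1L) {
  br <- with_stream(rng_stream(derive_seed(seed, "init", "gat")),
                    build_gat_branch(cfg, mask = graph$adjacency > 0,
                                     n_nodes = nrow(graph$adjacency)))
  x <- array(graph$node_features, c(dim(graph$node_features), 1L))
  drop(seq_forward(br$layers, x, train = FALSE))
}

#' Run the residual activity branch on one activity map
#'
#' @param map an `activity_map` from [build_activity_map()].
#' @param cfg a [satfem_config()].
#' @param seed init seed.
#' @return the pooled feature vector (length = last stage width).
#' @export
resnet_branch_forward <- function(map, cfg = satfem_config(), seed = 1L) {
  d <- dim(map$tensor)
  br <- with_stream(rng_stream(derive_seed(seed, "init", "resnet")),
                    build_resnet_branch(cfg, in_ch = d[3], in_size = d[1]))
  x <- array(map$tensor, c(d, 1L))
  drop(seq_forward(br$layers, x, train = FALSE))
}
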