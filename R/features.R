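#' Zero-phase Butterworth band-pass filter
#'
#' Filters every channel of a recording to `[low_hz, high_hz]` with an
#' order-`order` Butterworth filter applied forward and backward
#' (`signal::filtfilt`), so the output has no group delay.
#'
#' @param recording a [raw_recording()].
#' @param low_hz,high_hz band edges; must satisfy `0 < low < high < fs/2`.
#' @param order filter order (default 5).
#' @return a [raw_recording()] of identical shape containing only the band.
#' @export
bandpass_filter <- function(recording, low_hz, high_hz, order = 5) {
  fs <- recording$fs
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    abort(sprintf("band [%g, %g] Hz invalid for fs = %g Hz (need 0 < low < high < fs/2)",
                  low_hz, high_hz, fs), "invalid_band")
  }
  # filtfilt's edge padding needs a few filter lengths of signal
  warmup <- 6L * (2L * order + 1L)
  if (ncol(recording$samples) <= warmup) {
    abort(sprintf("recording too short to filter (%d samples <= %d warm-up)",
                  ncol(recording$samples), warmup), "too_short")
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  out <- recording
  out$samples <- t(apply(recording$samples, 1L, function(ch) signal::filtfilt(bf, ch)))
  out
}

#' Segment a recording into fixed non-overlapping windows
#'
#' @param recording a [raw_recording()].
#' @param window_seconds window length (default 4 s).
#' @return a list of [raw_recording()] windows of exactly
#'   `window_seconds * fs` samples, `window_index` assigned in time order
#'   (1-based); any trailing remainder is dropped.
#' @export
segment_windows <- function(recording, window_seconds = 4) {
  wlen <- as.integer(round(window_seconds * recording$fs))
  n <- ncol(recording$samples)
  k <- n %/% wlen
  if (k < 1L) {
    abort(sprintf("recording (%d samples) shorter than one %g-s window (%d samples)",
                  n, window_seconds, wlen), "too_short")
  }
  lapply(seq_len(k), function(i) {
    w <- recording
    w$samples <- recording$samples[, ((i - 1L) * wlen + 1L):(i * wlen), drop = FALSE]
    w$window_index <- i
    w
  })
}

#' Differential entropy of a band-limited signal
#'
#' Gaussian closed form \eqn{\tfrac12 \ln(2\pi e \hat\sigma^2)} in nats,
#' using the sample variance of the window. This is the standard per-band
#' EEG feature for band-filtered short windows, whose samples are well
#' approximated as Gaussian.
#'
#' @param x numeric vector (one channel, one window, one band).
#' @return differential entropy in nats.
#' @export
#' @examples
#' differential_entropy(rnorm(800))  # about 0.5 * log(2 * pi * exp(1))
differential_entropy <- function(x) {
  if (length(x) < 2L) abort("need at least 2 samples", "invalid_data")
  v <- stats::var(x)
  if (!is.finite(v) || v <= 0) abort("zero-variance (degenerate) signal", "degenerate_signal")
  0.5 * log(2 * pi * exp(1) * v)
}

#' Per-window differential-entropy feature matrices
#'
#' The shared precursor of both model inputs: for every non-overlapping
#' window, a 62 x 5 matrix whose entry (e, b) is the differential entropy of
#' electrode e filtered to band b. Channels are reordered to layout order;
#' each band is filtered once over the full recording before windowing.
#'
#' @param recording a [raw_recording()] covering all layout channels
#'   (matched case-insensitively).
#' @param scheme a [band_scheme()].
#' @param layout an [electrode_layout()].
#' @param window_seconds window length in seconds (default 4).
#' @param order Butterworth order passed to [bandpass_filter()].
#' @return a list of `de_features` objects, one per window, each with fields
#'   `values` (62 x 5 matrix, dimnames electrode x band), `window_index`,
#'   `window_seconds`, `subject_id`, `trial_id`, `label`.
#' @export
compute_de_features <- function(recording, scheme = band_scheme(),
                                layout = electrode_layout(),
                                window_seconds = 4, order = 5) {
  idx <- match(toupper(layout$names), toupper(recording$channel_names))
  if (anyNA(idx)) {
    abort(paste0("recording is missing layout channels: ",
                 paste(layout$names[is.na(idx)], collapse = ", ")), "missing_channel")
  }
  rec <- recording
  rec$samples <- recording$samples[idx, , drop = FALSE]
  rec$channel_names <- layout$names

  wlen <- as.integer(round(window_seconds * rec$fs))
  nwin <- ncol(rec$samples) %/% wlen
  if (nwin < 1L) {
    abort("recording shorter than one window", "too_short")
  }
  bands <- scheme$bands
  ne <- length(layout$names)
  # de[e, b, w]
  de <- array(NA_real_, c(ne, nrow(bands), nwin))
  for (b in seq_len(nrow(bands))) {
    filt <- bandpass_filter(rec, bands$low_hz[b], bands$high_hz[b], order = order)
    for (w in seq_len(nwin)) {
      seg <- filt$samples[, ((w - 1L) * wlen + 1L):(w * wlen), drop = FALSE]
      v <- row_var(seg)
      if (any(v <= 0)) abort("zero-variance window", "degenerate_signal")
      de[, b, w] <- 0.5 * log(2 * pi * exp(1) * v)
    }
  }
  lapply(seq_len(nwin), function(w) {
    structure(list(
      values = matrix(de[, , w], ne, nrow(bands),
                      dimnames = list(layout$names, bands$name)),
      window_index = w, window_seconds = window_seconds,
      subject_id = rec$subject_id, trial_id = rec$trial_id, label = rec$label
    ), class = "de_features")
  })
}

#' Spatial activity map
#'
#' Places each electrode's five band entropies at its scalp grid cell,
#' yielding the H x W x 5 tensor consumed by the convolutional branch. Cells
#' with no electrode are exactly zero, so the tensor total equals the feature
#' matrix total.
#'
#' @param features a `de_features` object (or bare 62 x 5 matrix).
#' @param layout an [electrode_layout()].
#' @return an `activity_map`: list with `tensor` (H x W x 5) and `layout`.
#' @export
build_activity_map <- function(features, layout = electrode_layout()) {
  vals <- if (is.matrix(features)) features else features$values
  if (nrow(vals) != length(layout$names)) abort("feature/layout size mismatch", "invalid_data")
  H <- layout$H; W <- layout$W; B <- ncol(vals)
  cell <- layout$grid[, "row"] * W + layout$grid[, "col"]
  if (anyDuplicated(cell)) abort("two electrodes share a grid cell", "layout_collision")
  tensor <- array(0, c(H, W, B))
  for (b in seq_len(B)) {
    plane <- matrix(0, H, W)
    plane[cbind(layout$grid[, "row"] + 1L, layout$grid[, "col"] + 1L)] <- vals[, b]
    tensor[, , b] <- plane
  }
  structure(list(tensor = tensor, layout = layout), class = "activity_map")
}

#' Recover the electrode x band matrix from an activity map
#'
#' Inverse of [build_activity_map()] through the layout's injective
#' electrode-to-cell placement.
#'
#' @param map an `activity_map`.
#' @return a 62 x 5 matrix.
#' @export
unmap_activity <- function(map) {
  layout <- map$layout
  B <- dim(map$tensor)[3]
  out <- matrix(NA_real_, length(layout$names), B,
                dimnames = list(layout$names, NULL))
  for (b in seq_len(B)) {
    out[, b] <- map$tensor[, , b][cbind(layout$grid[, "row"] + 1L,
                                        layout$grid[, "col"] + 1L)]
  }
  out
}

#' Spatial topology graph
#'
#' Bundles the 62 x 5 band-entropy node features with an electrode adjacency
#' into the graph consumed by the attention branch.
#'
#' @param features a `de_features` object (or bare 62 x 5 matrix) in layout
#'   order.
#' @param layout an [electrode_layout()].
#' @param adjacency a 62 x 62 symmetric matrix with unit diagonal, e.g. from
#'   [build_adjacency()].
#' @return a `topology_graph`: list with `node_features`, `adjacency`,
#'   `layout`.
#' @export
build_topology_graph <- function(features, layout = electrode_layout(),
                                 adjacency = build_adjacency(layout, "knn", 4)) {
  vals <- if (is.matrix(features)) features else features$values
  n <- length(layout$names)
  if (nrow(vals) != n) abort("feature/layout size mismatch", "invalid_data")
  if (!all(dim(adjacency) == c(n, n))) abort("adjacency shape mismatch", "invalid_data")
  if (!isTRUE(all.equal(adjacency, t(adjacency)))) abort("adjacency must be symmetric", "invalid_data")
  if (any(diag(adjacency) != 1)) abort("adjacency needs unit diagonal (self-loops)", "invalid_data")
  structure(list(node_features = vals, adjacency = adjacency, layout = layout),
            class = "topology_graph")
}
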