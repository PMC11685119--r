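#' Frequency band scheme
#'
#' The five conventional EEG rhythms used throughout the package. Differential
#' entropy is computed per band, and every downstream representation (activity
#' map, topology graph) stacks its planes in this order.
#'
#' @param bands a data.frame with columns `name`, `low_hz`, `high_hz`.
#'   Defaults to delta 1-4, theta 4-8, alpha 8-14, beta 14-31, gamma 31-50 Hz.
#' @return an object of class `band_scheme`.
#' @export
#' @examples
#' band_scheme()
band_scheme <- function(bands = NULL) {
  if (is.null(bands)) {
    bands <- data.frame(
      name    = c("delta", "theta", "alpha", "beta", "gamma"),
      low_hz  = c(1, 4, 8, 14, 31),
      high_hz = c(4, 8, 14, 31, 50),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(bands) != 5L) abort("a band scheme must define exactly 5 bands", "invalid_band")
  if (any(bands$low_hz >= bands$high_hz)) abort("each band needs low_hz < high_hz", "invalid_band")
  if (any(diff(bands$low_hz) <= 0) || any(bands$low_hz[-1] < bands$high_hz[-5])) {
    abort("bands must be ordered and non-overlapping", "invalid_band")
  }
  structure(list(bands = bands), class = "band_scheme")
}

#' @export
print.band_scheme <- function(x, ...) {
  cat("<band_scheme> ", paste0(x$bands$name, " ", x$bands$low_hz, "-", x$bands$high_hz, "Hz",
                               collapse = ", "), "\n")
  invisible(x)
}

#' 62-channel scalp electrode layout
#'
#' Loads the packaged 10-20 montage used by 62-channel ESI caps (FP1 ... CB2):
#' channel names, an injective placement on a 9x9 grid (row 0 is the frontal
#' edge), and unit-scale planar scalp coordinates used for neighbourhood
#' graphs.
#'
#' @param file optional path to a layout table (TSV with columns
#'   `name,row,col,x,y`); defaults to the packaged asset.
#' @return an object of class `electrode_layout` with fields `names`,
#'   `grid` (62 x 2 matrix of 0-based row/col), `xy` (62 x 2), `H`, `W`.
#' @export
#' @examples
#' lay <- electrode_layout()
#' head(lay$names)
electrode_layout <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "layout_10_20_62.tsv", package = "eegadapt", mustWork = TRUE)
  }
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "row", "col", "x", "y") %in% names(tab)))
  if (anyDuplicated(tab$name)) abort("duplicate electrode names in layout", "invalid_layout")
  H <- max(tab$row) + 1L
  W <- max(tab$col) + 1L
  cell <- tab$row * W + tab$col
  if (anyDuplicated(cell)) abort("two electrodes share a grid cell", "layout_collision")
  if (any(tab$row < 0) || any(tab$col < 0)) abort("negative grid coordinates", "invalid_layout")
  structure(list(
    names = tab$name,
    grid  = cbind(row = tab$row, col = tab$col),
    xy    = cbind(x = tab$x, y = tab$y),
    H = H, W = W
  ), class = "electrode_layout")
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat(sprintf("<electrode_layout> %d electrodes on a %dx%d grid (%s ... %s)\n",
              length(x$names), x$H, x$W, x$names[1], x$names[length(x$names)]))
  invisible(x)
}

#' Electrode adjacency matrix
#'
#' Builds the (symmetric, self-looped) adjacency of the electrode graph.
#' `knn` connects each electrode to its `param` nearest neighbours in planar
#' scalp coordinates and symmetrises by OR; `radius` connects all pairs within
#' Euclidean distance `param`; `full` is the complete graph.
#'
#' @param layout an [electrode_layout()].
#' @param rule one of `"knn"`, `"radius"`, `"full"`.
#' @param param neighbour count `k` (default 4) or radius, by rule.
#' @return a 62 x 62 binary matrix with unit diagonal, dimnames set to
#'   electrode names.
#' @export
#' @examples
#' A <- build_adjacency(electrode_layout(), "knn", 4)
#' isSymmetric(A)
build_adjacency <- function(layout, rule = c("knn", "radius", "full"), param = 4) {
  rule <- match.arg(rule)
  n <- length(layout$names)
  A <- matrix(0, n, n, dimnames = list(layout$names, layout$names))
  if (rule == "full") {
    A[] <- 1
    return(A)
  }
  if (param < 0 || (rule == "radius" && param <= 0)) {
    abort("adjacency parameter must be positive", "invalid_parameter")
  }
  d <- as.matrix(stats::dist(layout$xy))
  if (rule == "knn") {
    k <- as.integer(param)
    if (k > 0) {
      for (i in seq_len(n)) {
        ord <- order(d[i, ])          # self first (distance 0), ties by index
        nb <- ord[ord != i][seq_len(k)]
        A[i, nb] <- 1
      }
      A <- pmax(A, t(A))              # symmetrise by OR
    }
  } else {
    A[d <= param] <- 1
  }
  diag(A) <- 1
  A
}
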