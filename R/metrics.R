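#' Classification metrics report
#'
#' Accuracy, macro-averaged F1 and Cohen's kappa from paired label vectors,
#' together with the K x K confusion matrix (rows = truth, columns =
#' prediction). Macro F1 is the unweighted mean of per-class F1; classes
#' absent from both truth and prediction are excluded from the mean. Kappa is
#' `(p_o - p_e) / (1 - p_e)` with the expected agreement `p_e` computed from
#' the marginals.
#'
#' @param y_true,y_pred integer labels in `0..K-1`.
#' @param K number of classes.
#' @return a `metrics_report` list: `confusion`, `accuracy`, `macro_f1`,
#'   `kappa`, `n`.
#' @export
#' @examples
#' compute_metrics(c(0, 0, 1, 1), c(0, 0, 1, 0), K = 2)
compute_metrics <- function(y_true, y_pred, K) {
  if (length(y_true) == 0L) abort("empty input", "invalid_data")
  if (length(y_true) != length(y_pred)) abort("length mismatch", "invalid_data")
  if (any(y_true < 0 | y_true >= K | y_pred < 0 | y_pred >= K)) {
    abort("labels outside 0..K-1", "invalid_data")
  }
  lev <- 0:(K - 1L)
  cm <- table(factor(y_true, levels = lev), factor(y_pred, levels = lev))
  cm <- matrix(as.numeric(cm), K, K, dimnames = list(true = lev, pred = lev))
  metrics_from_confusion(cm)
}

#' @rdname compute_metrics
#' @param confusion a K x K count matrix (rows true, columns predicted).
#' @export
metrics_from_confusion <- function(confusion) {
  n <- sum(confusion)
  if (n == 0) abort("empty confusion matrix", "invalid_data")
  acc <- sum(diag(confusion)) / n
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  present <- (tp + fp + fn) > 0
  f1 <- ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), 0)
  macro_f1 <- mean(f1[present])
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  kappa <- if (pe >= 1) 0 else (acc - pe) / (1 - pe)
  structure(list(confusion = confusion, accuracy = acc, macro_f1 = macro_f1,
                 kappa = kappa, n = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d ACC=%.3f macroF1=%.3f kappa=%.3f\n",
              as.integer(x$n), x$accuracy, x$macro_f1, x$kappa))
  invisible(x)
}
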