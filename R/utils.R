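#' @keywords internal
"_PACKAGE"

# Condition helper: every package error carries class "eegadapt_error" plus a
# machine-readable subclass so callers (and the CLI) can distinguish config,
# data and numerical failures.
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("eegadapt_", class), "eegadapt_error", "error")))
}

#' Derive a child seed from a base seed and a character key
#'
#' Deterministic 31-bit hash used to give every stochastic component
#' (parameter init, batch shuffling, dropout, data generation) its own
#' reproducible stream derived from one user-facing seed.
#'
#' @param seed integer base seed.
#' @param ... character or numeric key components.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# A named RNG stream: an environment holding a saved .Random.seed state.
rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  set.seed(seed)
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  e
}

# Evaluate expr with the stream's RNG state, then save the advanced state back
# and restore the caller's global RNG untouched.
with_stream <- function(stream, expr) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

# Sample variance by moments; `stats::var` per row is slow for wide matrices.
row_var <- function(m) {
  n <- ncol(m)
  (rowMeans(m * m) - rowMeans(m)^2) * n / (n - 1)
}
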