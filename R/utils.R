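# internal helpers shared across modules

abort_aqua <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("aquastore_error_", class), "aquastore_error"), ...)
}

#' Derive reproducible sub-seeds from one master seed
#'
#' All randomness in the package flows from a single integer seed; stages that
#' need independent streams draw sub-seeds through this splitter so any one
#' stage can be replayed in isolation.
#'
#' @param seed Integer master seed.
#' @param n Number of sub-seeds to derive.
#' @return Integer vector of length `n`, each below `.Machine$integer.max`.
#' @export
split_seed <- function(seed, n) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_aqua("`seed` must be a single integer.", "parameter")
  }
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# evaluate `code` under `seed`, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

sample_sd <- function(x) stats::sd(x)

# row-wise sample sd of a matrix without apply() overhead
row_sds <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  sqrt(rowSums((x - m)^2) / (n - 1))
}

col_sds <- function(x) {
  n <- nrow(x)
  m <- colMeans(x)
  sqrt(colSums(sweep(x, 2L, m)^2) / (n - 1))
}
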