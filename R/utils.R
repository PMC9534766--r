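# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible sub-stream seed from a top-level seed
#'
#' All randomness in the study harnesses flows from one top-level seed through
#' named sub-streams (genotypes, phenotypes, probes, ...) so that replicates
#' are individually reproducible. Seeds stay below 2^31 - 1.
#'
#' @param seed integer top-level seed.
#' @param stream character sub-stream name.
#' @param index integer replicate or unit index (default 0).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  m <- 2147483647
  s <- (as.double(seed) %% m)
  s <- (s * 48271 + h * 9349 + as.double(index) * 2654435761) %% m
  as.integer(max(1, s))
}

# row-wise maximum of a (non-negative) matrix; sparse-aware O(nnz) path
row_max <- function(m) {
  if (inherits(m, "Matrix")) {
    ts <- methods::as(m, "TsparseMatrix")
    out <- numeric(nrow(m))
    if (length(ts@x)) {
      o <- order(ts@i, -ts@x)
      first <- !duplicated(ts@i[o])
      out[ts@i[o][first] + 1L] <- pmax(ts@x[o][first], 0)
    }
    return(out)
  }
  if (ncol(m) == 1L) return(as.numeric(m[, 1L]))
  out <- m[, 1L]
  for (j in 2L:ncol(m)) out <- pmax(out, m[, j])
  as.numeric(out)
}

as_dense <- function(m) {
  if (inherits(m, "Matrix")) as.matrix(m) else m
}

is_binary_vec <- function(y) all(y %in% c(0, 1))

# clamp a p-value into (0, 1]
clamp_p <- function(p, lo = .Machine$double.xmin) {
  pmin(pmax(p, lo), 1)
}

# scale rows / columns of a matrix, preserving sparsity for dgCMatrix
row_scale <- function(M, v) {
  if (inherits(M, "dgCMatrix")) {
    M@x <- M@x * v[M@i + 1L]
    M
  } else if (inherits(M, "Matrix")) {
    Matrix::Diagonal(nrow(M), v) %*% M
  } else M * v
}

col_scale <- function(M, v) {
  if (inherits(M, "dgCMatrix")) {
    M@x <- M@x * rep.int(v, diff(M@p))
    M
  } else if (inherits(M, "Matrix")) {
    M %*% Matrix::Diagonal(ncol(M), v)
  } else M * rep(v, each = nrow(M))
}
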