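#' @importFrom stats cor cov pnorm qnorm rnorm rexp runif rgamma rbinom
#'   nlminb optim median setNames
#' @importFrom utils head tail modifyList
NULL

# ---- half-vectorization ------------------------------------------------
# Frozen convention: vech() walks the LOWER triangle of a K x K symmetric
# matrix in column-major order: (1,1), (2,1), ..., (K,1), (2,2), (3,2), ...
# All V matrices, DWLS moment vectors and Jacobians use this order.

#' Half-vectorize a symmetric matrix (lower triangle, column-major)
#'
#' @param m symmetric numeric matrix
#' @return numeric vector of length K(K+1)/2
#' @export
vech <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  m[lower.tri(m, diag = TRUE)]
}

#' Indices of the half-vectorized elements
#'
#' Returns a two-column integer matrix (row, col) such that
#' \code{vech(m)[k] == m[vech_index(K)[k, 1], vech_index(K)[k, 2]]}.
#'
#' @param k matrix dimension
#' @export
vech_index <- function(k) {
  idx <- which(lower.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
}

#' Rebuild a symmetric matrix from its half-vectorization
#'
#' @param v vector as produced by [vech()]
#' @param k matrix dimension
#' @export
unvech <- function(v, k) {
  stopifnot(length(v) == k * (k + 1) / 2)
  m <- matrix(0, k, k)
  m[lower.tri(m, diag = TRUE)] <- v
  m <- m + t(m)
  diag(m) <- diag(m) / 2
  m
}

# ---- misc numeric helpers ---------------------------------------------

is_symmetric_tol <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    max(abs(m - t(m))) <= tol * max(1, max(abs(m)))
}

#' Nearest positive semi-definite matrix by eigenvalue truncation
#'
#' Eigenvalues below a small floor (relative to the largest eigenvalue) are
#' raised to the floor and the matrix reassembled. Symmetry is preserved;
#' already-PSD inputs are returned unchanged. The maximum element change is
#' attached as attribute \code{"max_change"}.
#'
#' @param m symmetric numeric matrix
#' @param floor_frac floor as a fraction of the largest eigenvalue
#'   (default 1e-8)
#' @return matrix of the same dimension, positive semi-definite
#' @export
smooth_to_psd <- function(m, floor_frac = 1e-8) {
  stopifnot(is_symmetric_tol(m, 1e-6))
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  floor_val <- floor_frac * max(e$values, 0)
  if (all(e$values >= floor_val)) {
    attr(m, "max_change") <- 0
    return(m)
  }
  vals <- pmax(e$values, floor_val)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(m)
  attr(out, "max_change") <- max(abs(out - m))
  out
}

# contiguous, maximally equal-sized jackknife blocks
block_ids <- function(n, n_blocks) {
  stopifnot(n_blocks >= 2, n_blocks <= n)
  ceiling(seq_len(n) * n_blocks / n)
}

# delete-m jackknife SE from a G-vector of leave-one-block-out estimates
jackknife_se <- function(delete_values) {
  g <- length(delete_values)
  sqrt((g - 1) / g * sum((delete_values - mean(delete_values))^2))
}

# hash a config-like list for provenance (md5 of canonical JSON)
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, na = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
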