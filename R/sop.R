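## Second-order pooling: covariance of stage-4 features, trace
## pre-normalization, Newton-Schulz iterative matrix square root,
## post-compensation, and upper-triangular feature extraction.
##
## The plain-matrix functions below are the reference implementations and
## the public API; graph_second_order_pool() composes the same chain from
## differentiable ops for use inside the network head.

#' Covariance of a feature matrix
#'
#' Computes \eqn{\Sigma = X \bar{I} X^\top} with
#' \eqn{\bar{I} = \frac{1}{S}(I - \frac{1}{S}\mathbf{1})}, i.e. the
#' 1/S-normalized mean-centered scatter matrix of the S spatial positions.
#'
#' @param X Numeric matrix, channels x spatial positions (C x S).
#' @return A symmetric positive semi-definite C x C covariance matrix.
#' @examples
#' compute_covariance(rbind(c(1, 3), c(2, 2)))
#' @export
compute_covariance <- function(X) {
  X <- as.matrix(X)
  S <- ncol(X)
  stopifnot(S >= 1)
  Xc <- X - rowMeans(X)
  Sigma <- tcrossprod(Xc) / S
  (Sigma + t(Sigma)) / 2
}

#' Trace pre-normalization of a covariance matrix
#'
#' Divides the covariance by its trace so the Newton-Schulz iteration
#' converges (it requires \eqn{\|I - A\| < 1}, guaranteed when
#' \eqn{tr(A) = 1} for PSD \eqn{A}).  A small guard keeps all-constant
#' feature maps (zero covariance) finite; in that case the normalized
#' matrix is zero and a warning is issued.
#'
#' @param Sigma Symmetric PSD matrix.
#' @param eps_guard Guard added to the trace denominator (default 1e-12).
#' @return List with `A` (trace-normalized matrix) and `trace_value`.
#' @export
pre_normalize <- function(Sigma, eps_guard = 1e-12) {
  tr <- sum(diag(Sigma))
  if (tr <= 0) {
    warning("covariance has zero trace (constant features); ",
            "second-order features will be zero")
  }
  list(A = Sigma / (tr + eps_guard), trace_value = tr)
}

#' Newton-Schulz iteration for the matrix square root
#'
#' Starting from \eqn{Y_0 = A}, \eqn{Z_0 = I}, iterates
#' \deqn{Y_l = \tfrac12 Y_{l-1}(3I - Z_{l-1}Y_{l-1}), \quad
#'       Z_l = \tfrac12 (3I - Z_{l-1}Y_{l-1}) Z_{l-1}}
#' so that \eqn{Y_L \to A^{1/2}} for trace-normalized \eqn{A}.
#' `L = 0` returns `A` unchanged (the no-normalization baseline).
#'
#' @param A Trace-normalized symmetric PSD matrix (tr(A) <= 1).
#' @param L Number of iterations (non-negative integer; default 8).
#' @return Approximation to the matrix square root of `A`.
#' @export
newton_schulz_sqrt <- function(A, L = 8L) {
  if (L < 0) stop("iteration count L must be non-negative")
  A <- as.matrix(A)
  if (L == 0) return(A)
  C <- nrow(A)
  Y <- A
  Z <- diag(C)
  I3 <- 3 * diag(C)
  for (l in seq_len(L)) {
    B <- I3 - Z %*% Y
    Y <- 0.5 * Y %*% B
    Z <- 0.5 * B %*% Z
  }
  Y
}

#' Post-compensation of the iterated square root
#'
#' Multiplies by \eqn{\sqrt{tr(\Sigma)}} to undo the magnitude change of
#' trace pre-normalization; for exact iterations the result is
#' \eqn{\Sigma^{1/2}}.
#'
#' @param Y_L Output of [newton_schulz_sqrt()].
#' @param trace_value Trace of the original covariance.
#' @return Compensated matrix \eqn{\hat{Y}}.
#' @export
post_compensate <- function(Y_L, trace_value) {
  sqrt(max(trace_value, 0)) * Y_L
}

utri_index <- function(C) {
  key <- paste0("utri_", C)
  idx <- the$cache[[key]]
  if (is.null(idx)) {
    jj <- unlist(lapply(seq_len(C), function(i) i:C))
    ii <- rep(seq_len(C), times = C - seq_len(C) + 1L)
    idx <- ii + C * (jj - 1L)
    the$cache[[key]] <- idx
  }
  idx
}

#' Extract the upper triangle (including diagonal) of a symmetric matrix
#'
#' Row-major order: (1,1), (1,2), ..., (1,C), (2,2), ..., (C,C); the
#' ordering is fixed and part of the checkpoint contract.
#'
#' @param Y Square symmetric matrix (C x C).
#' @return Numeric vector of length C(C+1)/2.
#' @export
extract_upper_triangular <- function(Y) {
  Y <- as.matrix(Y)
  if (nrow(Y) != ncol(Y)) stop("input must be square")
  as.vector(Y)[utri_index(nrow(Y))]
}

#' Second-order pooling of spatial feature maps
#'
#' Full chain: reshape each map to a C x S feature matrix (S = H*W),
#' covariance, trace pre-normalization, `L` Newton-Schulz iterations,
#' post-compensation, and upper-triangular extraction.
#'
#' @param map Array `(C, H, W)` for a single map or `(C, H, W, N)` batch.
#' @param L Newton-Schulz iteration count (default 8).
#' @param eps_guard Trace guard, see [pre_normalize()].
#' @return Matrix `(N, C(C+1)/2)` of pooled features (a single map yields
#'   one row).
#' @export
second_order_pool <- function(map, L = 8L, eps_guard = 1e-12) {
  d <- dim(map)
  if (length(d) == 3L) {
    dim(map) <- c(d, 1L)
    d <- dim(map)
  }
  stopifnot(length(d) == 4L)
  C <- d[1]; S <- d[2] * d[3]; N <- d[4]
  out <- matrix(0, N, C * (C + 1L) / 2L)
  for (n in seq_len(N)) {
    X <- matrix(map[, , , n], C, S)
    Sigma <- compute_covariance(X)
    pn <- pre_normalize(Sigma, eps_guard)
    Y <- newton_schulz_sqrt(pn$A, L)
    Yhat <- post_compensate(Y, pn$trace_value)
    out[n, ] <- extract_upper_triangular(Yhat)
  }
  out
}

## ---- differentiable (graph) counterparts, batched over dim 3 ----

## subtract the per-(channel, sample) mean over spatial positions
ag_center_cols <- function(x) {
  x <- ag_const(x)
  d <- dim(x$value)  # (C, S, N)
  S <- d[2]
  M <- matrix(aperm(x$value, c(2L, 1L, 3L)), nrow = S)
  mu <- colMeans(M)
  out <- aperm(array(sweep(M, 2, mu), c(S, d[1], d[3])), c(2L, 1L, 3L))
  ag_op(out, list(x), function(g) {
    G <- matrix(aperm(g, c(2L, 1L, 3L)), nrow = S)
    dx <- aperm(array(sweep(G, 2, colMeans(G)), c(S, d[1], d[3])),
                c(2L, 1L, 3L))
    list(dx)
  })
}

## per-sample trace of (C, C, N) -> length-N vector
ag_btrace <- function(x) {
  x <- ag_const(x)
  d <- dim(x$value)
  C <- d[1]
  di <- seq(1L, C * C, by = C + 1L)
  M <- matrix(x$value, C * C, d[3])
  ag_op(colSums(M[di, , drop = FALSE]), list(x), function(g) {
    dM <- matrix(0, C * C, d[3])
    dM[di, ] <- rep(g, each = C)
    dim(dM) <- d
    list(dM)
  })
}

## A_n = Sigma_n / (tr_n + eps)
ag_bdiv_vec <- function(Sigma, tr, eps = 1e-12) {
  Sigma <- ag_const(Sigma); tr <- ag_const(tr)
  d <- dim(Sigma$value)
  den <- as.vector(tr$value) + eps
  Sv <- Sigma$value
  out <- Sv
  for (n in seq_len(d[3])) out[, , n] <- Sv[, , n] / den[n]
  ag_op(out, list(Sigma, tr), function(g) {
    dS <- g; dtr <- numeric(d[3])
    for (n in seq_len(d[3])) {
      dS[, , n] <- g[, , n] / den[n]
      dtr[n] <- -sum(g[, , n] * Sv[, , n]) / den[n]^2
    }
    list(dS, dtr)
  })
}

## 3I - X per sample
ag_b3m <- function(x) {
  x <- ag_const(x)
  d <- dim(x$value)
  I3 <- 3 * diag(d[1])
  out <- x$value
  for (n in seq_len(d[3])) out[, , n] <- I3 - out[, , n]
  ag_op(out, list(x), function(g) list(-g))
}

## Yhat_n = sqrt(tr_n + eps) * Y_n
ag_bscale_sqrt <- function(Y, tr, eps = 1e-12) {
  Y <- ag_const(Y); tr <- ag_const(tr)
  d <- dim(Y$value)
  s <- sqrt(pmax(as.vector(tr$value), 0) + eps)
  Yv <- Y$value
  out <- Yv
  for (n in seq_len(d[3])) out[, , n] <- s[n] * Yv[, , n]
  ag_op(out, list(Y, tr), function(g) {
    dY <- g; dtr <- numeric(d[3])
    for (n in seq_len(d[3])) {
      dY[, , n] <- s[n] * g[, , n]
      dtr[n] <- 0.5 / s[n] * sum(g[, , n] * Yv[, , n])
    }
    list(dY, dtr)
  })
}

## upper-triangular extraction, batched: (C, C, N) -> (C(C+1)/2, N)
ag_triu_vec <- function(Y) {
  Y <- ag_const(Y)
  d <- dim(Y$value)
  C <- d[1]
  idx <- utri_index(C)
  M <- matrix(Y$value, C * C, d[3])
  ag_op(M[idx, , drop = FALSE], list(Y), function(g) {
    dM <- matrix(0, C * C, d[3])
    dM[idx, ] <- g
    dim(dM) <- d
    list(dM)
  })
}

## differentiable second-order pooling of a (C, H, W, N) map node
graph_second_order_pool <- function(map, L = 8L, eps_guard = 1e-12) {
  d <- dim(ag_value(map))
  C <- d[1]; S <- d[2] * d[3]; N <- d[4]
  X <- ag_reshape(map, c(C, S, N))
  Xc <- ag_center_cols(X)
  Sigma <- ag_bmm(Xc, Xc, transB = TRUE, scale = 1 / S)
  tr <- ag_btrace(Sigma)
  A <- ag_bdiv_vec(Sigma, tr, eps_guard)
  Y <- A
  if (L > 0) {
    Z <- NULL
    for (l in seq_len(L)) {
      ZY <- if (is.null(Z)) Y else ag_bmm(Z, Y)
      B <- ag_b3m(ZY)
      Ynew <- ag_bmm(Y, B, scale = 0.5)
      Z <- if (is.null(Z)) ag_scale(B, 0.5) else ag_bmm(B, Z, scale = 0.5)
      Y <- Ynew
    }
  }
  Yhat <- ag_bscale_sqrt(Y, tr, eps_guard)
  ag_triu_vec(Yhat)
}
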