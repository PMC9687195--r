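## Normalization layers, attention softmax, head split/merge, and
## batched matrix products.

## layer normalization over the first (feature) dimension of (d, ...) arrays
ag_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- ag_const(x); gamma <- ag_const(gamma); beta <- ag_const(beta)
  d <- dim(x$value)
  dd <- d[1]
  nc <- prod(d[-1])
  xm <- matrix(x$value, nrow = dd)
  mu <- .colMeans(xm, dd, nc)
  xc <- xm - rep(mu, each = dd)
  sd <- sqrt(.colMeans(xc * xc, dd, nc) + eps)
  xhat <- xc / rep(sd, each = dd)
  gv <- as.vector(gamma$value)
  out <- xhat * gv + as.vector(beta$value)
  dim(out) <- d
  ag_op(out, list(x, gamma, beta), function(g) {
    gm <- matrix(g, nrow = dd)
    dgamma <- .rowSums(gm * xhat, dd, nc)
    dbeta <- .rowSums(gm, dd, nc)
    dxh <- gm * gv
    t1 <- .colMeans(dxh, dd, nc)
    t2 <- .colMeans(dxh * xhat, dd, nc)
    dx <- (dxh - rep(t1, each = dd) - xhat * rep(t2, each = dd)) /
      rep(sd, each = dd)
    dim(dx) <- d
    list(dx, dgamma, dbeta)
  })
}

## batch normalization over (H, W, N) per channel of a (C, H, W, N) map;
## `layer` is an environment holding running_mean / running_var buffers
ag_batchnorm <- function(x, gamma, beta, layer, training = TRUE,
                         momentum = 0.1, eps = 1e-5) {
  x <- ag_const(x); gamma <- ag_const(gamma); beta <- ag_const(beta)
  d <- dim(x$value)
  C <- d[1]; M <- prod(d[-1])
  xm <- matrix(x$value, nrow = C)
  gv <- as.vector(gamma$value)
  if (training) {
    mu <- rowMeans(xm)
    xc <- xm - mu
    va <- rowMeans(xc * xc)
    layer$running_mean <- (1 - momentum) * layer$running_mean + momentum * mu
    layer$running_var <- (1 - momentum) * layer$running_var +
      momentum * va * M / max(M - 1, 1)
    sd <- sqrt(va + eps)
    xhat <- xc / sd
    out <- xhat * gv + as.vector(beta$value)
    dim(out) <- d
    ag_op(out, list(x, gamma, beta), function(g) {
      gm <- matrix(g, nrow = C)
      dgamma <- rowSums(gm * xhat)
      dbeta <- rowSums(gm)
      dxh <- gm * gv
      t1 <- rowMeans(dxh)
      t2 <- rowMeans(dxh * xhat)
      dx <- (dxh - t1 - xhat * t2) / sd
      dim(dx) <- d
      list(dx, dgamma, dbeta)
    })
  } else {
    sd <- sqrt(layer$running_var + eps)
    xhat <- (xm - layer$running_mean) / sd
    out <- xhat * gv + as.vector(beta$value)
    dim(out) <- d
    ag_op(out, list(x, gamma, beta), function(g) {
      gm <- matrix(g, nrow = C)
      dx <- gm * gv / sd
      dim(dx) <- d
      list(dx, rowSums(gm * xhat), rowSums(gm))
    })
  }
}

## softmax over the second dimension of a (Tq, Tk, B) score array,
## with max subtraction for stability; rows (fixed Tq, B) sum to 1
ag_softmax2 <- function(s) {
  s <- ag_const(s)
  d <- dim(s$value)
  Tk <- d[2]
  X <- matrix(aperm(s$value, c(2L, 1L, 3L)), nrow = Tk)
  nc <- ncol(X)
  m <- X[1L, ]
  if (Tk > 1L) for (r in 2:Tk) m <- pmax(m, X[r, ])
  E <- exp(X - rep(m, each = Tk))
  P <- E / rep(.colSums(E, Tk, nc), each = Tk)
  out <- aperm(array(P, c(Tk, d[1], d[3])), c(2L, 1L, 3L))
  ag_op(out, list(s), function(g) {
    G <- matrix(aperm(g, c(2L, 1L, 3L)), nrow = Tk)
    dX <- P * (G - rep(.colSums(P * G, Tk, nc), each = Tk))
    list(aperm(array(dX, c(Tk, d[1], d[3])), c(2L, 1L, 3L)))
  })
}

## (d, T, N) -> (d/h, T, N*h), batch index b = (n-1)*h + j for head j
ag_split_heads <- function(x, h) {
  x <- ag_const(x)
  d <- dim(x$value)
  dh <- d[1] %/% h
  v <- x$value
  dim(v) <- c(dh, h, d[2], d[3])
  v <- aperm(v, c(1L, 3L, 2L, 4L))
  dim(v) <- c(dh, d[2], h * d[3])
  ag_op(v, list(x), function(g) {
    dim(g) <- c(dh, d[2], h, d[3])
    g <- aperm(g, c(1L, 3L, 2L, 4L))
    dim(g) <- d
    list(g)
  })
}

## inverse of ag_split_heads: (dh, T, N*h) -> (dh*h, T, N)
ag_merge_heads <- function(x, h) {
  x <- ag_const(x)
  d <- dim(x$value)
  N <- d[3] %/% h
  v <- x$value
  dim(v) <- c(d[1], d[2], h, N)
  v <- aperm(v, c(1L, 3L, 2L, 4L))
  dim(v) <- c(d[1] * h, d[2], N)
  ag_op(v, list(x), function(g) {
    dim(g) <- c(d[1], h, d[2], N)
    g <- aperm(g, c(1L, 3L, 2L, 4L))
    dim(g) <- d
    list(g)
  })
}

## batched matrix multiply over the third dimension:
## out_b = scale * op(A_b) %*% op(B_b)
ag_bmm <- function(a, b, transA = FALSE, transB = FALSE, scale = 1) {
  a <- ag_const(a); b <- ag_const(b)
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(da[3] == db[3])
  B <- da[3]
  p <- if (transA) da[2] else da[1]
  r <- if (transB) db[1] else db[2]
  av <- a$value; bv <- b$value
  out <- array(0, c(p, r, B))
  for (i in seq_len(B)) {
    A <- av[, , i]; Bm <- bv[, , i]
    if (!is.matrix(A)) A <- matrix(A, da[1], da[2])
    if (!is.matrix(Bm)) Bm <- matrix(Bm, db[1], db[2])
    out[, , i] <- scale *
      (if (transA) crossprod(A, if (transB) t(Bm) else Bm)
       else if (transB) tcrossprod(A, Bm) else A %*% Bm)
  }
  ag_op(out, list(a, b), function(g) {
    dA <- array(0, da); dB <- array(0, db)
    for (i in seq_len(B)) {
      G <- matrix(g[, , i], p, r)
      A <- matrix(av[, , i], da[1], da[2])
      Bm <- matrix(bv[, , i], db[1], db[2])
      if (!transA && !transB) {
        dA[, , i] <- scale * tcrossprod(G, Bm)
        dB[, , i] <- scale * crossprod(A, G)
      } else if (!transA && transB) {
        dA[, , i] <- scale * (G %*% Bm)
        dB[, , i] <- scale * crossprod(G, A)
      } else if (transA && !transB) {
        dA[, , i] <- scale * tcrossprod(Bm, G)
        dB[, , i] <- scale * (A %*% G)
      } else {
        dA[, , i] <- scale * t(G %*% Bm)
        dB[, , i] <- scale * t(A %*% G)
      }
    }
    list(dA, dB)
  })
}
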