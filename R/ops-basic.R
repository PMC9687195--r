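## Elementwise, linear-algebra and reshape primitives.
## Array layout conventions used throughout the package:
##   feature map: dim (C, H, W, N)    tokens: dim (d, T, N), T = H*W,
##   token t corresponds to spatial (h, w) with h varying fastest, so
##   map <-> token reshapes are plain dim changes (lossless, no copy).

ag_add <- function(a, b) {
  a <- ag_const(a); b <- ag_const(b)
  stopifnot(identical(dim(a$value), dim(b$value)))
  ag_op(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_scale <- function(a, s) {
  a <- ag_const(a)
  ag_op(a$value * s, list(a), function(g) list(g * s))
}

ag_mul <- function(a, b) {
  a <- ag_const(a); b <- ag_const(b)
  av <- a$value; bv <- b$value
  ag_op(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

## bias broadcast along the first dimension (channels / features)
ag_add_bias <- function(x, b) {
  x <- ag_const(x); b <- ag_const(b)
  C <- dim(x$value)[1] %||% length(x$value)
  stopifnot(length(b$value) == C)
  ag_op(x$value + as.vector(b$value), list(x, b), function(g) {
    list(g, .rowSums(g, C, length(g) %/% C))
  })
}

ag_relu <- function(x) {
  x <- ag_const(x)
  m <- x$value > 0
  ag_op(x$value * m, list(x), function(g) list(g * m))
}

ag_gelu <- function(x) {
  x <- ag_const(x)
  xv <- x$value
  pn <- stats::pnorm(xv)
  ag_op(xv * pn, list(x), function(g) {
    list(g * (pn + xv * stats::dnorm(xv)))
  })
}

ag_matmul <- function(a, b) {
  a <- ag_const(a); b <- ag_const(b)
  av <- a$value; bv <- b$value
  ag_op(av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), crossprod(av, g))
  })
}

## x: (d_in, M) column-major batch of vectors; W: (d_out, d_in); b: length d_out
ag_linear <- function(x, W, b = NULL) {
  x <- ag_const(x); W <- ag_const(W)
  xv <- x$value; Wv <- W$value
  xm <- matrix(xv, nrow = dim(xv)[1])
  out <- Wv %*% xm
  odim <- dim(xv); odim[1] <- nrow(Wv)
  dout <- nrow(Wv)
  if (!is.null(b)) {
    b <- ag_const(b)
    out <- out + as.vector(b$value)
    dim(out) <- odim
    ag_op(out, list(x, W, b), function(g) {
      gm <- g
      dim(gm) <- c(dout, length(g) %/% dout)
      dx <- crossprod(Wv, gm)
      dim(dx) <- dim(xv)
      list(dx, tcrossprod(gm, xm), .rowSums(gm, dout, ncol(gm)))
    })
  } else {
    dim(out) <- odim
    ag_op(out, list(x, W), function(g) {
      gm <- g
      dim(gm) <- c(dout, length(g) %/% dout)
      dx <- crossprod(Wv, gm)
      dim(dx) <- dim(xv)
      list(dx, tcrossprod(gm, xm))
    })
  }
}

ag_reshape <- function(x, newdim) {
  x <- ag_const(x)
  olddim <- dim(x$value)
  v <- x$value
  dim(v) <- newdim
  ag_op(v, list(x), function(g) {
    dim(g) <- olddim
    list(g)
  })
}

## concatenate two 4-D maps along the channel (first) dimension
ag_concat_c <- function(a, b) {
  a <- ag_const(a); b <- ag_const(b)
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(length(da) == 4L, all(da[-1] == db[-1]))
  Ca <- da[1]; Cb <- db[1]
  out <- array(0, c(Ca + Cb, da[2], da[3], da[4]))
  out[seq_len(Ca), , , ] <- a$value
  out[Ca + seq_len(Cb), , , ] <- b$value
  ag_op(out, list(a, b), function(g) {
    list(g[seq_len(Ca), , , , drop = FALSE],
         g[Ca + seq_len(Cb), , , , drop = FALSE])
  })
}

## slice along the first dimension keeping remaining dims
ag_slice_c <- function(x, idx) {
  x <- ag_const(x)
  d <- dim(x$value)
  v <- if (length(d) == 4L) x$value[idx, , , , drop = FALSE]
       else if (length(d) == 3L) x$value[idx, , , drop = FALSE]
       else x$value[idx, , drop = FALSE]
  ag_op(v, list(x), function(g) {
    gx <- array(0, d)
    if (length(d) == 4L) gx[idx, , , ] <- g
    else if (length(d) == 3L) gx[idx, , ] <- g
    else gx[idx, ] <- g
    list(gx)
  })
}

## pick a single scalar element (used to seed Grad-CAM backprop)
ag_pick <- function(x, i, j) {
  x <- ag_const(x)
  d <- dim(x$value)
  ag_op(x$value[i, j], list(x), function(g) {
    gx <- array(0, d)
    gx[i, j] <- g
    list(gx)
  })
}

## global average pool: (C, H, W, N) -> (C, N)
ag_gap <- function(x) {
  x <- ag_const(x)
  d <- dim(x$value)
  C <- d[1]; S <- d[2] * d[3]; N <- d[4]
  v <- x$value
  dim(v) <- c(C, S, N)
  out <- matrix(0, C, N)
  for (n in seq_len(N)) out[, n] <- rowMeans(matrix(v[, , n], C, S))
  ag_op(out, list(x), function(g) {
    gx <- array(0, c(C, S, N))
    for (n in seq_len(N)) gx[, , n] <- matrix(g[, n], C, S) / S
    dim(gx) <- d
    list(gx)
  })
}

## weighted sum of scalar nodes (the three-branch objective)
ag_wsum <- function(nodes, weights) {
  nodes <- lapply(nodes, ag_const)
  v <- sum(vapply(seq_along(nodes), function(i) {
    weights[i] * as.numeric(nodes[[i]]$value)
  }, numeric(1)))
  ag_op(v, nodes, function(g) {
    lapply(weights, function(w) as.numeric(g) * w)
  })
}
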