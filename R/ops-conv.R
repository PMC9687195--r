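## Convolution, depthwise convolution and max pooling via cached
## im2col gather indices.  Index vectors depend only on the input
## geometry and are memoized in `the$cache`.

pad4 <- function(x, p, value = 0) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(value, c(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4]))
  out[, p + seq_len(d[2]), p + seq_len(d[3]), ] <- x
  out
}

unpad4 <- function(x, p, H, W) {
  if (p == 0) return(x)
  x[, p + seq_len(H), p + seq_len(W), , drop = FALSE]
}

conv_out_size <- function(H, k, stride, pad) {
  (H + 2L * pad - k) %/% stride + 1L
}

im2col_plan <- function(C, H, W, k, stride, pad) {
  key <- paste("c", C, H, W, k, stride, pad, sep = "_")
  pl <- the$cache[[key]]
  if (!is.null(pl)) return(pl)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- conv_out_size(H, k, stride, pad)
  Wo <- conv_out_size(W, k, stride, pad)
  if (Ho < 1L || Wo < 1L) {
    stop("convolution output size is non-positive for input ", H, "x", W,
         " with kernel ", k, ", stride ", stride, ", padding ", pad)
  }
  ## patch offsets: channel fastest, then kernel row, then kernel col
  patch <- rep(seq_len(C), times = k * k) +
    C * (rep(rep(0:(k - 1), each = C), times = k) +
           Hp * rep(0:(k - 1), each = C * k))
  origins <- as.vector(outer(C * stride * (0:(Ho - 1)),
                             C * Hp * stride * (0:(Wo - 1)), "+"))
  idx <- as.vector(outer(patch, origins, "+"))
  pl <- list(idx = idx, uidx = sort(unique(idx)), Hp = Hp, Wp = Wp,
             Ho = Ho, Wo = Wo, kkC = k * k * C, P = Ho * Wo)
  the$cache[[key]] <- pl
  pl
}

## x: (C_in, H, W, N); W: (C_out, C_in*k*k) with columns ordered channel
## fastest, then kernel row, then kernel col; b: length C_out or NULL.
ag_conv2d <- function(x, W, b = NULL, k, stride = 1L, pad = 0L) {
  x <- ag_const(x); W <- ag_const(W)
  d <- dim(x$value)
  C <- d[1]; H <- d[2]; Wd <- d[3]; N <- d[4]
  pl <- im2col_plan(C, H, Wd, k, stride, pad)
  Cout <- nrow(W$value)
  Xp <- pad4(x$value, pad)
  dim(Xp) <- c(C * pl$Hp * pl$Wp, N)
  cols <- Xp[pl$idx, , drop = FALSE]
  dim(cols) <- c(pl$kkC, pl$P * N)
  out <- W$value %*% cols
  bv <- if (!is.null(b)) { b <- ag_const(b); as.vector(b$value) } else NULL
  if (!is.null(bv)) out <- out + bv
  dim(out) <- c(Cout, pl$Ho, pl$Wo, N)
  if (!the$recording) return(new_ag_node(out))
  Wv <- W$value
  parents <- if (is.null(b)) list(x, W) else list(x, W, b)
  ag_op(out, parents, function(g) {
    gm <- matrix(g, nrow = Cout)
    dW <- tcrossprod(gm, cols)
    dcols <- crossprod(Wv, gm)
    dim(dcols) <- c(pl$kkC * pl$P, N)
    acc <- rowsum(dcols, group = pl$idx, reorder = TRUE)
    dXp <- matrix(0, C * pl$Hp * pl$Wp, N)
    dXp[pl$uidx, ] <- acc
    dim(dXp) <- c(C, pl$Hp, pl$Wp, N)
    dx <- unpad4(dXp, pad, H, Wd)
    if (is.null(b)) list(dx, dW) else list(dx, dW, rowSums(gm))
  })
}

dw_plan <- function(C, H, W, k, stride, pad) {
  key <- paste("d", C, H, W, k, stride, pad, sep = "_")
  pl <- the$cache[[key]]
  if (!is.null(pl)) return(pl)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- conv_out_size(H, k, stride, pad)
  Wo <- conv_out_size(W, k, stride, pad)
  grid <- as.vector(outer(stride * (0:(Ho - 1)), Hp * stride * (0:(Wo - 1)), "+"))
  base <- rep(seq_len(C), times = Ho * Wo) + C * rep(grid, each = C)
  idx <- vector("list", k * k)
  j <- 0L
  for (kw in 0:(k - 1)) for (kh in 0:(k - 1)) {
    j <- j + 1L
    idx[[j]] <- base + C * (kh + Hp * kw)
  }
  pl <- list(idx = idx, Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, P = Ho * Wo)
  the$cache[[key]] <- pl
  pl
}

## depthwise k x k convolution, stride 1; W9: (k*k, C); b: length C or NULL
ag_dwconv <- function(x, W9, b = NULL, k = 3L, pad = 1L) {
  x <- ag_const(x); W9 <- ag_const(W9)
  d <- dim(x$value)
  C <- d[1]; H <- d[2]; Wd <- d[3]; N <- d[4]
  pl <- dw_plan(C, H, Wd, k, 1L, pad)
  Xp <- pad4(x$value, pad)
  dim(Xp) <- c(C * pl$Hp * pl$Wp, N)
  kk <- k * k
  Wv <- W9$value
  rec <- the$recording
  colsl <- if (rec) vector("list", kk) else NULL
  wvecs <- vector("list", kk)
  out <- matrix(0, C * pl$P, N)
  for (j in seq_len(kk)) {
    cj <- Xp[pl$idx[[j]], , drop = FALSE]
    wvecs[[j]] <- rep(Wv[j, ], times = pl$P)
    out <- out + cj * wvecs[[j]]
    if (rec) colsl[[j]] <- cj
  }
  if (!is.null(b)) {
    b <- ag_const(b)
    out <- out + as.vector(b$value)
  }
  dim(out) <- c(C, pl$Ho, pl$Wo, N)
  if (!rec) return(new_ag_node(out))
  parents <- if (is.null(b)) list(x, W9) else list(x, W9, b)
  ag_op(out, parents, function(g) {
    gm <- matrix(g, nrow = C * pl$P)
    dW <- matrix(0, kk, C)
    dXp <- matrix(0, C * pl$Hp * pl$Wp, N)
    nc <- pl$P * N
    for (j in seq_len(kk)) {
      dW[j, ] <- .rowSums(colsl[[j]] * gm, C, nc)
      dXp[pl$idx[[j]], ] <- dXp[pl$idx[[j]], , drop = FALSE] + gm * wvecs[[j]]
    }
    dim(dXp) <- c(C, pl$Hp, pl$Wp, N)
    dx <- unpad4(dXp, pad, H, Wd)
    db <- if (is.null(b)) NULL else .rowSums(gm, C, nc)
    if (is.null(b)) list(dx, dW) else list(dx, dW, db)
  })
}

## max pooling, k x k window, given stride/padding (pad with -Inf)
ag_maxpool <- function(x, k = 3L, stride = 2L, pad = 1L) {
  x <- ag_const(x)
  d <- dim(x$value)
  C <- d[1]; H <- d[2]; Wd <- d[3]; N <- d[4]
  pl <- dw_plan(C, H, Wd, k, stride, pad)
  Xp <- pad4(x$value, pad, value = -Inf)
  dim(Xp) <- c(C * pl$Hp * pl$Wp, N)
  kk <- k * k
  cur <- Xp[pl$idx[[1]], , drop = FALSE]
  arg <- matrix(1L, nrow(cur), ncol(cur))
  for (j in 2:kk) {
    cand <- Xp[pl$idx[[j]], , drop = FALSE]
    upd <- cand > cur
    cur[upd] <- cand[upd]
    arg[upd] <- j
  }
  out <- cur
  dim(out) <- c(C, pl$Ho, pl$Wo, N)
  if (!the$recording) return(new_ag_node(out))
  ag_op(out, list(x), function(g) {
    gm <- matrix(g, nrow = C * pl$P)
    dXp <- matrix(0, C * pl$Hp * pl$Wp, N)
    for (j in seq_len(kk)) {
      m <- arg == j
      if (!any(m)) next
      tmp <- gm * m
      dXp[pl$idx[[j]], ] <- dXp[pl$idx[[j]], , drop = FALSE] + tmp
    }
    dim(dXp) <- c(C, pl$Hp, pl$Wp, N)
    list(unpad4(dXp, pad, H, Wd))
  })
}
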