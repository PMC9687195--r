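# Make selected internal building blocks available to the tests without
# exporting them from the package.
.pyrfuse_ns <- asNamespace("pyrfuse")
for (nm in c("ag_const", "ag_param", "ag_no_grad", "ag_tape_start",
               "ag_tape_stop", "ag_backward", "ag_zero_grads", "ag_value",
               "ag_op", "ag_relu", "ag_gelu", "ag_add", "ag_conv2d",
               "ag_dwconv", "ag_maxpool", "ag_linear", "ag_layernorm",
               "ag_batchnorm", "ag_softmax2", "ag_bmm", "ag_ls_ce",
               "ag_gap", "ag_reshape", "graph_second_order_pool",
               "new_ope", "ope_forward", "new_sr", "sr_forward",
               "new_attention", "attn_forward", "new_cff", "cff_forward",
               "new_pvt_block", "pvt_block_forward", "pvt_stage_forward",
               "new_stem", "stem_forward", "cnn_stage_forward",
               "new_ffm", "ffm_forward", "hybrid_forward_graph",
               "bn_layer", "ln_layer", "conv_layer", "linear_layer",
               "conv_fwd", "ln_fwd", "new_sgd_state", "sgd_step",
               "train_step", "eval_images", "load_split_images",
               "geom_test", "stack_batch", "log_softmax_cols")) {
  assign(nm, get(nm, envir = .pyrfuse_ns))
}
rm(nm)

# Independent oracles used across the suite.  Each is a deliberately
# plain, loop-based transcription of the mathematical definition, kept
# free of the batching tricks used by the implementation.

# random symmetric positive-definite matrix with a given condition number
rand_spd <- function(C, cond = 100) {
  Q <- qr.Q(qr(matrix(rnorm(C * C), C)))
  lam <- exp(seq(0, -log(cond), length.out = C))
  S <- Q %*% (t(Q) * lam)
  (S + t(S)) / 2
}

# eigendecomposition matrix square root
eig_sqrt <- function(A) {
  e <- eigen(A, symmetric = TRUE)
  e$vectors %*% (t(e$vectors) * sqrt(pmax(e$values, 0)))
}

rel_fro <- function(A, B) {
  norm(A - B, "F") / max(norm(B, "F"), 1e-12)
}

# brute-force covariance: center each row by its mean, multiply by the
# transpose, divide by S
cov_bruteforce <- function(X) {
  C <- nrow(X); S <- ncol(X)
  Xc <- X
  for (i in seq_len(C)) Xc[i, ] <- X[i, ] - mean(X[i, ])
  out <- matrix(0, C, C)
  for (i in seq_len(C)) for (j in seq_len(C)) {
    out[i, j] <- sum(Xc[i, ] * Xc[j, ]) / S
  }
  out
}

# Mann-Whitney pair-counting AUC, ties at 1/2
pair_auc <- function(score, pos) {
  ps <- score[pos]; ns <- score[!pos]
  tot <- 0
  for (a in ps) for (b in ns) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(ps) * length(ns))
}

# textbook multi-head scaled-dot-product attention on the same weights
# as an attention module (no spatial reduction)
oracle_attention <- function(at, x) {
  d <- dim(x)[1]; Tt <- dim(x)[2]; N <- dim(x)[3]
  h <- at$num_heads; dh <- d %/% h
  out <- array(0, dim(x))
  for (n in seq_len(N)) {
    X <- matrix(x[, , n], d, Tt)
    Q <- at$wq$W$value %*% X + at$wq$b$value
    K <- at$wk$W$value %*% X + at$wk$b$value
    V <- at$wv$W$value %*% X + at$wv$b$value
    O <- matrix(0, d, Tt)
    for (j in seq_len(h)) {
      rows <- (j - 1) * dh + seq_len(dh)
      S <- t(Q[rows, , drop = FALSE]) %*% K[rows, , drop = FALSE] / sqrt(dh)
      P <- exp(S - apply(S, 1, max))
      P <- P / rowSums(P)
      O[rows, ] <- V[rows, , drop = FALSE] %*% t(P)
    }
    out[, , n] <- at$wo$W$value %*% O + at$wo$b$value
  }
  out
}

# straight-line spatial reduction: reshape tokens to a map, convolve with
# kernel = stride = Rs, flatten, project, layer-normalize (per token)
oracle_spatial_reduction <- function(sr, x, H, W, Rs) {
  d <- dim(x)[1]; N <- dim(x)[3]
  Ho <- H %/% Rs; Wo <- W %/% Rs
  Wc <- sr$conv$W$value; bc <- as.vector(sr$conv$b$value)
  Ws <- sr$proj$W$value; bs <- as.vector(sr$proj$b$value)
  gam <- as.vector(sr$norm$gamma$value); bet <- as.vector(sr$norm$beta$value)
  out <- array(0, c(d, Ho * Wo, N))
  for (n in seq_len(N)) {
    map <- array(x[, , n], c(d, H, W))
    for (j in seq_len(Wo)) for (i in seq_len(Ho)) {
      block <- map[, (i - 1) * Rs + seq_len(Rs), (j - 1) * Rs + seq_len(Rs),
                   drop = FALSE]
      y <- Wc %*% as.vector(block) + bc
      z <- Ws %*% y + bs
      mu <- mean(z); sd <- sqrt(mean((z - mu)^2) + 1e-5)
      out[, i + (j - 1) * Ho, n] <- gam * (z - mu) / sd + bet
    }
  }
  out
}

# unbatched per-pixel evaluation of the fusion rule:
# M_pvt, M_cnn = Split(ReLU(G_fuse(Concat(F_pvt, F_cnn))));
# outputs F + G(M) for each branch
oracle_ffm <- function(ffm, fp, fc) {
  Cp <- dim(fp)[1]; Cc <- dim(fc)[1]
  H <- dim(fp)[2]; W <- dim(fp)[3]; N <- dim(fp)[4]
  Wf <- ffm$gfuse$W$value; bf <- as.vector(ffm$gfuse$b$value)
  Wp <- ffm$gpvt$W$value; bp <- as.vector(ffm$gpvt$b$value)
  Wc <- ffm$gcnn$W$value; bc <- as.vector(ffm$gcnn$b$value)
  op <- fp; oc <- fc
  for (n in seq_len(N)) for (j in seq_len(W)) for (i in seq_len(H)) {
    v <- c(fp[, i, j, n], fc[, i, j, n])
    m <- pmax(Wf %*% v + bf, 0)
    op[, i, j, n] <- fp[, i, j, n] + Wp %*% m[seq_len(Cp)] + bp
    oc[, i, j, n] <- fc[, i, j, n] + Wc %*% m[Cp + seq_len(Cc)] + bc
  }
  list(pvt = op, cnn = oc)
}

# central-difference gradient of a scalar-valued function
numgrad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# weighted-sum scalar node, used to seed backward passes in op tests
ag_test_sum <- function(n, w) {
  pyrfuse:::ag_op(sum(n$value * w), list(n),
                  function(g) list(as.numeric(g) * w))
}

# tiny synthetic dataset on disk, shared across engine tests
micro_dataset <- local({
  cache <- NULL
  function(n_per_class = 20L) {
    if (!is.null(cache) && cache$n == n_per_class) return(cache)
    dir <- file.path(tempdir(), paste0("pyrfuse_micro_", n_per_class))
    if (!dir.exists(dir)) {
      spec <- synthetic_spec(n_per_class = n_per_class, size = 64L, seed = 11L)
      generate_synthetic_dataset(spec, dir)
    }
    man <- read_manifest(file.path(dir, "manifest.csv"))
    man <- stratified_split(man, 0.8, seed = 3L)
    cache <<- list(dir = dir, manifest = man, n = n_per_class)
    cache
  }
})
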