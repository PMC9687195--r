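test_that("stage config validation enforces head divisibility and overlap", {
  expect_error(pvt_stage_config(1, 64, 5, 8, 8, 3, 7, 4, 3), "divisible")
  expect_error(pvt_stage_config(1, 64, 1, 8, 8, 3, 3, 3, 1), "overlap")
  cfgs <- pvt_default_configs()
  expect_equal(vapply(cfgs, `[[`, integer(1), "embed_dim"),
               c(64L, 128L, 320L, 512L))
  expect_equal(vapply(cfgs, `[[`, integer(1), "depth"), c(3L, 8L, 27L, 3L))
  expect_equal(vapply(cfgs, `[[`, integer(1), "sr_ratio"), c(8L, 4L, 2L, 1L))
})

test_that("overlapping patch embedding follows convolution output-size arithmetic", {
  set.seed(1)
  cfg1 <- pvt_default_configs()[[1]]
  ope <- new_ope(3L, cfg1)
  x <- array(rnorm(3 * 224 * 224), c(3, 224, 224, 1))
  emb <- ag_no_grad(ope_forward(ope, x))
  expect_equal(c(emb$grid_h, emb$grid_w), c(56, 56))
  expect_equal(dim(emb$tokens$value), c(64, 3136, 1))

  cfg2 <- pvt_default_configs()[[2]]
  ope2 <- new_ope(64L, cfg2)
  x2 <- array(rnorm(64 * 56 * 56), c(64, 56, 56, 1))
  emb2 <- ag_no_grad(ope_forward(ope2, x2))
  expect_equal(c(emb2$grid_h, emb2$grid_w), c(28, 28))

  # zero input with zero bias gives zero tokens before normalization
  ope2$conv$b$value[] <- 0
  z <- ag_no_grad(conv_fwd(ope2$conv, ag_const(array(0, c(64, 56, 56, 1)))))
  expect_true(all(z$value == 0))

  # non-positive output size names the offending geometry
  tiny_cfg <- pvt_stage_config(1, 8, 1, 1, 4, 1, 7, 4, 0)
  ope3 <- new_ope(3L, tiny_cfg)
  expect_error(ag_no_grad(ope_forward(ope3, array(0, c(3, 6, 6, 1)))),
               "smaller than")
})

test_that("spatial reduction matches a straight-line transcription of its formula", {
  set.seed(2)
  d <- 4L; H <- 8L; W <- 8L; Rs <- 4L
  sr <- new_sr(d, Rs)
  x <- array(rnorm(d * H * W * 2), c(d, H * W, 2))
  out <- ag_no_grad(sr_forward(sr, ag_const(x), H, W, Rs))$value
  expect_equal(dim(out), c(d, 4L, 2L))  # 64 tokens -> 4 tokens
  orc <- oracle_spatial_reduction(sr, x, H, W, Rs)
  expect_lt(max(abs(out - orc)), 1e-10)

  sr2 <- new_sr(3L, 2L)
  x2 <- array(rnorm(3 * 6 * 6 * 2), c(3, 36, 2))
  out2 <- ag_no_grad(sr_forward(sr2, ag_const(x2), 6L, 6L, 2L))$value
  expect_lt(max(abs(out2 - oracle_spatial_reduction(sr2, x2, 6L, 6L, 2L))),
            1e-10)

  expect_error(ag_no_grad(sr_forward(sr, ag_const(x), 6L, 6L, 4L)),
               "not divisible")
})

test_that("Rs=1 with identity reduction parameters degenerates to layer normalization", {
  set.seed(3)
  d <- 4L
  sr <- new_sr(d, 1L)
  # identity convolution and projection, unit-scale layer norm
  sr$conv$W$value <- diag(d); sr$conv$b$value[] <- 0
  sr$proj$W$value <- diag(d); sr$proj$b$value[] <- 0
  x <- array(rnorm(d * 9 * 2), c(d, 9, 2))
  out <- ag_no_grad(sr_forward(sr, ag_const(x), 3L, 3L, 1L))$value
  ln <- ag_no_grad(ln_fwd(sr$norm, ag_const(x)))$value
  expect_lt(max(abs(out - ln)), 1e-12)
})

test_that("spatial-reduction attention reduces to the textbook oracle when Rs=1", {
  set.seed(4)
  for (case in list(list(d = 4L, h = 1L, g = 3L), list(d = 8L, h = 2L, g = 8L),
                    list(d = 12L, h = 4L, g = 5L))) {
    cfg <- pvt_stage_config(4, case$d, case$h, 1L, 4L, 1L, 3L, 2L, 1L)
    at <- new_attention(cfg)
    x <- array(rnorm(case$d * case$g^2 * 2), c(case$d, case$g^2, 2))
    out <- ag_no_grad(attn_forward(at, ag_const(x), case$g, case$g))$value
    expect_lt(max(abs(out - oracle_attention(at, x))), 1e-5)
  }
})

test_that("single-key attention returns the value vector under identity projections", {
  cfg <- pvt_stage_config(4, 3L, 1L, 1L, 4L, 1L, 3L, 2L, 1L)
  at <- new_attention(cfg)
  for (ly in list(at$wq, at$wk, at$wv, at$wo)) {
    ly$W$value <- diag(3); ly$b$value[] <- 0
  }
  x <- array(c(0.3, -1, 2), c(3, 1, 1))  # a single token: softmax over 1 key
  out <- ag_no_grad(attn_forward(at, ag_const(x), 1L, 1L))$value
  expect_equal(out, x)
})

test_that("attention weights are row-stochastic and match a hand evaluation", {
  # 2 tokens, d = 2, h = 1, hand-set weights
  cfg <- pvt_stage_config(4, 2L, 1L, 1L, 4L, 1L, 3L, 2L, 1L)
  at <- new_attention(cfg)
  at$wq$W$value <- matrix(c(1, 0, 0, 1), 2); at$wq$b$value[] <- 0
  at$wk$W$value <- matrix(c(1, 0, 0, 1), 2); at$wk$b$value[] <- 0
  at$wv$W$value <- diag(2); at$wv$b$value[] <- 0
  at$wo$W$value <- diag(2); at$wo$b$value[] <- 0
  x <- array(c(1, 0, 0, 1), c(2, 2, 1))  # tokens e1, e2
  # scores q_i . k_j / sqrt(2): diag 1/sqrt(2), off-diag 0
  s <- 1 / sqrt(2)
  P <- matrix(c(exp(s), 1, 1, exp(s)), 2, byrow = TRUE)
  P <- P / rowSums(P)
  expected <- t(P %*% t(matrix(x[, , 1], 2)))
  out <- ag_no_grad(attn_forward(at, ag_const(x), 2L, 1L))$value
  expect_equal(matrix(out[, , 1], 2), expected, tolerance = 1e-12)
  expect_equal(rowSums(P), c(1, 1))
})

test_that("attention rows sum to one for every head and query", {
  set.seed(6)
  cfg <- pvt_stage_config(2, 8L, 2L, 2L, 4L, 1L, 3L, 2L, 1L)
  at <- new_attention(cfg)
  x <- array(rnorm(8 * 16 * 3), c(8, 16, 3))
  ag_tape_start()
  kv <- sr_forward(at$sr, ag_const(x), 4L, 4L, 2L)
  q <- ag_linear(ag_const(x), at$wq$W, at$wq$b)
  k <- ag_linear(kv, at$wk$W, at$wk$b)
  qh <- pyrfuse:::ag_split_heads(q, 2L)
  kh <- pyrfuse:::ag_split_heads(k, 2L)
  P <- ag_softmax2(ag_bmm(qh, kh, transA = TRUE, scale = 1 / 2))
  ag_tape_stop()
  sums <- apply(P$value, c(1, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-6)
})

test_that("the convolutional feed-forward preserves shape and zero projection gives residual identity", {
  set.seed(7)
  cfg <- pvt_stage_config(3, 320L, 5L, 2L, 4L, 1L, 3L, 2L, 1L)
  cf <- new_cff(cfg)
  expect_equal(cf$hidden, 1280L)
  cfg1 <- pvt_stage_config(1, 64L, 1L, 8L, 8L, 1L, 7L, 4L, 3L)
  expect_equal(new_cff(cfg1)$hidden, 512L)

  cfg_s <- pvt_stage_config(3, 8L, 2L, 2L, 4L, 1L, 3L, 2L, 1L)
  cfs <- new_cff(cfg_s)
  x <- array(rnorm(8 * 14 * 2), c(8, 14, 2))
  out <- ag_no_grad(cff_forward(cfs, ag_const(x), 7L, 2L))$value
  expect_equal(dim(out), dim(x))

  blk <- new_pvt_block(cfg_s)
  blk$attn$wo$W$value[] <- 0; blk$attn$wo$b$value[] <- 0
  blk$cff$fc2$W$value[] <- 0; blk$cff$fc2$b$value[] <- 0
  x44 <- array(rnorm(8 * 16 * 2), c(8, 16, 2))
  out2 <- ag_no_grad(pvt_block_forward(blk, ag_const(x44), 4L, 4L))$value
  expect_equal(out2, x44)  # zero-initialized outputs make the block identity
})

test_that("block forward equals the sequential residual composition", {
  set.seed(8)
  cfg <- pvt_stage_config(2, 8L, 2L, 2L, 4L, 1L, 3L, 2L, 1L)
  blk <- new_pvt_block(cfg)
  x <- array(rnorm(8 * 16 * 2), c(8, 16, 2))
  out <- ag_no_grad(pvt_block_forward(blk, ag_const(x), 4L, 4L))$value
  step <- ag_no_grad({
    t1 <- ag_add(ag_const(x),
                 attn_forward(blk$attn, ln_fwd(blk$ln1, ag_const(x)), 4L, 4L))
    ag_add(t1, cff_forward(blk$cff, ln_fwd(blk$ln2, t1), 4L, 4L))$value
  })
  expect_identical(out, step)
})

test_that("the branch produces the documented stage pyramid and is deterministic", {
  set.seed(9)
  branch <- new_pvt_branch(pvt_tiny_configs())
  x <- array(rnorm(3 * 64 * 64 * 2), c(3, 64, 64, 2))
  maps <- pvt_forward(branch, x)
  expect_equal(lapply(maps, function(m) dim(m)[1:3]),
               list(c(16L, 16L, 16L), c(32L, 8L, 8L), c(64L, 4L, 4L),
                    c(128L, 2L, 2L)))
  maps2 <- pvt_forward(branch, x)
  expect_identical(maps, maps2)
  # spatial sizes strictly decrease
  sizes <- vapply(maps, function(m) dim(m)[2], numeric(1))
  expect_true(all(diff(sizes) < 0))
})

test_that("token/map reshapes round-trip losslessly", {
  x <- array(rnorm(6 * 4 * 5 * 2), c(6, 4, 5, 2))
  tok <- ag_no_grad(ag_reshape(ag_const(x), c(6, 20, 2)))$value
  back <- ag_no_grad(ag_reshape(ag_const(tok), c(6, 4, 5, 2)))$value
  expect_identical(back, x)
})

test_that("parameter count is a pure function of the configuration", {
  set.seed(10)
  b1 <- new_pvt_branch(pvt_tiny_configs())
  set.seed(999)
  b2 <- new_pvt_branch(pvt_tiny_configs())
  n1 <- sum(vapply(collect_params(b1), function(p) length(p$value), numeric(1)))
  n2 <- sum(vapply(collect_params(b2), function(p) length(p$value), numeric(1)))
  expect_identical(n1, n2)
  expect_identical(n1, 441488)  # regression constant for the tiny plan
})
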