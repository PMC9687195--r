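## Pyramid vision Transformer branch: four stages of overlapping patch
## embedding (OPE) followed by blocks of spatial-reduction multi-head
## attention (SR-MHA) and a convolutional feed-forward network (CFF),
## exposing a spatial feature map after every stage.

#' Stage configuration for the pyramid Transformer branch
#'
#' @param stage_index Stage number 1..4.
#' @param embed_dim Token/channel dimension `d_i`.
#' @param num_heads Attention heads `h_i` (must divide `embed_dim`).
#' @param sr_ratio Spatial-reduction ratio `Rs_i` (kernel = stride of the
#'   reduction convolution applied to keys/values); 1 disables reduction.
#' @param mlp_ratio Feed-forward expansion `Rm_i`.
#' @param depth Number of attention/CFF blocks `N_i`.
#' @param patch_kernel,patch_stride,patch_padding Overlapping patch
#'   embedding convolution geometry; the kernel must exceed the stride
#'   (that is what makes neighbouring patches overlap).
#' @return A `pvt_stage_config` list.
#' @export
pvt_stage_config <- function(stage_index, embed_dim, num_heads, sr_ratio,
                             mlp_ratio, depth, patch_kernel, patch_stride,
                             patch_padding) {
  if (embed_dim %% num_heads != 0) {
    stop("stage ", stage_index, ": embed_dim ", embed_dim,
         " not divisible by num_heads ", num_heads)
  }
  if (patch_kernel <= patch_stride) {
    stop("stage ", stage_index, ": patch_kernel must exceed patch_stride ",
         "(overlap property)")
  }
  if (sr_ratio < 1 || depth < 1) {
    stop("stage ", stage_index, ": sr_ratio and depth must be >= 1")
  }
  structure(list(stage_index = as.integer(stage_index),
                 embed_dim = as.integer(embed_dim),
                 num_heads = as.integer(num_heads),
                 sr_ratio = as.integer(sr_ratio),
                 mlp_ratio = as.integer(mlp_ratio),
                 depth = as.integer(depth),
                 patch_kernel = as.integer(patch_kernel),
                 patch_stride = as.integer(patch_stride),
                 patch_padding = as.integer(patch_padding)),
            class = "pvt_stage_config")
}

#' Default four-stage plans for the pyramid Transformer branch
#'
#' The full-size plan uses embedding dims \[64, 128, 320, 512\], heads
#' \[1, 2, 5, 8\], spatial-reduction ratios \[8, 4, 2, 1\], feed-forward
#' ratios \[8, 8, 4, 4\] and depths \[3, 8, 27, 3\]; stage 1 embeds with a
#' 7x7 stride-4 convolution (pad 3) and stages 2-4 with 3x3 stride-2
#' (pad 1), so a 224 input yields 56/28/14/7 maps.  The tiny plan keeps
#' the same geometry on narrower dims for desk-scale runs.
#'
#' @param dims,heads,sr_ratios,mlp_ratios,depths Per-stage integer vectors.
#' @param stage1_stride Stride of the stage-1 embedding (default 4).
#' @return List of 4 [pvt_stage_config()].
#' @export
pvt_default_configs <- function(dims = c(64, 128, 320, 512),
                                heads = c(1, 2, 5, 8),
                                sr_ratios = c(8, 4, 2, 1),
                                mlp_ratios = c(8, 8, 4, 4),
                                depths = c(3, 8, 27, 3),
                                stage1_stride = 4L) {
  lapply(1:4, function(i) {
    pvt_stage_config(i, dims[i], heads[i], sr_ratios[i], mlp_ratios[i],
                     depths[i],
                     patch_kernel = if (i == 1) 7L else 3L,
                     patch_stride = if (i == 1) stage1_stride else 2L,
                     patch_padding = if (i == 1) 3L else 1L)
  })
}

#' @rdname pvt_default_configs
#' @export
pvt_tiny_configs <- function(dims = c(16, 32, 64, 128),
                             heads = c(1, 2, 4, 8),
                             sr_ratios = c(8, 4, 2, 1),
                             mlp_ratios = c(8, 8, 4, 4),
                             depths = c(1, 1, 1, 1)) {
  pvt_default_configs(dims, heads, sr_ratios, mlp_ratios, depths)
}

## ---- modules ----

new_ope <- function(cin, cfg) {
  new_layer("ope_module",
            conv = conv_layer(cin, cfg$embed_dim, cfg$patch_kernel,
                              cfg$patch_stride, cfg$patch_padding,
                              bias = TRUE, init = "trunc"),
            norm = ln_layer(cfg$embed_dim))
}

#' Overlapping patch embedding
#'
#' Tokenizes a feature map with a strided convolution whose kernel exceeds
#' its stride, then layer-normalizes the tokens.
#'
#' @param ope An OPE module created inside the branch (internal
#'   constructors; see [new_pvt_branch()]).
#' @param x Feature map node or array `(C, H, W, N)`.
#' @return List with `tokens` `(d, T, N)`, `grid_h`, `grid_w`.
#' @keywords internal
ope_forward <- function(ope, x) {
  xv <- ag_value(ag_const(x))
  d <- dim(xv)
  k <- ope$conv$k
  if (d[2] < k || d[3] < k) {
    stop("input ", d[2], "x", d[3], " smaller than patch kernel ", k)
  }
  m <- conv_fwd(ope$conv, x)
  md <- dim(m$value)
  tok <- ag_reshape(m, c(md[1], md[2] * md[3], md[4]))
  list(tokens = ln_fwd(ope$norm, tok), grid_h = md[2], grid_w = md[3])
}

new_sr <- function(d, Rs) {
  new_layer("sr_module",
            conv = conv_layer(d, d, Rs, stride = Rs, pad = 0L, init = "trunc"),
            proj = linear_layer(d, d),
            norm = ln_layer(d))
}

## literal spatial reduction: LN(RP2(Conv(RP1(x), Rs)) %*% W_S)
sr_forward <- function(sr, tokens, grid_h, grid_w, Rs) {
  d <- dim(ag_value(tokens))
  if (grid_h %% Rs != 0 || grid_w %% Rs != 0) {
    stop("token grid ", grid_h, "x", grid_w, " not divisible by sr_ratio ", Rs)
  }
  map <- ag_reshape(tokens, c(d[1], grid_h, grid_w, d[3]))
  red <- conv_fwd(sr$conv, map)
  rd <- dim(red$value)
  tok <- ag_reshape(red, c(rd[1], rd[2] * rd[3], rd[4]))
  ln_fwd(sr$norm, linear_fwd(sr$proj, tok))
}

new_attention <- function(cfg) {
  d <- cfg$embed_dim
  new_layer("attn_module",
            wq = linear_layer(d, d), wk = linear_layer(d, d),
            wv = linear_layer(d, d), wo = linear_layer(d, d),
            sr = if (cfg$sr_ratio > 1) new_sr(d, cfg$sr_ratio) else NULL,
            num_heads = cfg$num_heads, sr_ratio = cfg$sr_ratio)
}

## SR-MHA: queries from full-resolution tokens, keys/values from the
## spatially reduced tokens; per-head scaled dot-product attention
attn_forward <- function(at, tokens, grid_h, grid_w) {
  d <- dim(ag_value(tokens))
  h <- at$num_heads
  dh <- d[1] %/% h
  kv_src <- if (!is.null(at$sr)) {
    sr_forward(at$sr, tokens, grid_h, grid_w, at$sr_ratio)
  } else tokens
  q <- linear_fwd(at$wq, tokens)
  k <- linear_fwd(at$wk, kv_src)
  v <- linear_fwd(at$wv, kv_src)
  qh <- ag_split_heads(q, h)
  kh <- ag_split_heads(k, h)
  vh <- ag_split_heads(v, h)
  scores <- ag_bmm(qh, kh, transA = TRUE, scale = 1 / sqrt(dh))
  P <- ag_softmax2(scores)
  outh <- ag_bmm(vh, P, transB = TRUE)
  linear_fwd(at$wo, ag_merge_heads(outh, h))
}

new_cff <- function(cfg) {
  d <- cfg$embed_dim
  hid <- d * cfg$mlp_ratio
  new_layer("cff_module",
            fc1 = linear_layer(d, hid),
            dw = dw_layer(hid),
            fc2 = linear_layer(hid, d),
            hidden = hid)
}

## convolutional feed-forward: expand, depthwise 3x3 on the token map,
## GELU, project back
cff_forward <- function(cf, tokens, grid_h, grid_w) {
  d <- dim(ag_value(tokens))
  hidden <- ag_linear(tokens, cf$fc1$W, cf$fc1$b)
  hmap <- ag_reshape(hidden, c(cf$hidden, grid_h, grid_w, d[3]))
  hmap <- dw_fwd(cf$dw, hmap)
  htok <- ag_reshape(hmap, c(cf$hidden, grid_h * grid_w, d[3]))
  linear_fwd(cf$fc2, ag_gelu(htok))
}

new_pvt_block <- function(cfg) {
  new_layer("pvt_block",
            ln1 = ln_layer(cfg$embed_dim),
            attn = new_attention(cfg),
            ln2 = ln_layer(cfg$embed_dim),
            cff = new_cff(cfg))
}

## pre-norm residual composition: x + MHA(LN(x)); x + CFF(LN(x))
pvt_block_forward <- function(blk, tokens, grid_h, grid_w) {
  a <- attn_forward(blk$attn, ln_fwd(blk$ln1, tokens), grid_h, grid_w)
  tokens <- ag_add(tokens, a)
  f <- cff_forward(blk$cff, ln_fwd(blk$ln2, tokens), grid_h, grid_w)
  ag_add(tokens, f)
}

new_pvt_stage <- function(cin, cfg) {
  new_layer("pvt_stage",
            ope = new_ope(cin, cfg),
            blocks = lapply(seq_len(cfg$depth), function(i) new_pvt_block(cfg)),
            norm = ln_layer(cfg$embed_dim),
            cfg = cfg)
}

## one stage: OPE -> blocks -> stage-end LN -> reshape tokens to a map
pvt_stage_forward <- function(stage, x) {
  emb <- ope_forward(stage$ope, x)
  tok <- emb$tokens
  for (blk in stage$blocks) {
    tok <- pvt_block_forward(blk, tok, emb$grid_h, emb$grid_w)
  }
  tok <- ln_fwd(stage$norm, tok)
  d <- dim(tok$value)
  ag_reshape(tok, c(d[1], emb$grid_h, emb$grid_w, d[3]))
}

#' Construct the pyramid Transformer branch
#'
#' @param cfgs List of 4 [pvt_stage_config()] (see [pvt_default_configs()]).
#' @param in_chans Input image channels (default 3).
#' @return A `pvt_branch` module.
#' @export
new_pvt_branch <- function(cfgs = pvt_default_configs(), in_chans = 3L) {
  cins <- c(in_chans, vapply(cfgs[-4], `[[`, integer(1), "embed_dim"))
  new_layer("pvt_branch",
            stages = lapply(1:4, function(i) new_pvt_stage(cins[i], cfgs[[i]])),
            cfgs = cfgs)
}

#' Forward pass of the pyramid Transformer branch
#'
#' @param branch A `pvt_branch`.
#' @param image Array `(3, H, W, N)` of normalized image values.
#' @return List of 4 stage feature maps (arrays `(d_i, H_i, W_i, N)`) with
#'   strictly decreasing spatial size.
#' @export
pvt_forward <- function(branch, image) {
  ag_no_grad({
    x <- ag_const(image)
    maps <- vector("list", 4L)
    for (i in 1:4) {
      x <- pvt_stage_forward(branch$stages[[i]], x)
      maps[[i]] <- x$value
    }
    maps
  })
}
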