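## Convolutional branch: ResNet50-style stem plus four bottleneck stages,
## exposing a spatial map after every stage so that resolutions match the
## Transformer branch stage-for-stage (a precondition for fusion).

#' Configuration of the convolutional branch
#'
#' @param plan Output channels per stage (default the ResNet50 plan
#'   `c(256, 512, 1024, 2048)`).
#' @param blocks Bottleneck blocks per stage (default `c(3, 4, 6, 3)`).
#' @param stem_out Stem channels (default `plan[1] / 4`, i.e. 64 for the
#'   full plan).
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(plan = c(256, 512, 1024, 2048),
                       blocks = c(3, 4, 6, 3),
                       stem_out = plan[1] %/% 4L) {
  structure(list(plan = as.integer(plan), blocks = as.integer(blocks),
                 stem_out = as.integer(stem_out)),
            class = "cnn_config")
}

#' @rdname cnn_config
#' @export
cnn_tiny_config <- function() {
  cnn_config(plan = c(32, 64, 128, 256), blocks = c(1, 1, 1, 1))
}

new_stem <- function(stem_out, in_chans = 3L) {
  new_layer("cnn_stem",
            conv = conv_layer(in_chans, stem_out, 7L, stride = 2L, pad = 3L,
                              bias = FALSE),
            bn = bn_layer(stem_out))
}

## 7x7 stride-2 conv + BN + ReLU + 3x3 stride-2 max pool (1/4 resolution)
stem_forward <- function(st, x, training) {
  h <- ag_relu(bn_fwd(st$bn, conv_fwd(st$conv, x), training))
  ag_maxpool(h, k = 3L, stride = 2L, pad = 1L)
}

new_bottleneck <- function(cin, width, cout, stride) {
  project <- (cin != cout) || (stride != 1L)
  new_layer("bottleneck",
            conv1 = conv_layer(cin, width, 1L, bias = FALSE),
            bn1 = bn_layer(width),
            conv2 = conv_layer(width, width, 3L, stride = stride, pad = 1L,
                               bias = FALSE),
            bn2 = bn_layer(width),
            conv3 = conv_layer(width, cout, 1L, bias = FALSE),
            bn3 = bn_layer(cout),
            down_conv = if (project) conv_layer(cin, cout, 1L, stride = stride,
                                                bias = FALSE) else NULL,
            down_bn = if (project) bn_layer(cout) else NULL)
}

bottleneck_forward <- function(bk, x, training) {
  h <- ag_relu(bn_fwd(bk$bn1, conv_fwd(bk$conv1, x), training))
  h <- ag_relu(bn_fwd(bk$bn2, conv_fwd(bk$conv2, h), training))
  h <- bn_fwd(bk$bn3, conv_fwd(bk$conv3, h), training)
  sc <- if (!is.null(bk$down_conv)) {
    bn_fwd(bk$down_bn, conv_fwd(bk$down_conv, x), training)
  } else x
  ag_relu(ag_add(h, sc))
}

new_cnn_stage <- function(cin, cout, nblocks, stride) {
  width <- cout %/% 4L
  blocks <- vector("list", nblocks)
  blocks[[1]] <- new_bottleneck(cin, width, cout, stride)
  if (nblocks > 1) {
    for (i in 2:nblocks) blocks[[i]] <- new_bottleneck(cout, width, cout, 1L)
  }
  new_layer("cnn_stage", blocks = blocks)
}

cnn_stage_forward <- function(stage, x, training) {
  for (bk in stage$blocks) x <- bottleneck_forward(bk, x, training)
  x
}

#' Construct the convolutional branch
#'
#' @param cfg A [cnn_config()].
#' @param in_chans Input channels (default 3).
#' @return A `cnn_branch` module.
#' @export
new_cnn_branch <- function(cfg = cnn_config(), in_chans = 3L) {
  cins <- c(cfg$stem_out, cfg$plan[-4])
  strides <- c(1L, 2L, 2L, 2L)
  new_layer("cnn_branch",
            stem = new_stem(cfg$stem_out, in_chans),
            stages = lapply(1:4, function(i) {
              new_cnn_stage(cins[i], cfg$plan[i], cfg$blocks[i], strides[i])
            }),
            cfg = cfg)
}

#' Forward pass of the convolutional branch
#'
#' @param branch A `cnn_branch`.
#' @param image Array `(3, H, W, N)`.
#' @return List of 4 stage feature maps (arrays).
#' @export
cnn_forward <- function(branch, image) {
  ag_no_grad({
    x <- stem_forward(branch$stem, ag_const(image), training = FALSE)
    maps <- vector("list", 4L)
    for (i in 1:4) {
      x <- cnn_stage_forward(branch$stages[[i]], x, training = FALSE)
      maps[[i]] <- x$value
    }
    maps
  })
}
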