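## Feature fusion module (FFM) and the hybrid dual-branch model with its
## three classification heads (two average-pooling auxiliary heads, one
## second-order-pooling main head).

new_ffm <- function(c_pvt, c_cnn) {
  csum <- c_pvt + c_cnn
  new_layer("ffm_module",
            gfuse = conv_layer(csum, csum, 1L),
            gpvt = conv_layer(c_pvt, c_pvt, 1L),
            gcnn = conv_layer(c_cnn, c_cnn, 1L),
            c_pvt = as.integer(c_pvt), c_cnn = as.integer(c_cnn))
}

## M_pvt, M_cnn = Split(ReLU(G_fuse(Concat(F_pvt, F_cnn)))); the split
## parts pass through G_pvt / G_cnn and are added back residually.
ffm_forward <- function(ffm, f_pvt, f_cnn) {
  dp <- dim(ag_value(f_pvt)); dc <- dim(ag_value(f_cnn))
  if (!all(dp[2:3] == dc[2:3])) {
    stop("FFM spatial mismatch: transformer map ",
         paste(dp, collapse = "x"), " vs convolutional map ",
         paste(dc, collapse = "x"))
  }
  fused <- ag_relu(conv_fwd(ffm$gfuse, ag_concat_c(f_pvt, f_cnn)))
  m_pvt <- ag_slice_c(fused, seq_len(ffm$c_pvt))
  m_cnn <- ag_slice_c(fused, ffm$c_pvt + seq_len(ffm$c_cnn))
  list(pvt = ag_add(f_pvt, conv_fwd(ffm$gpvt, m_pvt)),
       cnn = ag_add(f_cnn, conv_fwd(ffm$gcnn, m_cnn)))
}

#' Channel-level feature fusion of two equal-resolution maps
#'
#' Array-level interface to the fusion module: concatenates the two maps
#' along channels, mixes them with a 1x1 convolution + ReLU, splits back
#' into the original channel counts, projects each part with a 1x1
#' convolution, and adds the result residually onto the inputs.
#'
#' @param f_pvt,f_cnn Arrays `(C_pvt, H, W, N)` and `(C_cnn, H, W, N)`.
#' @param ffm Fusion module (from the model, or `NULL` to create one with
#'   random weights using the current RNG state).
#' @return List of two arrays shaped like the inputs.
#' @export
ffm_fuse <- function(f_pvt, f_cnn, ffm = NULL) {
  if (is.null(ffm)) ffm <- new_ffm(dim(f_pvt)[1], dim(f_cnn)[1])
  ag_no_grad({
    out <- ffm_forward(ffm, ag_const(f_pvt), ag_const(f_cnn))
    list(pvt = out$pvt$value, cnn = out$cnn$value)
  })
}

#' Construct the dual-branch hybrid classifier
#'
#' Builds the pyramid-Transformer branch, the convolutional branch, the
#' three fusion modules coupling stages 1-3, and the heads: global average
#' pooling + linear for each branch (auxiliary), and channel concatenation
#' of the stage-4 maps followed by second-order pooling + linear for the
#' main output.
#'
#' @param pvt_cfgs List of 4 [pvt_stage_config()].
#' @param cnn_cfg A [cnn_config()].
#' @param num_classes Number of classes K (default 4).
#' @param ffm_enabled Fuse stages 1-3 (`FALSE` reduces the model to two
#'   independent branches plus the concatenation head).
#' @param sop_L Newton-Schulz iteration count for the main head (default 8).
#' @param sop_reduce Optional channel count of a 1x1 reduction convolution
#'   before second-order pooling (`NULL` follows the concatenated width
#'   literally; reduction is recommended on desk hardware).
#' @param sop_mode `"sop"` for covariance pooling, `"gap"` to replace the
#'   main head's pooling by global average pooling (ablation switch).
#' @return A `hybrid_model` module.
#' @export
new_hybrid_model <- function(pvt_cfgs = pvt_tiny_configs(),
                             cnn_cfg = cnn_tiny_config(),
                             num_classes = 4L,
                             ffm_enabled = TRUE,
                             sop_L = 8L,
                             sop_reduce = NULL,
                             sop_mode = c("sop", "gap")) {
  sop_mode <- match.arg(sop_mode)
  dims <- vapply(pvt_cfgs, `[[`, integer(1), "embed_dim")
  plan <- cnn_cfg$plan
  c4 <- dims[4] + plan[4]
  c_sop <- if (is.null(sop_reduce)) c4 else as.integer(sop_reduce)
  feat_len <- if (sop_mode == "sop") (c_sop * (c_sop + 1L)) %/% 2L else c_sop
  new_layer("hybrid_model",
            pvt = new_pvt_branch(pvt_cfgs),
            cnn = new_cnn_branch(cnn_cfg),
            ffms = lapply(1:3, function(i) new_ffm(dims[i], plan[i])),
            reduce = if (!is.null(sop_reduce)) {
              new_layer("reduce_module",
                        conv = conv_layer(c4, c_sop, 1L, bias = FALSE),
                        bn = bn_layer(c_sop))
            } else NULL,
            fc_combine = linear_layer(feat_len, num_classes, init = "trunc"),
            fc_pvt = linear_layer(dims[4], num_classes, init = "trunc"),
            fc_cnn = linear_layer(plan[4], num_classes, init = "trunc"),
            num_classes = as.integer(num_classes),
            ffm_enabled = isTRUE(ffm_enabled),
            sop_L = as.integer(sop_L),
            sop_mode = sop_mode)
}

## graph-level forward; returns logit nodes and (optionally) the fused /
## unfused stage maps and the pre-head concatenated map for Grad-CAM
hybrid_forward_graph <- function(model, x, training = FALSE,
                                 collect_maps = FALSE) {
  x <- ag_const(x)
  xp <- x
  xc <- stem_forward(model$cnn$stem, x, training)
  maps <- if (collect_maps) list() else NULL
  for (i in 1:4) {
    xp <- pvt_stage_forward(model$pvt$stages[[i]], xp)
    xc <- cnn_stage_forward(model$cnn$stages[[i]], xc, training)
    if (collect_maps) {
      maps[[paste0("stage", i, ".pvt.before")]] <- xp
      maps[[paste0("stage", i, ".cnn.before")]] <- xc
    }
    if (i < 4 && model$ffm_enabled) {
      fused <- ffm_forward(model$ffms[[i]], xp, xc)
      xp <- fused$pvt
      xc <- fused$cnn
      if (collect_maps) {
        maps[[paste0("stage", i, ".pvt.after")]] <- xp
        maps[[paste0("stage", i, ".cnn.after")]] <- xc
      }
    }
  }
  concat <- ag_concat_c(xp, xc)
  head_in <- if (!is.null(model$reduce)) {
    ag_relu(bn_fwd(model$reduce$bn, conv_fwd(model$reduce$conv, concat),
                   training))
  } else concat
  if (collect_maps) maps[["head.input"]] <- head_in
  feats <- if (model$sop_mode == "sop") {
    graph_second_order_pool(head_in, L = model$sop_L)
  } else {
    ag_gap(head_in)
  }
  list(logits_pvt = linear_fwd(model$fc_pvt, ag_gap(xp)),
       logits_cnn = linear_fwd(model$fc_cnn, ag_gap(xc)),
       logits_combine = linear_fwd(model$fc_combine, feats),
       head_input = head_in,
       maps = maps)
}

#' Forward pass of the hybrid model
#'
#' Runs both branches stage-by-stage with fusion after stages 1-3, the
#' stage-4 channel concatenation, and all three heads.  At inference the
#' model's prediction is the argmax of `logits_combine` (the main head);
#' the auxiliary heads only contribute to the training objective.
#'
#' @param model A `hybrid_model`.
#' @param image Array `(3, H, W, N)` of normalized values.
#' @param training Use batch statistics in batch normalization.
#' @return List with `logits_pvt`, `logits_cnn`, `logits_combine`
#'   (matrices `(K, N)`) and `probs` (softmax of the main head, `(N, K)`).
#' @export
hybrid_forward <- function(model, image, training = FALSE) {
  out <- ag_no_grad(hybrid_forward_graph(model, image, training = training))
  lc <- out$logits_combine$value
  lp <- exp(log_softmax_cols(lc))
  list(logits_pvt = out$logits_pvt$value,
       logits_cnn = out$logits_cnn$value,
       logits_combine = lc,
       probs = t(lp))
}

#' Predict classes for an image batch
#'
#' @param model A `hybrid_model`.
#' @param image Array `(3, H, W, N)`.
#' @return List with `class` (integer labels `1..K`) and `probs` `(N, K)`.
#' @export
hybrid_predict <- function(model, image) {
  out <- hybrid_forward(model, image, training = FALSE)
  list(class = apply(out$logits_combine, 2, which.max), probs = out$probs)
}
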