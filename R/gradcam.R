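## Grad-CAM class-activation maps and per-stage feature-map dumps.

## bilinear upsample of a single-channel matrix to h x w
upsample_bilinear <- function(m, h, w) {
  EBImage::imageData(EBImage::resize(EBImage::Image(m), w = h, h = w))
}

heat_colormap <- function(v) {
  ## simple blue -> green -> red map on [0,1]
  r <- pmin(pmax(1.5 - abs(4 * v - 3), 0), 1)
  g <- pmin(pmax(1.5 - abs(4 * v - 2), 0), 1)
  b <- pmin(pmax(1.5 - abs(4 * v - 1), 0), 1)
  array(c(r, g, b), c(dim(v), 3L))
}

#' Gradient-weighted class activation map
#'
#' Backpropagates the main-head logit of a target class to a chosen
#' spatial feature map, weights the map's channels by their spatially
#' averaged gradients, rectifies, min-max normalizes to `[0, 1]`, and
#' bilinearly upsamples to the input size.
#'
#' @param mc A `hybrid_checkpoint`, RDS path, or list with `model` and
#'   `config`.
#' @param img Raw H x W x 3 image in `[0, 1]` (the deterministic test
#'   transform is applied).
#' @param target_class Severity grade 0..K-1.
#' @param layer Which map to explain: `"cnn_stage4"` (default; the
#'   convolutional branch gives the crispest spatial gradients),
#'   `"pvt_stage4"`, or `"head_input"` (post-concatenation).
#' @param overlay_path Optional path for an overlay PNG.
#' @return List with `heatmap` (crop x crop matrix in `[0, 1]`) and
#'   `overlay` (H x W x 3 array).
#' @export
gradcam_heatmap <- function(mc, img, target_class, layer = "cnn_stage4",
                            overlay_path = NULL) {
  if (inherits(mc, "hybrid_checkpoint") || is.character(mc)) {
    mc <- load_checkpoint(mc)
  }
  sel <- c(cnn_stage4 = "stage4.cnn.before", pvt_stage4 = "stage4.pvt.before",
           head_input = "head.input")[layer]
  if (is.na(sel)) stop("unknown layer '", layer, "'")
  x <- geom_test(if (mc$config$augment$clahe) {
    clahe_enhance(img, mc$config$augment$clahe_clip,
                  mc$config$augment$clahe_tiles)
  } else img, mc$config$augment)
  xb <- array(x, c(dim(x), 1L))
  ag_tape_start()
  out <- hybrid_forward_graph(mc$model, xb, training = FALSE,
                              collect_maps = TRUE)
  node <- out$maps[[sel]]
  node$retain <- TRUE
  score <- ag_pick(out$logits_combine, as.integer(target_class) + 1L, 1L)
  ag_backward(score)
  g <- node$grad
  a <- node$value
  ag_tape_stop()
  d <- dim(a)
  C <- d[1]; S <- d[2] * d[3]
  wts <- rowMeans(matrix(g, C))
  cam <- matrix(colSums(matrix(a, C) * wts), d[2], d[3])
  cam <- pmax(cam, 0)
  rng <- range(cam)
  if (diff(rng) > 0) cam <- (cam - rng[1]) / diff(rng) else cam[] <- 0
  side <- mc$config$augment$crop
  heat <- upsample_bilinear(cam, side, side)
  heat <- pmin(pmax(heat, 0), 1)
  base <- resize_rgb(img, side)
  overlay <- 0.5 * base + 0.5 * heat_colormap(heat)
  if (!is.null(overlay_path)) png::writePNG(overlay, overlay_path)
  list(heatmap = heat, overlay = overlay)
}

## tile the first n channels of a (C, H, W) map into a grid image,
## each channel min-max normalized
channel_grid <- function(map, n = 16L) {
  C <- dim(map)[1]
  n <- min(n, C)
  ncol_g <- ceiling(sqrt(n))
  nrow_g <- ceiling(n / ncol_g)
  h <- dim(map)[2]; w <- dim(map)[3]
  out <- matrix(0, nrow_g * h, ncol_g * w)
  for (i in seq_len(n)) {
    ch <- map[i, , ]
    rng <- range(ch)
    if (diff(rng) > 0) ch <- (ch - rng[1]) / diff(rng)
    r <- (i - 1L) %/% ncol_g
    cc <- (i - 1L) %% ncol_g
    out[r * h + seq_len(h), cc * w + seq_len(w)] <- ch
  }
  out
}

#' Dump per-stage feature maps before and after fusion
#'
#' Writes channel-grid PNGs for both branches: stages 1-3 before and
#' after the fusion module, stage 4 before only (no fusion is applied at
#' stage 4); with fusion disabled the before/after grids are identical.
#'
#' @param mc Checkpoint, RDS path, or list with `model` and `config`.
#' @param img Raw H x W x 3 image in `[0, 1]`.
#' @param dir Output directory.
#' @param n_channels Channels per grid (default 16).
#' @return Character vector of written files.
#' @export
dump_feature_maps <- function(mc, img, dir, n_channels = 16L) {
  if (inherits(mc, "hybrid_checkpoint") || is.character(mc)) {
    mc <- load_checkpoint(mc)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  x <- geom_test(if (mc$config$augment$clahe) {
    clahe_enhance(img, mc$config$augment$clahe_clip,
                  mc$config$augment$clahe_tiles)
  } else img, mc$config$augment)
  xb <- array(x, c(dim(x), 1L))
  out <- ag_no_grad(hybrid_forward_graph(mc$model, xb, training = FALSE,
                                         collect_maps = TRUE))
  files <- character(0)
  for (nm in names(out$maps)) {
    if (nm == "head.input") next
    a <- out$maps[[nm]]$value
    grid <- channel_grid(array(a[, , , 1], dim(a)[1:3]), n_channels)
    fn <- file.path(dir, paste0(gsub("\\.", "_", nm), ".png"))
    png::writePNG(grid, fn)
    files <- c(files, fn)
  }
  files
}
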