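## Image I/O, CLAHE preprocessing, train/test transforms, stratified
## splitting, and a seedable synthetic 4-class endoscopy-like image
## generator.  Images are H x W x 3 arrays in [0, 1] on disk/IO; model
## input uses channel-first (3, H, W, N) arrays.

#' Augmentation / preprocessing specification
#'
#' @param flip_p Probability of each of horizontal and vertical flip
#'   (default 0.3).
#' @param resize Edge length images are resized to before cropping
#'   (default 256).
#' @param crop Side of the square crop fed to the network (default 224;
#'   random position at train time, centered at test time).
#' @param clahe Apply contrast-limited adaptive histogram equalization to
#'   the lightness channel before geometric transforms (default TRUE;
#'   applied deterministically to train and test images).
#' @param clahe_clip,clahe_tiles CLAHE clip limit and tile grid.
#' @param mean,std Per-channel normalization constants (default ImageNet
#'   statistics).
#' @return An `augment_spec` list.
#' @export
augment_spec <- function(flip_p = 0.3, resize = 256L, crop = 224L,
                         clahe = TRUE, clahe_clip = 2, clahe_tiles = 8L,
                         mean = c(0.485, 0.456, 0.406),
                         std = c(0.229, 0.224, 0.225)) {
  stopifnot(flip_p >= 0, flip_p <= 1, crop <= resize)
  structure(list(flip_p = flip_p, resize = as.integer(resize),
                 crop = as.integer(crop), clahe = isTRUE(clahe),
                 clahe_clip = clahe_clip,
                 clahe_tiles = as.integer(clahe_tiles),
                 mean = mean, std = std),
            class = "augment_spec")
}

#' CLAHE contrast enhancement of an RGB image
#'
#' Converts to CIELAB, applies contrast-limited adaptive histogram
#' equalization to the lightness channel (via EBImage), and recombines.
#' Images whose side is not divisible by the tile grid are padded by edge
#' replication for the enhancement and cropped back.
#'
#' @param img H x W x 3 array with values in `[0, 1]`.
#' @param clip Clip limit (default 2).
#' @param tiles Tile grid (number of tiles per side, default 8).
#' @return Enhanced image, same shape and range.
#' @export
clahe_enhance <- function(img, clip = 2, tiles = 8L) {
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L) stop("input must be an H x W x 3 RGB array")
  rgb <- matrix(img, ncol = 3L)
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  L <- matrix(lab[, 1] / 100, d[1], d[2])
  if (diff(range(L)) < 1e-8) return(img)  # constant: nothing to equalize
  pad_h <- (tiles - d[1] %% tiles) %% tiles
  pad_w <- (tiles - d[2] %% tiles) %% tiles
  Lp <- L
  if (pad_h > 0) Lp <- rbind(Lp, Lp[rep(nrow(Lp), pad_h), , drop = FALSE])
  if (pad_w > 0) Lp <- cbind(Lp, Lp[, rep(ncol(Lp), pad_w), drop = FALSE])
  Le <- EBImage::clahe(EBImage::Image(Lp), nx = tiles, ny = tiles,
                       limit = clip)
  Le <- EBImage::imageData(Le)[seq_len(d[1]), seq_len(d[2])]
  lab[, 1] <- pmin(pmax(as.vector(Le), 0), 1) * 100
  out <- grDevices::convertColor(lab, from = "Lab", to = "sRGB")
  array(pmin(pmax(out, 0), 1), d)
}

## bilinear resize to h x w via EBImage
resize_rgb <- function(img, h, w = h) {
  out <- EBImage::imageData(EBImage::resize(EBImage::Image(img, colormode = "Color"),
                                            w = h, h = w))
  array(pmin(pmax(out, 0), 1), c(h, w, 3L))
}

crop_rgb <- function(img, top, left, size) {
  img[top:(top + size - 1L), left:(left + size - 1L), , drop = FALSE]
}

## (H, W, 3) in [0,1] -> channel-first normalized (3, H, W)
normalize_chw <- function(img, mean, std) {
  x <- aperm(img, c(3L, 1L, 2L))
  (x - mean) / std
}

#' Training-time transform
#'
#' CLAHE, resize, random square crop, random horizontal then vertical
#' flip (probability `spec$flip_p` each), channel normalization.  All
#' randomness is drawn from the current RNG state, so a seeded caller is
#' fully reproducible.
#'
#' @param img H x W x 3 array in `[0, 1]`.
#' @param spec An [augment_spec()].
#' @return Normalized array `(3, crop, crop)`.
#' @export
train_transform <- function(img, spec = augment_spec()) {
  if (spec$clahe) img <- clahe_enhance(img, spec$clahe_clip, spec$clahe_tiles)
  img <- resize_rgb(img, spec$resize)
  span <- spec$resize - spec$crop
  top <- 1L + if (span > 0) sample.int(span + 1L, 1L) - 1L else 0L
  left <- 1L + if (span > 0) sample.int(span + 1L, 1L) - 1L else 0L
  img <- crop_rgb(img, top, left, spec$crop)
  if (stats::runif(1) < spec$flip_p) img <- img[, ncol(img):1, , drop = FALSE]
  if (stats::runif(1) < spec$flip_p) img <- img[nrow(img):1, , , drop = FALSE]
  normalize_chw(img, spec$mean, spec$std)
}

#' Test-time transform (deterministic)
#'
#' CLAHE, resize, center crop, channel normalization.
#'
#' @inheritParams train_transform
#' @return Normalized array `(3, crop, crop)`.
#' @export
test_transform <- function(img, spec = augment_spec()) {
  if (spec$clahe) img <- clahe_enhance(img, spec$clahe_clip, spec$clahe_tiles)
  img <- resize_rgb(img, spec$resize)
  off <- (spec$resize - spec$crop) %/% 2L
  img <- crop_rgb(img, 1L + off, 1L + off, spec$crop)
  normalize_chw(img, spec$mean, spec$std)
}

#' Stratified train/test split or k-fold assignment
#'
#' @param manifest Data frame with columns `filename` and `label` (0-3).
#' @param ratio Training fraction for a two-way split (default 0.8).
#' @param seed Integer seed for the shuffle.
#' @param k If not `NULL`, assign stratified folds `fold_1..fold_k`
#'   instead of a two-way split.
#' @return The manifest with a `split` column; per-class proportions are
#'   preserved to within one image.
#' @export
stratified_split <- function(manifest, ratio = 0.8, seed = 1L, k = NULL) {
  stopifnot(all(c("filename", "label") %in% names(manifest)))
  set.seed(seed)
  manifest$split <- NA_character_
  for (cl in sort(unique(manifest$label))) {
    idx <- which(manifest$label == cl)
    idx <- idx[sample.int(length(idx))]
    if (is.null(k)) {
      ntr <- round(ratio * length(idx))
      manifest$split[idx[seq_len(ntr)]] <- "train"
      if (ntr < length(idx)) {
        manifest$split[idx[(ntr + 1L):length(idx)]] <- "test"
      }
    } else {
      if (length(idx) < k) {
        stop("class ", cl, " has fewer images (", length(idx),
             ") than folds (", k, ")")
      }
      fold <- rep(seq_len(k), length.out = length(idx))
      manifest$split[idx] <- paste0("fold_", fold)
    }
  }
  manifest
}

#' Read / write a dataset manifest CSV (`filename,label,split`)
#'
#' @param path CSV path.
#' @return Data frame with columns filename, label and (if present) split.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("filename", "label") %in% names(m)))
  m
}

#' @rdname read_manifest
#' @param manifest Data frame to write.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(manifest)
}
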