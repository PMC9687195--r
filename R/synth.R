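## Seedable synthetic endoscopy-like image generator.  Four classes mimic
## the MES feature hierarchy: grade 0 shows a clear vascular pattern
## (thin dark-red curves), grade 1 diffuse erythema blotches with a
## decreased vascular pattern, grade 2 marked erythema with bright
## erosion-like spots, grade 3 a large dark-red bleeding/ulceration
## region.  All randomness is drawn from the current R RNG, so a fixed
## seed reproduces images byte-for-byte.

#' Specification of the synthetic dataset generator
#'
#' Defaults emulate a desk-scale version of a severity-graded endoscopy
#' dataset: 200 images per class at 64 x 64.
#'
#' @param n_per_class Images per class (default 200).
#' @param size Square image side in pixels (default 64).
#' @param seed Integer seed; identical spec + seed gives byte-identical
#'   images.
#' @param noise_sd Gaussian pixel noise standard deviation (default 0.02).
#' @param vessel_count Range of vessel curves for grade 0.
#' @param blotch_count Range of erythema blotches for grades 1-2.
#' @param spot_count Range of bright erosion spots for grade 2.
#' @param dark_fraction Range of the dark-red region area fraction for
#'   grade 3.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_per_class = 200L, size = 64L, seed = 1L,
                           noise_sd = 0.02,
                           vessel_count = c(8L, 14L),
                           blotch_count = c(6L, 10L),
                           spot_count = c(6L, 12L),
                           dark_fraction = c(0.25, 0.40)) {
  structure(list(n_per_class = as.integer(n_per_class),
                 size = as.integer(size), seed = as.integer(seed),
                 noise_sd = noise_sd, vessel_count = vessel_count,
                 blotch_count = blotch_count, spot_count = spot_count,
                 dark_fraction = dark_fraction),
            class = "synthetic_spec")
}

rint <- function(range) {
  if (range[1] >= range[2]) return(as.integer(range[1]))
  as.integer(sample(seq(range[1], range[2]), 1L))
}

## radial lumen-gradient mucosa background
synth_background <- function(size) {
  cy <- stats::runif(1, 0.35, 0.65) * size
  cx <- stats::runif(1, 0.35, 0.65) * size
  rr <- matrix(seq_len(size), size, size)
  cc <- matrix(seq_len(size), size, size, byrow = TRUE)
  r <- sqrt((rr - cy)^2 + (cc - cx)^2) / (0.75 * size)
  base <- c(0.82, 0.55, 0.50) + stats::rnorm(3, sd = 0.03)
  f <- 0.35 + 0.62 * pmin(r, 1)
  img <- array(0, c(size, size, 3L))
  for (ch in 1:3) img[, , ch] <- base[ch] * f
  img
}

blend <- function(img, alpha, color) {
  for (ch in 1:3) {
    img[, , ch] <- img[, , ch] * (1 - alpha) + color[ch] * alpha
  }
  img
}

## thin random-walk curves (vascular pattern)
synth_vessels <- function(size, n, strength) {
  a <- matrix(0, size, size)
  for (v in seq_len(n)) {
    y <- stats::runif(1, 2, size - 1)
    x <- stats::runif(1, 2, size - 1)
    th <- stats::runif(1, 0, 2 * pi)
    for (s in seq_len(as.integer(size * 1.5))) {
      th <- th + stats::rnorm(1, sd = 0.35)
      y <- y + sin(th); x <- x + cos(th)
      iy <- round(y); ix <- round(x)
      if (iy < 1 || iy > size || ix < 1 || ix > size) break
      a[iy, ix] <- pmin(a[iy, ix] + strength, 1)
    }
  }
  a
}

## sum of Gaussian bumps, used for erythema blotches and smooth fields
synth_field <- function(size, n, sigma_range, amp_range = c(1, 1)) {
  rr <- matrix(seq_len(size), size, size)
  cc <- matrix(seq_len(size), size, size, byrow = TRUE)
  f <- matrix(0, size, size)
  for (b in seq_len(n)) {
    cy <- stats::runif(1, 1, size)
    cx <- stats::runif(1, 1, size)
    sg <- stats::runif(1, sigma_range[1], sigma_range[2]) * size
    amp <- stats::runif(1, amp_range[1], amp_range[2])
    f <- f + amp * exp(-((rr - cy)^2 + (cc - cx)^2) / (2 * sg^2))
  }
  f
}

synth_spots <- function(img, size, n) {
  rr <- matrix(seq_len(size), size, size)
  cc <- matrix(seq_len(size), size, size, byrow = TRUE)
  for (s in seq_len(n)) {
    cy <- stats::runif(1, 3, size - 2)
    cx <- stats::runif(1, 3, size - 2)
    rad <- stats::runif(1, 1.2, 2.8)
    a <- 0.85 * exp(-((rr - cy)^2 + (cc - cx)^2) / (2 * rad^2))
    img <- blend(img, a, c(0.96, 0.93, 0.86))
  }
  img
}

#' Generate one synthetic image of a given severity grade
#'
#' Uses the current RNG state; callers control reproducibility via
#' `set.seed()`.
#'
#' @param class Severity grade 0-3.
#' @param spec A [synthetic_spec()].
#' @return List with `img` (H x W x 3 array in `[0, 1]`) and, for grade 3,
#'   `mask` (logical H x W matrix of the dark-red region), else `NULL`.
#' @export
synth_image <- function(class, spec = synthetic_spec()) {
  stopifnot(class %in% 0:3)
  size <- spec$size
  img <- synth_background(size)
  mask <- NULL
  if (class == 0L) {
    a <- synth_vessels(size, rint(spec$vessel_count), 0.65)
    img <- blend(img, a * 0.6, c(0.58, 0.14, 0.16))
  } else if (class == 1L) {
    f <- synth_field(size, rint(spec$blotch_count), c(0.06, 0.14))
    w <- pmin(f, 1)
    img[, , 1] <- img[, , 1] + 0.22 * w
    img[, , 2] <- img[, , 2] - 0.14 * w
    img[, , 3] <- img[, , 3] - 0.10 * w
    a <- synth_vessels(size, rint(c(2L, 4L)), 0.4)
    img <- blend(img, a * 0.22, c(0.58, 0.14, 0.16))
  } else if (class == 2L) {
    f <- synth_field(size, rint(spec$blotch_count), c(0.08, 0.16))
    w <- pmin(f, 1)
    img[, , 1] <- img[, , 1] + 0.26 * w
    img[, , 2] <- img[, , 2] - 0.18 * w
    img[, , 3] <- img[, , 3] - 0.12 * w
    img <- synth_spots(img, size, rint(spec$spot_count))
  } else {
    frac <- stats::runif(1, spec$dark_fraction[1], spec$dark_fraction[2])
    f <- synth_field(size, 6L, c(0.15, 0.30))
    thr <- stats::quantile(f, 1 - frac)
    mask <- f >= thr
    edge <- pmin(pmax((f - thr) / (0.15 * max(abs(f - thr), 1e-8)), 0), 1)
    img <- blend(img, 0.85 * edge, c(0.42, 0.06, 0.08))
  }
  img <- img + array(stats::rnorm(length(img), sd = spec$noise_sd), dim(img))
  list(img = array(pmin(pmax(img, 0), 1), dim(img)), mask = mask)
}

#' Generate a synthetic dataset on disk
#'
#' Writes PNG images and a `manifest.csv` (`filename,label`) to `dir`;
#' grade-3 region masks go to `dir/masks/` when `write_masks = TRUE`.
#' Running twice with the same spec produces byte-identical files.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @param write_masks Write grade-3 dark-region masks (default TRUE).
#' @return The manifest data frame (invisibly written to
#'   `dir/manifest.csv`).
#' @export
generate_synthetic_dataset <- function(spec = synthetic_spec(), dir,
                                       write_masks = TRUE) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create directory ", dir)
  }
  if (write_masks) dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  set.seed(spec$seed)
  rows <- list()
  for (cl in 0:3) {
    for (i in seq_len(spec$n_per_class)) {
      res <- synth_image(cl, spec)
      fn <- sprintf("class%d_%04d.png", cl, i)
      png::writePNG(res$img, file.path(dir, fn))
      if (write_masks && !is.null(res$mask)) {
        png::writePNG(res$mask * 1, file.path(dir, "masks", fn))
      }
      rows[[length(rows) + 1L]] <- data.frame(filename = fn, label = cl)
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  manifest
}
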