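test_that("CLAHE keeps range, fixes constants, and flattens low-contrast histograms", {
  flat <- array(0.5, c(64, 64, 3))
  expect_identical(clahe_enhance(flat), flat)  # no contrast to amplify
  r <- matrix(seq(0.35, 0.65, length.out = 64), 64, 64)
  ramp <- array(c(r, r, r), c(64, 64, 3))
  out <- clahe_enhance(ramp, clip = 4)
  expect_true(all(out >= 0 & out <= 1))
  expect_identical(dim(out), dim(ramp))
  # equalization spreads intensities: dispersion does not shrink
  expect_gte(sd(out), sd(ramp) * 0.95)
  entropy <- function(x) {
    h <- hist(x, breaks = seq(0, 1, by = 0.02), plot = FALSE)$counts
    p <- h[h > 0] / sum(h)
    -sum(p * log(p))
  }
  expect_gt(entropy(out[, , 1]), entropy(ramp[, , 1]) - 1e-6)
  expect_identical(out, clahe_enhance(ramp, clip = 4))  # deterministic
  expect_error(clahe_enhance(matrix(0.5, 8, 8)), "RGB")
})

test_that("the test transform is deterministic with a centered crop", {
  set.seed(1)
  res <- synth_image(1, synthetic_spec(size = 96))
  spec <- augment_spec(resize = 256, crop = 224, clahe = FALSE)
  out <- test_transform(res$img, spec)
  expect_equal(dim(out), c(3, 224, 224))
  expect_identical(out, test_transform(res$img, spec))
  expect_true(all(is.finite(out)))
  # center crop offset is (256 - 224) / 2 = 16 on both axes
  full <- pyrfuse:::resize_rgb(res$img, 256)
  manual <- pyrfuse:::normalize_chw(full[17:240, 17:240, , drop = FALSE],
                                    spec$mean, spec$std)
  expect_identical(out, manual)
})

test_that("the train transform is reproducible under a seed and flips twice to identity", {
  set.seed(2)
  res <- synth_image(2, synthetic_spec())
  spec <- augment_spec(flip_p = 0, resize = 72, crop = 64, clahe = FALSE)
  set.seed(10)
  a <- train_transform(res$img, spec)
  set.seed(10)
  b <- train_transform(res$img, spec)
  expect_identical(a, b)
  expect_equal(dim(a), c(3, 64, 64))
  # forced double flip restores the image
  img <- res$img
  flipped <- img[, ncol(img):1, , drop = FALSE]
  expect_identical(flipped[, ncol(img):1, , drop = FALSE], img)
  # default flip probability follows the protocol
  expect_equal(augment_spec()$flip_p, 0.3)
  expect_equal(augment_spec()$resize, 256L)
  expect_equal(augment_spec()$crop, 224L)
})

test_that("stratified splits preserve class proportions to within one image", {
  man <- data.frame(filename = sprintf("f%03d.png", 1:220),
                    label = rep(0:3, c(100, 60, 40, 20)))
  sp <- stratified_split(man, 0.8, seed = 5)
  for (cl in 0:3) {
    n <- sum(man$label == cl)
    ntr <- sum(sp$label == cl & sp$split == "train")
    expect_lte(abs(ntr - 0.8 * n), 1)
  }
  expect_false(any(duplicated(sp$filename)))
  sp2 <- stratified_split(man, 0.8, seed = 5)
  expect_identical(sp, sp2)
  sp3 <- stratified_split(man, 0.8, seed = 6)
  expect_false(identical(sp$split, sp3$split))
})

test_that("k-fold assignment partitions every class across folds", {
  man <- data.frame(filename = sprintf("f%03d.png", 1:100),
                    label = rep(0:3, each = 25))
  sp <- stratified_split(man, seed = 1, k = 5)
  expect_setequal(unique(sp$split), paste0("fold_", 1:5))
  expect_true(all(table(sp$split) == 20))
  for (cl in 0:3) {
    expect_true(all(table(sp$split[sp$label == cl]) == 5))
  }
  tiny <- data.frame(filename = c("a.png", "b.png"), label = c(0, 0))
  expect_error(stratified_split(tiny, seed = 1, k = 5), "fewer images")
})

test_that("the generator is byte-deterministic and honors requested counts", {
  spec <- synthetic_spec(n_per_class = 3, size = 48, seed = 21)
  d1 <- file.path(tempdir(), "synth_det_a")
  d2 <- file.path(tempdir(), "synth_det_b")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- generate_synthetic_dataset(spec, d1)
  m2 <- generate_synthetic_dataset(spec, d2)
  expect_equal(as.vector(table(m1$label)), rep(3, 4))
  for (f in m1$filename) {
    expect_identical(readBin(file.path(d1, f), "raw", 5e5),
                     readBin(file.path(d2, f), "raw", 5e5))
  }
  # grade-3 masks exist and mark a plausible fraction of the image
  m3 <- m1$filename[m1$label == 3]
  mask <- png::readPNG(file.path(d1, "masks", m3[1]))
  expect_true(mean(mask > 0.5) > 0.15 && mean(mask > 0.5) < 0.55)
  # a different seed changes the images
  m_other <- generate_synthetic_dataset(synthetic_spec(3, 48, seed = 22),
                                        file.path(tempdir(), "synth_det_c"))
  expect_false(identical(readBin(file.path(d1, m1$filename[1]), "raw", 5e5),
                         readBin(file.path(tempdir(), "synth_det_c",
                                           m1$filename[1]), "raw", 5e5)))
})

test_that("a pixel-statistics baseline separates the synthetic classes", {
  skip_if_not_installed("nnet")
  dat <- micro_dataset(60L)
  feats <- t(vapply(seq_len(nrow(dat$manifest)), function(i) {
    img <- png::readPNG(file.path(dat$dir, dat$manifest$filename[i]))
    c(apply(img, 3, mean), apply(img, 3, stats::sd))
  }, numeric(6)))
  df <- data.frame(y = factor(dat$manifest$label), feats)
  trd <- df[dat$manifest$split == "train", ]
  ted <- df[dat$manifest$split == "test", ]
  fit <- nnet::multinom(y ~ ., trd, trace = FALSE, maxit = 200)
  acc <- mean(predict(fit, ted) == ted$y)
  expect_gte(acc, 0.7)
})

test_that("manifest round-trips through CSV", {
  man <- data.frame(filename = c("a.png", "b.png"), label = c(0L, 3L),
                    split = c("train", "test"))
  p <- tempfile(fileext = ".csv")
  write_manifest(man, p)
  expect_equal(read_manifest(p), man)
})
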