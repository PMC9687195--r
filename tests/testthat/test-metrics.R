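test_that("label smoothing reduces to plain cross-entropy at eps = 0", {
  set.seed(1)
  for (i in 1:20) {
    N <- sample(1:8, 1); K <- sample(2:5, 1)
    v <- matrix(rnorm(N * K, sd = 2), N, K)
    y <- sample(K, N, replace = TRUE)
    p <- exp(v - apply(v, 1, max))
    p <- p / rowSums(p)
    ce <- -mean(log(p[cbind(seq_len(N), y)]))
    expect_equal(label_smoothing_ce(v, y, eps = 0), ce, tolerance = 1e-7)
  }
})

test_that("uniform logits give log K for any smoothing coefficient", {
  for (eps in c(0, 0.1, 0.5)) {
    expect_equal(label_smoothing_ce(matrix(0, 3, 4), c(1, 2, 4), eps),
                 log(4), tolerance = 1e-12)
  }
})

test_that("the single-sample smoothed loss matches the hand evaluation", {
  # softmax(2,0,0,0) = (0.7112, 0.0963, 0.0963, 0.0963);
  # 0.9 * 0.3408 + 0.1 * 1.8408 = 0.4908
  v <- matrix(c(2, 0, 0, 0), 1)
  expect_equal(label_smoothing_ce(v, 1L, eps = 0.1), 0.4908, tolerance = 1e-3)
  expect_error(label_smoothing_ce(v, 5L), "labels")
  expect_error(label_smoothing_ce(matrix(c(Inf, 0), 1), 1L), "finite")
})

test_that("the smoothed loss is convex in the logits", {
  set.seed(2)
  for (i in 1:25) {
    v1 <- matrix(rnorm(8), 2, 4); v2 <- matrix(rnorm(8), 2, 4)
    y <- sample(4, 2, replace = TRUE)
    mid <- label_smoothing_ce((v1 + v2) / 2, y, 0.1)
    avg <- (label_smoothing_ce(v1, y, 0.1) + label_smoothing_ce(v2, y, 0.1)) / 2
    expect_lte(mid, avg + 1e-12)
  }
})

test_that("the loss is invariant to permuting the batch", {
  set.seed(3)
  v <- matrix(rnorm(20), 5, 4)
  y <- sample(4, 5, replace = TRUE)
  p <- sample(5)
  expect_equal(label_smoothing_ce(v, y, 0.1),
               label_smoothing_ce(v[p, ], y[p], 0.1))
})

test_that("the total objective is the exact weighted sum", {
  expect_equal(total_loss(c(1, 1, 1), c(1, 1, 1)), 3)
  a <- 0.3; b <- 1.7; cc <- 0.4
  expect_equal(total_loss(c(a, b, cc)), a + b + 2 * cc)  # default 1:1:2
  expect_equal(total_loss(c(5, 5, 5), c(0, 0, 0)), 0)
  expect_error(total_loss(c(1, 1, 1), c(-1, 1, 1)), "non-negative")
})

test_that("confusion matrices count correctly", {
  cm <- confusion_matrix(c(1, 1, 2, 2), c(1, 2, 2, 2), 2)
  expect_equal(unname(cm), rbind(c(1, 1), c(0, 2)))
  expect_equal(sum(cm), 4)
  perfect <- confusion_matrix(c(1, 2, 3, 4), c(1, 2, 3, 4), 4)
  expect_true(all(perfect[upper.tri(perfect)] == 0) &&
                all(perfect[lower.tri(perfect)] == 0))
  expect_error(confusion_matrix(1:3, 1:2, 3), "equal length")
})

test_that("per-class rates reproduce the hand-computed worked example", {
  pm <- per_class_metrics(rbind(c(1, 1), c(0, 2)))
  c1 <- pm$per_class[1, ]
  expect_equal(c1$SEN, 0.5)
  expect_equal(c1$SPE, 1.0)
  expect_equal(c1$PPV, 1.0)
  expect_equal(c1$NPV, 2 / 3)
  expect_equal(c1$ACC, 0.75)
  expect_equal(c1$F1, 2 / 3)
  expect_equal(pm$total_accuracy, 0.75)
  # diagonal confusion: every metric 1
  pmd <- per_class_metrics(diag(c(3, 2, 4)))
  expect_true(all(abs(as.matrix(pmd$per_class[, c("ACC", "SEN", "SPE", "PPV",
                                                  "NPV", "F1")]) - 1) < 1e-12))
  expect_equal(pmd$total_accuracy, 1)
})

test_that("zero-denominator rates are flagged as undefined rather than zeroed", {
  # class 3 never true and never predicted
  cm <- rbind(c(2, 0, 0), c(0, 2, 0), c(0, 0, 0))
  pm <- per_class_metrics(cm)
  expect_true(is.na(pm$per_class$SEN[3]))
  expect_true(is.na(pm$per_class$PPV[3]))
  expect_true(pm$undefined[3, "SEN"] && pm$undefined[3, "PPV"])
  expect_false(any(pm$undefined[1:2, c("SEN", "PPV")]))
})

test_that("trapezoidal AUC matches the pair-counting oracle on small score sets", {
  # perfectly separating scores
  s <- cbind(c(0.9, 0.8, 0.1, 0.2), c(0.1, 0.2, 0.9, 0.8))
  expect_equal(unname(roc_auc(s, c(1, 1, 2, 2))), c(1, 1))
  # label-independent scores
  s2 <- matrix(0.5, 6, 2)
  expect_equal(unname(roc_auc(s2, c(1, 2, 1, 2, 1, 2))), c(0.5, 0.5))
  # one inversion among eight positive-negative pairs
  sc <- c(0.9, 0.8, 0.6, 0.4, 0.5, 0.3)
  pos <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  expect_equal(pair_auc(sc, pos), 0.875)
  expect_equal(unname(roc_auc(cbind(sc, 1 - sc), ifelse(pos, 1, 2)))[1], 0.875)
  # randomized agreement with the oracle, N <= 12, with ties
  set.seed(4)
  for (i in 1:40) {
    N <- sample(2:12, 1)
    y <- sample(1:2, N, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- 3 - y[2]
    sc <- round(runif(N), 1)  # coarse grid forces ties
    expect_equal(unname(roc_auc(cbind(sc, 1 - sc), y))[1],
                 pair_auc(sc, y == 1), tolerance = 1e-12)
  }
  # degenerate single-class truth is flagged
  expect_true(is.na(roc_auc(cbind(c(0.4, 0.6), c(0.6, 0.4)), c(1, 1))[2]))
})

test_that("AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  for (i in 1:10) {
    y <- sample(1:2, 20, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- 3 - y[2]
    sc <- runif(20)
    ref <- as.numeric(pROC::auc(pROC::roc(y == 1, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(unname(roc_auc(cbind(sc, 1 - sc), y))[1], ref,
                 tolerance = 1e-10)
  }
})

test_that("reports serialize to the table layout and JSON", {
  set.seed(6)
  y <- sample(1:4, 40, replace = TRUE)
  pred <- y; pred[1:8] <- sample(1:4, 8, replace = TRUE)
  sc <- matrix(runif(160), 40, 4)
  sc <- sc / rowSums(sc)
  rep <- metrics_report(y, pred, sc, K = 4)
  tab <- metrics_table(rep)
  expect_equal(dim(tab), c(7L, 4L))  # six rates + AUC by class
  expect_equal(rownames(tab)[1:6], c("ACC", "SEN", "SPE", "PPV", "NPV", "F1"))
  tmp_json <- tempfile(fileext = ".json"); tmp_csv <- tempfile(fileext = ".csv")
  write_metrics_report(rep, tmp_json, tmp_csv)
  parsed <- jsonlite::fromJSON(tmp_json)
  expect_equal(parsed$total_accuracy, rep$total_accuracy)
  csv <- utils::read.csv(tmp_csv, check.names = FALSE)
  expect_equal(csv$metric[1:6], c("ACC", "SEN", "SPE", "PPV", "NPV", "F1"))
  expect_equal(sum(rep$confusion), 40)
})
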