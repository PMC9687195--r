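## Training / evaluation orchestration: SGD with momentum and the step
## learning-rate schedule, per-epoch logging, checkpointing, stratified
## cross-validation.

new_sgd_state <- function(params) {
  vel <- lapply(params, function(p) array(0, dim(p$value) %||% length(p$value)))
  names(vel) <- names(params)
  list(vel = vel)
}

## v <- m v + (grad + wd theta); theta <- theta - lr v
sgd_step <- function(params, state, lr, momentum, weight_decay) {
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.null(p$grad)) next
    g <- p$grad + weight_decay * p$value
    v <- momentum * state$vel[[nm]] + g
    state$vel[[nm]] <- v
    p$value <- p$value - lr * v
  }
  state
}

first_nonfinite_param <- function(params) {
  for (nm in names(params)) {
    if (any(!is.finite(params[[nm]]$value))) return(nm)
  }
  NULL
}

## read a manifest split into a preprocessed in-memory image list;
## CLAHE is deterministic and applied once here
load_split_images <- function(manifest, images_dir, split, aug) {
  rows <- manifest[is.na(split) | manifest$split == split, , drop = FALSE]
  imgs <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    img <- png::readPNG(file.path(images_dir, rows$filename[i]))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
    if (aug$clahe) img <- clahe_enhance(img, aug$clahe_clip, aug$clahe_tiles)
    imgs[[i]] <- img
  }
  list(imgs = imgs, labels = as.integer(rows$label) + 1L, rows = rows)
}

## geometric part of the train transform (CLAHE already applied)
geom_train <- function(img, aug) {
  img <- resize_rgb(img, aug$resize)
  span <- aug$resize - aug$crop
  top <- 1L + if (span > 0) sample.int(span + 1L, 1L) - 1L else 0L
  left <- 1L + if (span > 0) sample.int(span + 1L, 1L) - 1L else 0L
  img <- crop_rgb(img, top, left, aug$crop)
  if (stats::runif(1) < aug$flip_p) img <- img[, ncol(img):1, , drop = FALSE]
  if (stats::runif(1) < aug$flip_p) img <- img[nrow(img):1, , , drop = FALSE]
  normalize_chw(img, aug$mean, aug$std)
}

geom_test <- function(img, aug) {
  img <- resize_rgb(img, aug$resize)
  off <- (aug$resize - aug$crop) %/% 2L
  img <- crop_rgb(img, 1L + off, 1L + off, aug$crop)
  normalize_chw(img, aug$mean, aug$std)
}

stack_batch <- function(lst) {
  d <- dim(lst[[1]])
  out <- array(0, c(d, length(lst)))
  for (i in seq_along(lst)) out[, , , i] <- lst[[i]]
  out
}

## one optimization step; returns loss and combine-head predictions
train_step <- function(model, params, state, xb, yb, config, lr) {
  ag_tape_start()
  out <- hybrid_forward_graph(model, xb, training = TRUE)
  w <- config$loss_weights
  eps <- config$label_smooth_eps
  tot <- ag_wsum(list(ag_ls_ce(out$logits_pvt, yb, eps),
                      ag_ls_ce(out$logits_cnn, yb, eps),
                      ag_ls_ce(out$logits_combine, yb, eps)),
                 w)
  if (!is.finite(tot$value)) {
    bad <- first_nonfinite_param(params)
    ag_tape_stop()
    stop("non-finite loss encountered",
         if (!is.null(bad)) paste0(" (first non-finite parameter: ", bad, ")"))
  }
  ag_zero_grads(params)
  ag_backward(tot)
  ag_tape_stop()
  state <- sgd_step(params, state, lr, config$momentum, config$weight_decay)
  list(state = state, loss = as.numeric(tot$value),
       pred = apply(out$logits_combine$value, 2, which.max))
}

#' Train the hybrid model
#'
#' Optimizes the three-branch label-smoothed cross-entropy
#' \eqn{\alpha L_{pvt} + \beta L_{cnn} + \gamma L_{combine}} with SGD
#' under the step learning-rate schedule, logging per-epoch training loss
#' and accuracy (and validation accuracy when a validation split is
#' present), and keeps the checkpoint with the best validation accuracy
#' (falling back to the final epoch when no validation split exists).
#'
#' @param config A [run_config()].
#' @param manifest Manifest data frame with `filename`, `label` and a
#'   `split` column.
#' @param images_dir Directory holding the images.
#' @param train_split,val_split Split tags (defaults "train" / "test";
#'   `val_split = NULL` skips validation).
#' @param checkpoint_path Optional path to save the best checkpoint (RDS).
#' @param log_path Optional JSONL per-epoch log path.
#' @param verbose Print per-epoch progress.
#' @return A `hybrid_checkpoint`: model weights and buffers, optimizer
#'   state, config, and the per-epoch `history` data frame.
#' @export
train <- function(config, manifest, images_dir,
                  train_split = "train", val_split = "test",
                  checkpoint_path = NULL, log_path = NULL, verbose = TRUE) {
  if (!("split" %in% names(manifest))) manifest$split <- train_split
  tr <- load_split_images(manifest, images_dir, train_split, config$augment)
  if (length(tr$imgs) == 0L) stop("empty training split")
  va <- if (!is.null(val_split) &&
            any(manifest$split == val_split)) {
    load_split_images(manifest, images_dir, val_split, config$augment)
  } else NULL
  model <- build_model(config)
  params <- collect_params(model)
  state <- new_sgd_state(params)
  set.seed(config$seed_train)
  n <- length(tr$imgs)
  bs <- config$batch_size
  history <- list()
  best <- list(acc = -Inf, ckpt = NULL)
  for (epoch in seq_len(config$epochs) - 1L) {
    lr <- lr_at_epoch(config, epoch)
    ord <- sample.int(n)
    ep_loss <- 0; ep_hits <- 0L
    nb <- 0L
    for (start in seq(1L, n, by = bs)) {
      take <- ord[start:min(start + bs - 1L, n)]
      xb <- stack_batch(lapply(tr$imgs[take], geom_train, aug = config$augment))
      yb <- tr$labels[take]
      st <- train_step(model, params, state, xb, yb, config, lr)
      state <- st$state
      ep_loss <- ep_loss + st$loss * length(take)
      ep_hits <- ep_hits + sum(st$pred == yb)
      nb <- nb + 1L
    }
    train_loss <- ep_loss / n
    train_acc <- ep_hits / n
    val_acc <- NA_real_
    if (!is.null(va)) {
      ev <- eval_images(model, va$imgs, va$labels, config)
      val_acc <- ev$total_accuracy
      if (val_acc >= best$acc) {
        best <- list(acc = val_acc,
                     ckpt = snapshot_checkpoint(model, state, config,
                                                epoch = epoch))
      }
    }
    history[[length(history) + 1L]] <-
      data.frame(epoch = epoch, lr = lr, train_loss = train_loss,
                 train_acc = train_acc, val_acc = val_acc)
    if (verbose) {
      message(sprintf("epoch %02d lr %.1e loss %.4f acc %.3f val %.3f",
                      epoch, lr, train_loss, train_acc, val_acc))
    }
    if (!is.null(log_path)) {
      cat(jsonlite::toJSON(history[[length(history)]], auto_unbox = TRUE,
                           dataframe = "rows", na = "null"),
          "\n", file = log_path, append = TRUE)
    }
    if (!is.null(config$early_stop_train_acc) &&
        train_acc >= config$early_stop_train_acc) break
  }
  history <- do.call(rbind, history)
  ckpt <- if (!is.null(best$ckpt)) best$ckpt
          else snapshot_checkpoint(model, state, config,
                                   epoch = max(history$epoch))
  ckpt$history <- history
  ckpt$final <- snapshot_checkpoint(model, state, config,
                                    epoch = max(history$epoch))$weights
  if (!is.null(checkpoint_path)) saveRDS(ckpt, checkpoint_path)
  ckpt
}

snapshot_checkpoint <- function(model, state, config, epoch) {
  params <- collect_params(model)
  buffers <- collect_buffers(model)
  structure(list(
    weights = lapply(params, function(p) p$value),
    buffers = lapply(buffers, function(b) {
      list(running_mean = b$running_mean, running_var = b$running_var)
    }),
    opt_state = state,
    epoch = epoch,
    config = config
  ), class = "hybrid_checkpoint")
}

#' Restore a model (and optionally optimizer state) from a checkpoint
#'
#' @param ckpt A `hybrid_checkpoint` or an RDS path.
#' @return List with `model` and `config`.
#' @export
load_checkpoint <- function(ckpt) {
  if (is.character(ckpt)) ckpt <- readRDS(ckpt)
  model <- build_model(ckpt$config)
  params <- collect_params(model)
  stopifnot(identical(names(params), names(ckpt$weights)))
  for (nm in names(params)) params[[nm]]$value <- ckpt$weights[[nm]]
  buffers <- collect_buffers(model)
  for (nm in names(buffers)) {
    buffers[[nm]]$running_mean <- ckpt$buffers[[nm]]$running_mean
    buffers[[nm]]$running_var <- ckpt$buffers[[nm]]$running_var
  }
  list(model = model, config = ckpt$config)
}

## evaluate preprocessed images in batches with the main (combine) head
eval_images <- function(model, imgs, labels, config) {
  bs <- config$batch_size
  n <- length(imgs)
  preds <- integer(n)
  probs <- matrix(0, n, config$num_classes)
  for (start in seq(1L, n, by = bs)) {
    take <- start:min(start + bs - 1L, n)
    xb <- stack_batch(lapply(imgs[take], geom_test, aug = config$augment))
    out <- hybrid_forward(model, xb, training = FALSE)
    preds[take] <- apply(out$logits_combine, 2, which.max)
    probs[take, ] <- out$probs
  }
  rep <- metrics_report(labels, preds, scores = probs, K = config$num_classes)
  rep$predictions <- preds
  rep$probs <- probs
  rep
}

#' Evaluate a checkpoint (or model) on a manifest split
#'
#' Applies the deterministic test transform, predicts with the main-head
#' argmax, and returns a full [metrics_report()].
#'
#' @param ckpt A `hybrid_checkpoint`, RDS path, or a list with `model`
#'   and `config`.
#' @param manifest Manifest data frame.
#' @param images_dir Image directory.
#' @param split Split tag to evaluate (default "test").
#' @return A `metrics_report` (with `predictions` and `probs` attached).
#' @export
evaluate <- function(ckpt, manifest, images_dir, split = "test") {
  mc <- if (inherits(ckpt, "hybrid_checkpoint") || is.character(ckpt)) {
    load_checkpoint(ckpt)
  } else ckpt
  te <- load_split_images(manifest, images_dir, split, mc$config$augment)
  if (length(te$imgs) == 0L) stop("empty split '", split, "'")
  eval_images(mc$model, te$imgs, te$labels, mc$config)
}

#' Stratified k-fold cross-validation
#'
#' Trains one model per fold (fold f validates on `fold_f`, trains on the
#' rest) and reports per-fold metrics plus their unweighted mean accuracy.
#'
#' @param config A [run_config()].
#' @param manifest Manifest data frame (any existing split is replaced by
#'   fold tags).
#' @param images_dir Image directory.
#' @param k Number of folds (default 5, must be >= 2).
#' @param verbose Print progress.
#' @return List with `folds` (list of `metrics_report`) and
#'   `mean_accuracy`.
#' @export
cross_validate <- function(config, manifest, images_dir, k = 5L,
                           verbose = TRUE) {
  stopifnot(k >= 2L)
  manifest <- stratified_split(manifest, seed = config$seed, k = k)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    fm <- manifest
    fm$split <- ifelse(fm$split == paste0("fold_", f), "val", "train")
    ck <- train(config, fm, images_dir, train_split = "train",
                val_split = "val", verbose = verbose)
    reports[[f]] <- evaluate(ck, fm, images_dir, split = "val")
  }
  list(folds = reports,
       mean_accuracy = mean(vapply(reports, `[[`, numeric(1),
                                   "total_accuracy")))
}
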