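## Run configuration: optimizer protocol, loss weights, model preset and
## data pipeline settings, serializable to/from YAML.

#' Create a run configuration
#'
#' The optimization protocol defaults to SGD with momentum 0.9, weight
#' decay 1e-5, initial learning rate 1e-3 multiplied by 0.1 every 10
#' epochs.  The `paper` preset uses the full-size backbones (224 input);
#' the `tiny` preset uses narrow backbones on 64 x 64 input with a 64
#' channel reduction before second-order pooling, sized for single-CPU
#' runs.
#'
#' @param preset `"tiny"` or `"paper"`.
#' @param epochs Training epochs (default 50 for `paper`, 30 for `tiny`).
#' @param batch_size Mini-batch size (default 16; the loss is normalized
#'   by batch size, so this is a free parameter).
#' @param lr,momentum,weight_decay SGD hyperparameters.
#' @param lr_step,lr_gamma Learning-rate schedule: multiply by `lr_gamma`
#'   every `lr_step` epochs.
#' @param loss_weights Three-branch loss weights (alpha, beta, gamma);
#'   default `c(1, 1, 2)`.
#' @param label_smooth_eps Label smoothing coefficient (default 0.1).
#' @param sop_L Newton-Schulz iterations in the main head (default 8).
#' @param sop_reduce Channel width of the 1x1 reduction before SOP
#'   (`NULL` = no reduction).
#' @param sop_mode `"sop"` or `"gap"` (ablation).
#' @param ffm_enabled Couple the branches after stages 1-3.
#' @param num_classes Number of classes (default 4).
#' @param augment An [augment_spec()]; defaults depend on the preset.
#' @param seed Master seed; model initialization and the training loop
#'   derive their own named seeds from it.
#' @param deterministic Keep all computation single-threaded /
#'   sequentially seeded so identical runs agree bit-for-bit.
#' @param early_stop_train_acc Stop training once the running training
#'   accuracy reaches this level (`NULL` disables).
#' @return A `run_config` list.
#' @export
run_config <- function(preset = c("tiny", "paper"),
                       epochs = NULL, batch_size = 16L,
                       lr = 1e-3, momentum = 0.9, weight_decay = 1e-5,
                       lr_step = 10L, lr_gamma = 0.1,
                       loss_weights = c(1, 1, 2), label_smooth_eps = 0.1,
                       sop_L = 8L, sop_reduce = NULL,
                       sop_mode = "sop", ffm_enabled = TRUE,
                       num_classes = 4L, augment = NULL, seed = 1L,
                       deterministic = TRUE,
                       early_stop_train_acc = NULL) {
  preset <- match.arg(preset)
  if (is.null(epochs)) epochs <- if (preset == "paper") 50L else 30L
  if (is.null(augment)) {
    augment <- if (preset == "paper") augment_spec()
               else augment_spec(resize = 72L, crop = 64L)
  }
  if (preset == "tiny" && missing(sop_reduce)) sop_reduce <- 64L
  structure(list(preset = preset, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 momentum = momentum, weight_decay = weight_decay,
                 lr_step = as.integer(lr_step), lr_gamma = lr_gamma,
                 loss_weights = loss_weights,
                 label_smooth_eps = label_smooth_eps,
                 sop_L = as.integer(sop_L),
                 sop_reduce = if (is.null(sop_reduce)) NULL
                              else as.integer(sop_reduce),
                 sop_mode = sop_mode, ffm_enabled = isTRUE(ffm_enabled),
                 num_classes = as.integer(num_classes), augment = augment,
                 seed = as.integer(seed),
                 seed_init = as.integer(seed) * 1000L + 1L,
                 seed_train = as.integer(seed) * 1000L + 2L,
                 deterministic = isTRUE(deterministic),
                 early_stop_train_acc = early_stop_train_acc),
            class = "run_config")
}

#' Learning rate at a given (0-based) epoch under the step schedule
#' @param config A [run_config()].
#' @param epoch 0-based epoch index.
#' @return Numeric learning rate.
#' @export
lr_at_epoch <- function(config, epoch) {
  config$lr * config$lr_gamma^(epoch %/% config$lr_step)
}

#' Write / read a run configuration as YAML
#' @param config A [run_config()].
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  obj <- unclass(config)
  obj$augment <- unclass(obj$augment)
  yaml::write_yaml(obj, path)
  invisible(config)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  aug <- do.call(augment_spec, obj$augment[c("flip_p", "resize", "crop",
                                             "clahe", "clahe_clip",
                                             "clahe_tiles", "mean", "std")])
  args <- obj[setdiff(names(obj), c("augment", "seed_init", "seed_train"))]
  args$augment <- aug
  args$loss_weights <- unlist(args$loss_weights)
  do.call(run_config, args)
}

#' Build the hybrid model described by a configuration
#'
#' Parameter initialization is driven by the config's `seed_init`, so a
#' given configuration always builds the same model.
#'
#' @param config A [run_config()].
#' @return A `hybrid_model`.
#' @export
build_model <- function(config) {
  set.seed(config$seed_init)
  pvt_cfgs <- if (config$preset == "paper") pvt_default_configs()
              else pvt_tiny_configs()
  cnn_cfg <- if (config$preset == "paper") cnn_config() else cnn_tiny_config()
  new_hybrid_model(pvt_cfgs, cnn_cfg, num_classes = config$num_classes,
                   ffm_enabled = config$ffm_enabled, sop_L = config$sop_L,
                   sop_reduce = config$sop_reduce,
                   sop_mode = config$sop_mode)
}
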