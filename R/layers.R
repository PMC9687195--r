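## Layer constructors.  A layer is an environment holding parameter nodes
## (class "ag_param") plus any non-trainable buffers; parameters are found
## by recursive traversal (collect_params) in sorted-name order, which
## fixes the checkpoint key schema.

init_normal <- function(n, sd) array(stats::rnorm(n, sd = sd), dim = n)

## Kaiming (fan-in, ReLU gain) initialization for conv weights
init_kaiming <- function(cout, fanin) {
  matrix(stats::rnorm(cout * fanin, sd = sqrt(2 / fanin)), cout, fanin)
}

## truncated-normal(0.02) initialization used for transformer projections
init_trunc <- function(cout, cin, sd = 0.02) {
  x <- stats::rnorm(cout * cin, sd = sd)
  while (any(bad <- abs(x) > 2 * sd)) x[bad] <- stats::rnorm(sum(bad), sd = sd)
  matrix(x, cout, cin)
}

new_layer <- function(class, ...) {
  e <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(class, "nn_layer")
  e
}

conv_layer <- function(cin, cout, k, stride = 1L, pad = 0L, bias = TRUE,
                       init = c("kaiming", "trunc")) {
  init <- match.arg(init)
  W <- if (init == "kaiming") init_kaiming(cout, cin * k * k)
       else init_trunc(cout, cin * k * k)
  new_layer("conv_layer",
            W = ag_param(W),
            b = if (bias) ag_param(numeric(cout)) else NULL,
            k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad))
}

conv_fwd <- function(ly, x) {
  ag_conv2d(x, ly$W, ly$b, k = ly$k, stride = ly$stride, pad = ly$pad)
}

bn_layer <- function(C) {
  new_layer("bn_layer",
            gamma = ag_param(rep(1, C)), beta = ag_param(numeric(C)),
            running_mean = numeric(C), running_var = rep(1, C))
}

bn_fwd <- function(ly, x, training) {
  ag_batchnorm(x, ly$gamma, ly$beta, ly, training = training)
}

ln_layer <- function(d) {
  new_layer("ln_layer", gamma = ag_param(rep(1, d)),
            beta = ag_param(numeric(d)))
}

ln_fwd <- function(ly, x) ag_layernorm(x, ly$gamma, ly$beta)

linear_layer <- function(din, dout, bias = TRUE, init = c("trunc", "kaiming")) {
  init <- match.arg(init)
  W <- if (init == "trunc") init_trunc(dout, din) else init_kaiming(dout, din)
  new_layer("linear_layer", W = ag_param(W),
            b = if (bias) ag_param(numeric(dout)) else NULL)
}

linear_fwd <- function(ly, x) ag_linear(x, ly$W, ly$b)

dw_layer <- function(C, k = 3L) {
  new_layer("dw_layer",
            W9 = ag_param(matrix(stats::rnorm(k * k * C, sd = sqrt(2 / (k * k))),
                                 k * k, C)),
            b = ag_param(numeric(C)), k = as.integer(k))
}

dw_fwd <- function(ly, x) ag_dwconv(x, ly$W9, ly$b, k = ly$k, pad = (ly$k - 1L) %/% 2L)

## ---- parameter traversal ----

#' Collect trainable parameters of a model
#'
#' Walks the nested layer structure in sorted-name order and returns the
#' parameter nodes under stable dotted names (the checkpoint key schema).
#'
#' @param x Model, module, layer or list thereof.
#' @param prefix Name prefix used during recursion.
#' @return Named list of parameter nodes.
#' @export
collect_params <- function(x, prefix = "") {
  out <- list()
  if (inherits(x, "ag_param")) {
    out[[prefix]] <- x
    return(out)
  }
  if (inherits(x, "ag_node")) return(out)
  kids <- NULL
  if (is.environment(x)) {
    nms <- sort(ls(x))
    kids <- mget(nms, envir = x)
  } else if (is.list(x)) {
    nms <- names(x)
    if (is.null(nms)) nms <- as.character(seq_along(x))
    o <- order(nms)
    kids <- x[o]
    names(kids) <- nms[o]
  } else {
    return(out)
  }
  for (nm in names(kids)) {
    v <- kids[[nm]]
    if (is.function(v) || is.character(v) || is.null(v)) next
    if (is.numeric(v) && !inherits(v, "ag_node")) next
    sub <- collect_params(v, if (nzchar(prefix)) paste(prefix, nm, sep = ".")
                          else nm)
    out <- c(out, sub)
  }
  out
}

## collect batch-norm buffer environments (running statistics)
collect_buffers <- function(x, prefix = "") {
  out <- list()
  if (inherits(x, "bn_layer")) {
    out[[prefix]] <- x
    return(out)
  }
  if (inherits(x, "ag_node")) return(out)
  kids <- NULL
  if (is.environment(x)) {
    nms <- sort(ls(x))
    kids <- mget(nms, envir = x)
  } else if (is.list(x)) {
    nms <- names(x)
    if (is.null(nms)) nms <- as.character(seq_along(x))
    o <- order(nms)
    kids <- x[o]
    names(kids) <- nms[o]
  } else {
    return(out)
  }
  for (nm in names(kids)) {
    v <- kids[[nm]]
    if (!is.environment(v) && !is.list(v)) next
    if (inherits(v, "ag_node") && !inherits(v, "bn_layer")) next
    sub <- collect_buffers(v, if (nzchar(prefix)) paste(prefix, nm, sep = ".")
                           else nm)
    out <- c(out, sub)
  }
  out
}
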