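## Reverse-mode automatic differentiation over plain R arrays.
##
## A "node" is an environment holding a value (numeric array), an optional
## gradient, the parent nodes it was computed from, and a backward closure
## mapping the node's gradient to a list of parent gradients.  Operations
## append nodes to a tape; ag_backward() walks the tape in reverse.
## Parameters live off-tape and keep their gradients until zeroed.

the <- new.env(parent = emptyenv())
the$recording <- FALSE
the$tape <- vector("list", 0L)
the$ntape <- 0L
the$cache <- new.env(parent = emptyenv())  # im2col index cache

#' Start a fresh autodiff tape
#'
#' Clears any previous tape and turns on recording, so that subsequent
#' tensor operations register backward closures.
#' @return Invisibly, `NULL`.
#' @keywords internal
ag_tape_start <- function() {
  the$tape <- vector("list", 256L)
  the$ntape <- 0L
  the$recording <- TRUE
  invisible(NULL)
}

#' Stop recording and drop the tape
#' @return Invisibly, `NULL`.
#' @keywords internal
ag_tape_stop <- function() {
  the$recording <- FALSE
  the$tape <- vector("list", 0L)
  the$ntape <- 0L
  invisible(NULL)
}

#' Evaluate an expression without recording gradients
#'
#' @param expr Expression to evaluate in inference mode.
#' @return The value of `expr`.
#' @keywords internal
ag_no_grad <- function(expr) {
  old <- the$recording
  the$recording <- FALSE
  on.exit(the$recording <- old)
  expr
}

new_ag_node <- function(value, parents = list(), backward = NULL,
                        param = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  nd$retain <- FALSE
  class(nd) <- if (param) c("ag_param", "ag_node") else "ag_node"
  nd
}

#' Wrap a plain array as a constant node
#' @param x Numeric array.
#' @return An autodiff node with no parents.
#' @keywords internal
ag_const <- function(x) {
  if (inherits(x, "ag_node")) return(x)
  new_ag_node(x)
}

#' Create a trainable parameter node
#' @param x Initial numeric array.
#' @return A parameter node (kept off-tape; gradient persists after backward).
#' @keywords internal
ag_param <- function(x) new_ag_node(x, param = TRUE)

## Register an op result.  `backward` receives the accumulated output
## gradient and must return a list of gradients aligned with `parents`
## (NULL entries allowed).
ag_op <- function(value, parents, backward) {
  if (!the$recording) return(new_ag_node(value))
  nd <- new_ag_node(value, parents, backward)
  n <- the$ntape + 1L
  if (n > length(the$tape)) length(the$tape) <- 2L * length(the$tape)
  the$tape[[n]] <- nd
  the$ntape <- n
  nd
}

#' Backpropagate from a node through the current tape
#'
#' @param root Node to seed (typically a scalar loss).
#' @param seed Gradient seed, default 1.
#' @return Invisibly, `NULL`; parameter nodes hold their gradients in `$grad`.
#' @keywords internal
ag_backward <- function(root, seed = 1) {
  g0 <- array(seed, dim = dim(root$value) %||% length(root$value))
  root$grad <- if (is.null(root$grad)) g0 else root$grad + g0
  for (i in rev(seq_len(the$ntape))) {
    nd <- the$tape[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- ps[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    if (!nd$retain) nd$grad <- NULL
  }
  invisible(NULL)
}

#' Zero the gradients of a parameter list
#' @param params List of parameter nodes.
#' @return Invisibly, `NULL`.
#' @keywords internal
ag_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

ag_value <- function(x) if (inherits(x, "ag_node")) x$value else x

`%||%` <- function(a, b) if (is.null(a)) b else a
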