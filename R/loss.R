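## Label-smoothed cross-entropy and the three-branch weighted objective.

log_softmax_cols <- function(lm) {
  m <- apply(lm, 2, max)
  z <- sweep(lm, 2, m)
  sweep(z, 2, log(colSums(exp(z))))
}

#' Label-smoothed cross-entropy loss
#'
#' For logits \eqn{v} and labels \eqn{y} over \eqn{K} classes,
#' \deqn{(1-\epsilon)\left[-\frac1N \sum_n \log p_{y_n}\right] +
#'       \epsilon\left[-\frac{1}{NK} \sum_n \sum_k \log p_k\right]}
#' where \eqn{p = \mathrm{softmax}(v)}.  Equivalent to cross-entropy
#' against targets \eqn{(1-\epsilon)\,\mathrm{onehot}(y) + \epsilon/K}.
#' With `eps = 0` this is the standard mean cross-entropy.
#'
#' @param logits Numeric matrix `(N, K)`, one row per sample.
#' @param y Integer labels in `1..K`.
#' @param eps Smoothing coefficient in `[0, 1)` (default 0.1).
#' @return Scalar loss (non-negative).
#' @examples
#' label_smoothing_ce(matrix(c(2, 0, 0, 0), 1), 1L, eps = 0.1)
#' @export
label_smoothing_ce <- function(logits, y, eps = 0.1) {
  logits <- as.matrix(logits)
  if (any(!is.finite(logits))) stop("logits must be finite")
  N <- nrow(logits); K <- ncol(logits)
  y <- as.integer(y)
  if (length(y) != N) stop("length(y) must equal nrow(logits)")
  if (any(y < 1L | y > K)) stop("labels must lie in 1..", K)
  lp <- log_softmax_cols(t(logits))  # (K, N)
  nll <- -mean(lp[cbind(y, seq_len(N))])
  unif <- -mean(lp)
  (1 - eps) * nll + eps * unif
}

#' Weighted sum of the three branch losses
#'
#' The model's total objective is
#' \eqn{\alpha\,L_{pvt} + \beta\,L_{cnn} + \gamma\,L_{combine}};
#' the default ratio is 1:1:2.
#'
#' @param losses Numeric vector of length 3 (pvt, cnn, combine).
#' @param weights Non-negative weights, default `c(1, 1, 2)`.
#' @return Scalar total loss.
#' @export
total_loss <- function(losses, weights = c(1, 1, 2)) {
  stopifnot(length(losses) == 3L, length(weights) == 3L)
  if (any(weights < 0)) stop("loss weights must be non-negative")
  sum(weights * losses)
}

## graph op: logits node (K, N), labels 1..K; backward: (p - q)/N
ag_ls_ce <- function(logits, y, eps = 0.1) {
  logits <- ag_const(logits)
  lm <- logits$value
  K <- nrow(lm); N <- ncol(lm)
  lp <- log_softmax_cols(lm)
  nll <- -mean(lp[cbind(y, seq_len(N))])
  unif <- -mean(lp)
  val <- (1 - eps) * nll + eps * unif
  ag_op(val, list(logits), function(g) {
    p <- exp(lp)
    q <- matrix(eps / K, K, N)
    q[cbind(y, seq_len(N))] <- q[cbind(y, seq_len(N))] + (1 - eps)
    list(as.numeric(g) * (p - q) / N)
  })
}
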