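#' Softplus activation
#'
#' `log(1 + exp(x))`, computed overflow-safely as
#' `max(x, 0) + log1p(exp(-|x|))`.
#'
#' @param x Numeric vector/matrix.
#' @return Softplus of `x`, elementwise.
#' @export
#' @examples
#' softplus(0)    # log(2)
#' softplus(100)  # ~100, no overflow
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# d/dx softplus = logistic sigmoid
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Softmax probabilities
#'
#' Exponentiate-and-normalize with max subtraction for stability. For a
#' matrix, columns are treated as independent logit vectors.
#'
#' @param logits Numeric vector, or matrix with one column per sample.
#' @return Probabilities of the same shape; each vector/column sums to 1.
#' @export
#' @examples
#' softmax_prob(c(0, log(3))) # 0.25 0.75
softmax_prob <- function(logits) {
  if (is.matrix(logits)) {
    z <- exp(sweep(logits, 2, apply(logits, 2, max)))
    sweep(z, 2, colSums(z), "/")
  } else {
    z <- exp(logits - max(logits))
    z / sum(z)
  }
}

#' Batch-normalization forward pass
#'
#' Normalizes a mini-batch of values by its own mean and population
#' variance, then applies the learned scale and shift:
#' `bn(F_j) = gamma * (F_j - mu_b) / sqrt(sigma_b^2 + eps) + xi`.
#'
#' @param batch Numeric vector of batch values `F_1..F_K`.
#' @param gamma,xi Scale and shift.
#' @param eps Stability constant (default `1e-5`).
#' @return Normalized values, same length as `batch`.
#' @export
#' @examples
#' batchnorm_forward(c(0, 2, 4), gamma = 2, xi = 1)
batchnorm_forward <- function(batch, gamma = 1, xi = 0, eps = 1e-5) {
  mu <- mean(batch)
  sig2 <- mean((batch - mu)^2)
  gamma * (batch - mu) / sqrt(sig2 + eps) + xi
}
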