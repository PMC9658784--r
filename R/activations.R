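#' FHE-compatible activation approximations
#'
#' Polynomial stand-ins for ReLU and sigmoid that evaluate with homomorphic
#' additions and multiplications only. Each runs identically on plaintext
#' numerics and on `ckks_ct` ciphertexts through the shared element-wise call
#' surface, consuming two multiplicative levels of a ciphertext input.
#'
#' The ReLU approximation over a dynamic range `[-q, q]` is
#' `Ra(x) = 4/(3*pi*q) x^2 + x/2 + q/(3*pi)`; its derivative is
#' `dRa(x) = 8/(3*pi*q) x + 1/2`.
#'
#' @param x numeric vector or `ckks_ct`.
#' @param q positive approximation range.
#' @return same kind as `x`.
#' @export
relu_approx <- function(x, q = 1) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0)
    stop(fhe_condition("fhe_value_error", "q must be a positive scalar"))
  ## ciphertext path: x*x is one ct x ct level, the coefficient product a
  ## second; the linear branch consumes one level and aligns on addition
  (x * x) * (4 / (3 * pi * q)) + x * 0.5 + q / (3 * pi)
}

#' @rdname relu_approx
#' @export
relu_approx_derivative <- function(x, q = 1) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0)
    stop(fhe_condition("fhe_value_error", "q must be a positive scalar"))
  x * (8 / (3 * pi * q)) + 0.5
}

#' @rdname relu_approx
#' @export
relu_exact <- function(x) pmax(0, x)

#' Sigmoid approximation
#'
#' `sigmoid_approx(x) = 0.5 + 0.197 x - 0.004 x^3`, a static polynomial
#' approximation of the logistic function faithful on roughly `[-5, 5]`.
#' The cubic term is computed as `(x * -0.004) * (x * x)` so a ciphertext
#' input consumes two multiplicative levels. The analytic derivative is
#' `0.197 - 0.012 x^2`; [sigmoid_exact()] is the plaintext reference.
#'
#' @param x numeric vector or `ckks_ct`.
#' @return same kind as `x`.
#' @export
sigmoid_approx <- function(x) {
  (x * -0.004) * (x * x) + x * 0.197 + 0.5
}

#' @rdname sigmoid_approx
#' @export
sigmoid_approx_derivative <- function(x) {
  (x * x) * -0.012 + 0.197
}

#' @rdname sigmoid_approx
#' @export
sigmoid_exact <- function(x) 1 / (1 + exp(-x))

## ---------------------------------------------------------------------------
## Plaintext-only loss / prediction circuit. Softmax and argmax need division
## and context respectively, neither of which is abelian-compatible, so they
## run client-side after decryption; calling them on a ciphertext is an
## explicit FHE-incompatibility error.

require_plaintext <- function(x, what) {
  if (is_ct(x))
    stop(fhe_condition("fhe_compat_error",
                       paste0(what, " is not FHE-compatible; decrypt first")))
  invisible(x)
}

#' Numerically stabilised softmax
#'
#' @param a plaintext activation vector.
#' @return probability vector summing to one.
#' @export
softmax <- function(a) {
  require_plaintext(a, "softmax")
  e <- exp(a - max(a))
  e / sum(e)
}

#' Categorical cross-entropy with combined softmax gradient
#'
#' @param p probability vector (softmax output).
#' @param y_onehot one-hot encoded true class.
#' @param eps clamp for log(0).
#' @return list with `loss` and `grad` (the combined softmax+CCE gradient
#'   `p - y`, routed back through the softmax to the dense layer).
#' @export
cce_loss <- function(p, y_onehot, eps = 1e-12) {
  require_plaintext(p, "categorical cross-entropy")
  s <- sum(p)
  if (is.finite(s) && abs(s - 1) > 1e-6)
    warning("probabilities do not sum to 1", call. = FALSE)
  list(loss = -sum(y_onehot * log(pmax(p, eps))), grad = p - y_onehot)
}

#' Mean squared error
#'
#' @param yhat,y plaintext predictions and targets of equal shape.
#' @return list with `loss` and `grad` (`2 (yhat - y) / n`).
#' @export
mse_loss <- function(yhat, y) {
  require_plaintext(yhat, "MSE")
  if (length(yhat) != length(y))
    stop(fhe_condition("fhe_shape_error", "yhat and y differ in length"))
  d <- yhat - y
  list(loss = mean(d^2), grad = 2 * d / length(d))
}

#' One-hot prediction circuit
#'
#' `argmax_onehot` turns an activation vector into a one-hot vector (ties
#' break toward the lowest index); `onehot_decode` recovers the 0-based class
#' index; `onehot_encode` encodes a 0-based class. All plaintext-only.
#'
#' @param a plaintext activation vector.
#' @export
argmax_onehot <- function(a) {
  require_plaintext(a, "argmax")
  v <- numeric(length(a))
  v[which.max(a)] <- 1
  v
}

#' @rdname argmax_onehot
#' @param v one-hot vector.
#' @export
onehot_decode <- function(v) {
  require_plaintext(v, "one-hot decoding")
  which.max(v) - 1L
}

#' @rdname argmax_onehot
#' @param y 0-based class index.
#' @param K number of classes.
#' @export
onehot_encode <- function(y, K) {
  v <- numeric(K)
  v[y + 1L] <- 1
  v
}

#' Mean absolute percentage error
#'
#' @param y true values (strictly nonzero).
#' @param yhat predictions.
#' @return `100 * mean(|y - yhat| / |y|)`.
#' @export
mape <- function(y, yhat) {
  if (any(y == 0))
    stop(fhe_condition("fhe_value_error", "MAPE undefined for zero targets"))
  100 * mean(abs(y - yhat) / abs(y))
}
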