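#' Graph node family
#'
#' Nodes are environment-backed computational objects exposing named
#' *receptors* ("forward", "backward") invoked by signal propagation, plus an
#' integer multiplicative-depth `node_cost()` used by the autoFHE
#' parameteriser. All forward receptors are written against the shared
#' element-wise call surface, so the same node computes plaintext arrays and
#' `ckks_ct` ciphertexts interchangeably.
#'
#' @name fhe-nodes
NULL

new_node <- function(type, fields = list()) {
  nd <- new.env(parent = emptyenv())
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = nd)
  nd$training <- FALSE
  nd$last_output <- NULL
  class(nd) <- c(type, "fhe_node")
  nd
}

#' Invoke a receptor on a node
#'
#' @param node an `fhe_node`.
#' @param r receptor name.
#' @param s gathered signal.
#' @export
node_receptor <- function(node, r, s) {
  res <- switch(r,
    forward = node_forward(node, s),
    backward = node_backward(node, s),
    if (!is.null(node$receptors) && r %in% names(node$receptors))
      node$receptors[[r]](node, s)
    else
      stop(fhe_condition("fhe_receptor_error",
                         paste0("receptor not supported: ", r))))
  if (identical(r, "forward")) node$last_output <- res
  res
}

#' @rdname node_receptor
#' @export
node_forward <- function(node, s) UseMethod("node_forward")

#' @rdname node_receptor
#' @export
node_backward <- function(node, s) UseMethod("node_backward")

#' Multiplicative-depth cost of a node
#'
#' The number of ciphertext levels (rescales) the node's forward receptor
#' consumes; additions are free, each ct x ct or ct x pt product stage costs
#' one level.
#'
#' @param node an `fhe_node`.
#' @export
node_cost <- function(node) UseMethod("node_cost")

#' @export
node_cost.default <- function(node) 0L

#' Does a node participate in backpropagation?
#'
#' Prediction-branch nodes (argmax, one-hot codecs, raw outputs/inputs)
#' produce no gradients; backward gathering and emission skip their edges.
#'
#' @param node an `fhe_node`.
#' @export
node_backprop <- function(node) UseMethod("node_backprop")

#' @export
node_backprop.default <- function(node) TRUE

#' @export
print.fhe_node <- function(x, ...) {
  cat(sprintf("<%s: cost %d>\n", class(x)[1], node_cost(x)))
  invisible(x)
}

## fan-out gradient accumulation: a node with several backward in-signals
## receives their sum (standard chain rule)
sum_grads <- function(s) if (is.list(s) && !is_ct(s)) Reduce(`+`, s) else s

## ---------------------------------------------------------------------------
## Row-major slot layout helpers. Messages are packed row-major (last axis
## fastest), 0-based window offsets, valid (no padding) placement.

flatten_rm <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) == 1L) return(as.numeric(x))
  as.numeric(aperm(x, rev(seq_along(d))))
}

## row-major flat index (1-based) of a 0-based position vector
rm_index <- function(pos, shape) {
  idx <- 0
  for (i in seq_along(shape)) idx <- idx * shape[i] + pos[i]
  as.integer(idx + 1L)
}

## 0-based kernel element positions in row-major order
rm_positions <- function(shape) {
  grids <- lapply(rev(shape), function(d) 0:(d - 1L))
  gr <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  as.matrix(gr[, rev(seq_along(shape)), drop = FALSE])
}

#' Kernel masquerading
#'
#' Merges a convolution kernel and its zero mask into one input-shaped sparse
#' tensor: kernel values at the window placed at `window_offset`, zeros
#' elsewhere. Flattened to slot order it multiplies the whole ciphertext as a
#' single Hadamard product, so one window of a cross-correlation costs one
#' multiplicative level.
#'
#' @param kernel numeric array (window shape).
#' @param input_shape integer vector, the full input tensor shape.
#' @param window_offset 0-based offset of the window per axis.
#' @return an array of shape `input_shape`.
#' @export
masquerade <- function(kernel, input_shape, window_offset) {
  kdim <- dim(kernel)
  if (is.null(kdim)) kdim <- length(kernel)
  if (length(kdim) != length(input_shape))
    stop(fhe_condition("fhe_shape_error", "kernel and input rank differ"))
  if (any(window_offset < 0) || any(window_offset + kdim > input_shape))
    stop(fhe_condition("fhe_shape_error", "window out of bounds"))
  out <- array(0, dim = input_shape)
  ix <- lapply(seq_along(kdim),
               function(i) window_offset[i] + seq_len(kdim[i]))
  do.call(`[<-`, c(list(out), ix, list(value = kernel)))
}

## valid window offsets (0-based) in row-major order
window_offsets <- function(input_shape, kernel_shape, stride) {
  axes <- lapply(seq_along(input_shape), function(i)
    seq(0L, input_shape[i] - kernel_shape[i], by = stride[i]))
  gr <- expand.grid(rev(axes), KEEP.OUT.ATTRS = FALSE)
  m <- as.matrix(gr[, rev(seq_along(input_shape)), drop = FALSE])
  lapply(seq_len(nrow(m)), function(i) as.integer(m[i, ]))
}

## ---------------------------------------------------------------------------
## Ingress / egress / glue nodes

#' @rdname fhe-nodes
#' @export
node_input <- function() new_node("input_node")
#' @export
node_forward.input_node <- function(node, s) s
#' @export
node_backward.input_node <- function(node, s) NULL
#' @export
node_backprop.input_node <- function(node) FALSE

#' @rdname fhe-nodes
#' @param cost integer depth cost (generic fixture nodes).
#' @param fn forward function (generic fixture nodes).
#' @export
node_generic <- function(cost = 0L, fn = identity)
  new_node("generic_node", list(cost = as.integer(cost), fn = fn))
#' @export
node_forward.generic_node <- function(node, s) node$fn(s)
#' @export
node_backward.generic_node <- function(node, s) sum_grads(s)
#' @export
node_cost.generic_node <- function(node) node$cost

#' @rdname fhe-nodes
#' @param params,key_id encryption parameters and key, typically configured
#'   by [assign_parameters()].
#' @export
node_encrypt <- function(params = NULL, key_id = NULL)
  new_node("encrypt_node", list(params = params, key_id = key_id,
                                mode = "encrypt"))
#' @export
node_forward.encrypt_node <- function(node, s) {
  if (is_ct(s)) return(s)                    # already a ciphertext
  v <- flatten_rm(s)
  if (identical(node$mode, "pass") || is.null(node$params)) return(v)
  encrypt(v, node$params, if (is.null(node$key_id)) "k0" else node$key_id)
}
#' @export
node_backward.encrypt_node <- function(node, s) sum_grads(s)

#' @rdname fhe-nodes
#' @export
node_decrypt <- function() new_node("decrypt_node")
#' @export
node_forward.decrypt_node <- function(node, s) {
  dec1 <- function(x) if (is_ct(x)) decrypt(x) else as.numeric(x)
  if (is.list(s) && !is_ct(s)) {
    node$in_arity <- length(s)
    unlist(lapply(s, dec1))
  } else {
    node$in_arity <- 1L
    dec1(s)
  }
}
#' @export
node_backward.decrypt_node <- function(node, s) {
  g <- sum_grads(s)
  k <- node$in_arity
  if (is.null(k)) stop(fhe_condition("fhe_state_error", "no cached forward pass"))
  if (k == 1L) return(g)
  signal_generator(as.list(g[seq_len(k)]))
}

#' @rdname fhe-nodes
#' @param mode rotation mode: "fold", "refresh" or "split".
#' @export
node_rotate <- function(mode = "fold", params = NULL, key_id = NULL)
  new_node("rotate_node", list(mode = mode, params = params, key_id = key_id))
#' @export
node_forward.rotate_node <- function(node, s) {
  node$in_len <- value_length(s)
  if (is_ct(s)) {
    p <- if (is.null(node$params)) s$params else node$params
    k <- if (is.null(node$key_id)) s$key_id else node$key_id
    rotate(s, p, k, mode = node$mode)
  } else {
    switch(node$mode,
           fold = sum(s),
           refresh = s,
           split = as.list(s))
  }
}
#' @export
node_backward.rotate_node <- function(node, s) {
  g <- sum_grads(s)
  if (is.null(node$in_len))
    stop(fhe_condition("fhe_state_error", "no cached forward pass"))
  switch(node$mode,
         fold = rep(g, node$in_len),
         refresh = g,
         stop(fhe_condition("fhe_receptor_error",
                            "split rotation has no backward receptor")))
}

## ---------------------------------------------------------------------------
## Cross-correlation (CNN) node with kernel masquerading and commuted bias

#' @rdname fhe-nodes
#' @param kernel numeric array of kernel weights.
#' @param bias scalar bias, commuted as `bias/N` into each of the `N` window
#'   products so a downstream fold-sum reproduces `sum(x*w) + b` exactly.
#' @param stride positive integer stride per axis (scalar recycled).
#' @param input_shape shape of the packed input tensor.
#' @export
node_cc <- function(kernel, bias = 0, stride = 1, input_shape) {
  kdim <- dim(kernel); if (is.null(kdim)) kdim <- length(kernel)
  stride <- rep_len(as.integer(stride), length(input_shape))
  offs <- window_offsets(input_shape, kdim, stride)
  kpos <- rm_positions(kdim)
  N <- length(kernel)
  windows <- lapply(offs, function(off) {
    sup <- vapply(seq_len(nrow(kpos)),
                  function(i) rm_index(off + kpos[i, ], input_shape),
                  integer(1))
    list(offset = off, support = sup)
  })
  len <- prod(input_shape)
  for (i in seq_along(windows)) {
    v <- numeric(len); v[windows[[i]]$support] <- 1
    windows[[i]]$ind_flat <- v
  }
  new_node("cc_node", list(
    kernel = kernel, bias = bias, stride = stride,
    input_shape = as.integer(input_shape), N = N,
    windows = windows, T_x = length(windows),
    grad_kernel = array(0, dim = kdim), grad_bias = 0,
    cached_x = NULL))
}

#' @export
node_cost.cc_node <- function(node) 1L

#' @export
node_forward.cc_node <- function(node, s) {
  x <- if (is_ct(s)) s else flatten_rm(s)
  node$cached_x <- if (is_ct(s)) NULL else x
  ## masquerade with the *current* kernel: kernel values at the window
  ## support, zeros elsewhere (weights are plaintext and trainable)
  kf <- flatten_rm(node$kernel)
  len <- prod(node$input_shape)
  outs <- lapply(node$windows, function(w) {
    mf <- numeric(len); mf[w$support] <- kf
    x * mf + w$ind_flat * (node$bias / node$N)
  })
  signal_generator(outs)
}

#' @export
node_backward.cc_node <- function(node, s) {
  x <- node$cached_x
  if (is.null(x))
    stop(fhe_condition("fhe_state_error",
                       "no cached plaintext forward pass for backward"))
  grads <- if (is.list(s) && !is_ct(s)) s else list(s)
  if (length(grads) != node$T_x)
    stop(fhe_condition("fhe_shape_error", "one gradient per window expected"))
  kdim <- dim(node$kernel); if (is.null(kdim)) kdim <- length(node$kernel)
  kf <- flatten_rm(node$kernel)
  len <- length(x)
  dk <- numeric(node$N)
  db <- 0
  dx <- numeric(len)
  for (t in seq_along(grads)) {
    w <- node$windows[[t]]
    gt <- grads[[t]]
    dk <- dk + gt[w$support] * x[w$support]
    db <- db + sum(gt[w$support]) / node$N
    mf <- numeric(len); mf[w$support] <- kf
    dx <- dx + gt * mf
  }
  ## dk is in row-major kernel order; fold back into array layout
  dka <- array(0, dim = kdim)
  kp <- rm_positions(kdim)
  for (i in seq_len(nrow(kp)))
    dka[matrix(kp[i, ] + 1L, 1L)] <- dk[i]
  node$grad_kernel <- node$grad_kernel + dka
  node$grad_bias <- node$grad_bias + db
  dx
}

## ---------------------------------------------------------------------------
## Dense node

#' @rdname fhe-nodes
#' @param w numeric weight vector; one weight per inbound branch (sequence
#'   input) or per element (single packed input).
#' @export
node_dense <- function(w, bias = 0)
  new_node("dense_node", list(w = w, bias = bias,
                              grad_w = numeric(length(w)), grad_bias = 0,
                              cached_xs = NULL))

#' @export
node_cost.dense_node <- function(node) 1L

#' @export
node_forward.dense_node <- function(node, s) {
  if (is.list(s) && !is_ct(s)) {
    N <- length(s)
    if (length(node$w) != N)
      stop(fhe_condition("fhe_shape_error",
                         sprintf("dense expects %d inputs, got %d",
                                 length(node$w), N)))
    lens <- vapply(s, value_length, integer(1))
    if (length(unique(lens)) != 1L)
      stop(fhe_condition("fhe_shape_error", "ragged dense inputs"))
    node$cached_xs <- s
    node$cached_mode <- "seq"
    acc <- s[[1L]] * node$w[1L] + node$bias / N
    if (N > 1L) for (i in 2:N) acc <- acc + (s[[i]] * node$w[i] + node$bias / N)
    acc
  } else {
    n <- value_length(s)
    if (length(node$w) != n)
      stop(fhe_condition("fhe_shape_error",
                         sprintf("dense expects length %d, got %d",
                                 length(node$w), n)))
    node$cached_xs <- s
    node$cached_mode <- "packed"
    s * node$w + node$bias / n        # un-summed; a fold-rotation completes z
  }
}

#' @export
node_backward.dense_node <- function(node, s) {
  g <- sum_grads(s)
  xs <- node$cached_xs
  if (is.null(xs)) stop(fhe_condition("fhe_state_error", "no cached forward pass"))
  if (identical(node$cached_mode, "seq")) {
    if (any(vapply(xs, is_ct, logical(1))))
      stop(fhe_condition("fhe_state_error",
                         "backward requires a plaintext forward pass"))
    dw <- vapply(xs, function(x) sum(g * x), numeric(1))
    node$grad_w <- node$grad_w + dw
    node$grad_bias <- node$grad_bias + sum(g)
    signal_generator(lapply(node$w, function(wi) g * wi))
  } else {
    x <- xs
    node$grad_w <- node$grad_w + g * x
    node$grad_bias <- node$grad_bias + sum(g) / length(node$w)
    g * node$w
  }
}

## ---------------------------------------------------------------------------
## Activation nodes

#' @rdname fhe-nodes
#' @param q initial ReLU approximation range.
#' @param alpha EMA rate for the dynamic range tracker.
#' @param q_update "ema" (default) tracks `max(abs(x))` during training;
#'   "grad" performs a gradient step on q in the backward pass instead.
#' @export
node_relu <- function(q = 1, alpha = 0.1, q_update = c("ema", "grad"))
  new_node("relu_node", list(q = q, alpha = alpha,
                             q_update = match.arg(q_update),
                             q_lr = 0.01, cached_x = NULL))

#' @export
node_cost.relu_node <- function(node) 2L

#' @export
node_forward.relu_node <- function(node, s) {
  if (node$training && !is_ct(s)) relu_range_update(node, s)
  node$cached_x <- if (is_ct(s)) NULL else s
  relu_approx(s, node$q)
}

#' @export
node_backward.relu_node <- function(node, s) {
  g <- sum_grads(s)
  x <- node$cached_x
  if (is.null(x)) stop(fhe_condition("fhe_state_error", "no cached forward pass"))
  if (identical(node$q_update, "grad") && node$training) {
    dq <- sum(g * (-4 * x^2 / (3 * pi * node$q^2) + 1 / (3 * pi)))
    node$q <- max(node$q - node$q_lr * dq, 1e-3)
  }
  g * relu_approx_derivative(x, node$q)
}

#' Update the dynamic ReLU approximation range
#'
#' Exponential moving average toward the batch magnitude:
#' `q <- (1 - alpha) q + alpha max(abs(batch))`. With `alpha = 1` the range
#' snaps to the batch; with `alpha = 0` it never moves.
#'
#' @param node a ReLU approximation node.
#' @param batch_inputs plaintext activations observed at the node.
#' @return the updated range, invisibly.
#' @export
relu_range_update <- function(node, batch_inputs) {
  if (length(batch_inputs) == 0L) return(invisible(node$q))
  m <- max(abs(batch_inputs))
  if (!is.finite(m)) return(invisible(node$q))
  node$q <- max((1 - node$alpha) * node$q + node$alpha * m, 1e-3)
  invisible(node$q)
}

#' @rdname fhe-nodes
#' @export
node_sigmoid <- function() new_node("sigmoid_node", list(cached_x = NULL))

#' @export
node_cost.sigmoid_node <- function(node) 2L

#' @export
node_forward.sigmoid_node <- function(node, s) {
  node$cached_x <- if (is_ct(s)) NULL else s
  sigmoid_approx(s)
}

#' @export
node_backward.sigmoid_node <- function(node, s) {
  g <- sum_grads(s)
  x <- node$cached_x
  if (is.null(x)) stop(fhe_condition("fhe_state_error", "no cached forward pass"))
  g * sigmoid_approx_derivative(x)
}

## ---------------------------------------------------------------------------
## Plaintext loss / prediction circuit nodes

#' @rdname fhe-nodes
#' @export
node_softmax <- function() new_node("softmax_node")
#' @export
node_forward.softmax_node <- function(node, s) softmax(s)
## the combined softmax+CCE gradient (p - y) arrives from the loss node and
## passes through unchanged
#' @export
node_backward.softmax_node <- function(node, s) sum_grads(s)

#' @rdname fhe-nodes
#' @export
node_cce <- function() new_node("cce_node", list(loss = NULL, grad = NULL))
#' @export
node_forward.cce_node <- function(node, s) {
  if (!is.list(s) || length(s) != 2L)
    stop(fhe_condition("fhe_shape_error",
                       "CCE expects (probabilities, one-hot y) in edge order"))
  r <- cce_loss(s[[1L]], s[[2L]])
  node$loss <- r$loss
  node$grad <- r$grad
  r$loss
}
#' @export
node_backward.cce_node <- function(node, s) {
  if (is.null(node$grad)) stop(fhe_condition("fhe_state_error", "no cached loss"))
  node$grad * sum_grads(s)
}

#' @rdname fhe-nodes
#' @export
node_mse <- function() new_node("mse_node", list(loss = NULL, grad = NULL))
#' @export
node_forward.mse_node <- function(node, s) {
  if (!is.list(s) || length(s) != 2L)
    stop(fhe_condition("fhe_shape_error", "MSE expects (yhat, y) in edge order"))
  r <- mse_loss(as.numeric(s[[1L]]), as.numeric(s[[2L]]))
  node$loss <- r$loss
  node$grad <- r$grad
  r$loss
}
#' @export
node_backward.mse_node <- function(node, s) node$grad * sum_grads(s)

#' @rdname fhe-nodes
#' @export
node_argmax <- function() new_node("argmax_node")
#' @export
node_forward.argmax_node <- function(node, s) argmax_onehot(s)
#' @export
node_backward.argmax_node <- function(node, s) NULL
#' @export
node_backprop.argmax_node <- function(node) FALSE

#' @rdname fhe-nodes
#' @export
node_onehot_decode <- function() new_node("onehot_decode_node")
#' @export
node_forward.onehot_decode_node <- function(node, s) onehot_decode(s)
#' @export
node_backward.onehot_decode_node <- function(node, s) NULL
#' @export
node_backprop.onehot_decode_node <- function(node) FALSE

#' @rdname fhe-nodes
#' @param K number of classes.
#' @export
node_onehot_encode <- function(K) new_node("onehot_encode_node", list(K = K))
#' @export
node_forward.onehot_encode_node <- function(node, s) onehot_encode(s, node$K)
#' @export
node_backward.onehot_encode_node <- function(node, s) NULL
#' @export
node_backprop.onehot_encode_node <- function(node) FALSE

#' @rdname fhe-nodes
#' @export
node_output <- function() new_node("output_node")
#' @export
node_forward.output_node <- function(node, s) s
#' @export
node_backward.output_node <- function(node, s) NULL
#' @export
node_backprop.output_node <- function(node) FALSE

## ---------------------------------------------------------------------------
## Graph-wide node state helpers

#' Toggle training mode / encryption on a graph
#'
#' Training mode enables dynamic-range tracking on ReLU nodes; encryption
#' mode controls whether encrypt nodes actually encrypt (training runs
#' plaintext-side, the inference path runs either way).
#'
#' @param g a `compgraph`.
#' @param on logical.
#' @export
set_training <- function(g, on = TRUE) {
  for (nm in g$node_order) g$nodes[[nm]]$node$training <- on
  invisible(g)
}

#' @rdname set_training
#' @export
set_encryption <- function(g, on = TRUE) {
  for (nm in g$node_order) {
    nd <- g$nodes[[nm]]$node
    if (inherits(nd, "encrypt_node")) nd$mode <- if (on) "encrypt" else "pass"
  }
  invisible(g)
}

#' Apply accumulated SGD updates to all learnable nodes
#'
#' @param g a `compgraph`.
#' @param lr learning rate.
#' @export
sgd_update <- function(g, lr) {
  for (nm in g$node_order) {
    nd <- g$nodes[[nm]]$node
    if (inherits(nd, "cc_node")) {
      nd$kernel <- nd$kernel - lr * nd$grad_kernel
      nd$bias <- nd$bias - lr * nd$grad_bias
      nd$grad_kernel[] <- 0
      nd$grad_bias <- 0
    } else if (inherits(nd, "dense_node")) {
      nd$w <- nd$w - lr * nd$grad_w
      nd$bias <- nd$bias - lr * nd$grad_bias
      nd$grad_w[] <- 0
      nd$grad_bias <- 0
    }
  }
  invisible(g)
}
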