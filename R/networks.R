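#' Network configuration
#'
#' Collects the shape, depth and optimisation choices for the built-in
#' network topologies. The seed fixes all weight initialisation.
#'
#' @param input_shape input tensor shape (e.g. `c(8, 8)` for images,
#'   `c(T_x, F)` for feature windows).
#' @param kernel_shape convolution kernel shape.
#' @param stride stride per axis (scalar recycled).
#' @param n_classes number of classes (classification networks).
#' @param n_filters number of convolution filter neurons (default one).
#' @param output_dim output dimension (regression networks).
#' @param activation "relu" or "sigmoid" approximation for the
#'   classification network.
#' @param scale_power,special_mult CKKS parameteriser inputs.
#' @param seed RNG seed for weight initialisation.
#' @param lr SGD learning rate.
#' @param epochs maximum training epochs.
#' @param early_stop_acc optional training accuracy at which to stop early.
#' @export
network_config <- function(input_shape = c(8, 8), kernel_shape = c(3, 3),
                           stride = 2, n_classes = 2, n_filters = 1,
                           output_dim = 1,
                           activation = c("relu", "sigmoid"),
                           scale_power = 40, special_mult = 1.5,
                           seed = 42, lr = 0.01, epochs = 50,
                           early_stop_acc = NULL) {
  cfg <- list(input_shape = as.integer(input_shape),
              kernel_shape = as.integer(kernel_shape),
              stride = as.integer(stride),
              n_classes = as.integer(n_classes),
              n_filters = as.integer(n_filters),
              output_dim = as.integer(output_dim),
              activation = match.arg(activation),
              scale_power = scale_power, special_mult = special_mult,
              seed = as.integer(seed), lr = lr, epochs = as.integer(epochs),
              early_stop_acc = early_stop_acc)
  if (any(cfg$kernel_shape > cfg$input_shape))
    stop(fhe_condition("fhe_config_error", "kernel larger than input"))
  strides <- rep_len(cfg$stride, length(cfg$input_shape))
  cfg$T_x <- prod((cfg$input_shape - cfg$kernel_shape) %/% strides + 1L)
  class(cfg) <- "network_config"
  cfg
}

act_node <- function(kind) {
  if (identical(kind, "relu")) node_relu() else node_sigmoid()
}

#' Build the "sphira" classification graph
#'
#' An encrypted-inference CNN classifier: the image ciphertext enters at
#' `x`, is encrypted, cross-correlated with a masqueraded kernel (one
#' ciphertext per window), fold-summed by key-rotation nodes, activated, and
#' interpreted by one dense node per class, each with its own activation.
#' After decryption the graph branches into a prediction circuit
#' (argmax -> one-hot decode) and a loss circuit (softmax -> categorical
#' cross-entropy, fed by the one-hot encoded label entering at `y`).
#' [autohe()] runs at build time and configures the encrypt/rotation nodes.
#'
#' @param cfg a [network_config()].
#' @return a fired-ready `compgraph` with attributes `pred_node`,
#'   `loss_node` and `cfg` stored on the graph environment.
#' @export
build_sphira <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  if (cfg$n_classes < 2)
    stop(fhe_condition("fhe_config_error", "classification needs >= 2 classes"))
  set.seed(cfg$seed)
  g <- compgraph()
  add_node(g, "x", node_input())
  add_node(g, "enc_x", node_encrypt())
  add_edge(g, "x", "enc_x")
  ## one filter neuron by default; extra filters get their own window chains
  act_names <- character()
  for (f in seq_len(cfg$n_filters)) {
    kN <- prod(cfg$kernel_shape)
    kernel <- array(stats::rnorm(kN, sd = 1 / sqrt(kN)),
                    dim = cfg$kernel_shape)
    ccn <- if (cfg$n_filters == 1L) "cc" else paste0("cc_", f)
    add_node(g, ccn, node_cc(kernel, bias = 0, stride = cfg$stride,
                             input_shape = cfg$input_shape))
    T_x <- g$nodes[[ccn]]$node$T_x
    add_edge(g, "enc_x", ccn)
    for (t in seq_len(T_x)) {
      sfx <- if (cfg$n_filters == 1L) t else paste0(f, "_", t)
      add_node(g, paste0("fold_", sfx), node_rotate("fold"))
      add_node(g, paste0("act_w_", sfx), act_node(cfg$activation))
      add_edge(g, ccn, paste0("fold_", sfx))
      add_edge(g, paste0("fold_", sfx), paste0("act_w_", sfx))
      act_names <- c(act_names, paste0("act_w_", sfx))
    }
  }
  for (k in seq_len(cfg$n_classes)) {
    w <- stats::rnorm(length(act_names), sd = 1 / sqrt(length(act_names)))
    add_node(g, paste0("dense_", k), node_dense(w, bias = 0))
    add_node(g, paste0("act_d_", k), act_node(cfg$activation))
    for (a in act_names) add_edge(g, a, paste0("dense_", k))
    add_edge(g, paste0("dense_", k), paste0("act_d_", k))
  }
  add_node(g, "dec", node_decrypt())
  for (k in seq_len(cfg$n_classes)) add_edge(g, paste0("act_d_", k), "dec")
  ## prediction circuit (plaintext, no backprop)
  add_node(g, "argmax", node_argmax())
  add_node(g, "pred", node_onehot_decode())
  add_edge(g, "dec", "argmax")
  add_edge(g, "argmax", "pred")
  ## loss circuit: softmax edge must precede the one-hot y edge into cce
  add_node(g, "softmax", node_softmax())
  add_node(g, "cce", node_cce())
  add_node(g, "y", node_input())
  add_node(g, "onehot_y", node_onehot_encode(cfg$n_classes))
  add_edge(g, "dec", "softmax")
  add_edge(g, "softmax", "cce")
  add_edge(g, "y", "onehot_y")
  add_edge(g, "onehot_y", "cce")
  g$cfg <- cfg
  g$kind <- "classification"
  g$pred_node <- "pred"
  g$loss_node <- "cce"
  g$ingress <- c("x", "y")
  groups <- autohe(g, "enc_x")
  assign_parameters(g, groups, scale_power = cfg$scale_power,
                    special_mult = cfg$special_mult)
  g$groups <- groups
  g
}

#' Build the "constellation" regression graph
#'
#' A 1D time-series CNN for yield regression: the encrypted feature window
#' passes through a 1D cross-correlation, per-window fold-sum rotations and
#' sigmoid approximations, a dense merge across windows, a final sigmoid and
#' decryption into a prediction output and an MSE loss node fed by the
#' plaintext target at `y`.
#'
#' @inheritParams build_sphira
#' @export
build_constellation <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  set.seed(cfg$seed)
  kN <- prod(cfg$kernel_shape)
  kernel <- array(stats::rnorm(kN, sd = 1 / sqrt(kN)), dim = cfg$kernel_shape)
  g <- compgraph()
  add_node(g, "x", node_input())
  add_node(g, "enc_x", node_encrypt())
  add_node(g, "cc", node_cc(kernel, bias = 0, stride = cfg$stride,
                            input_shape = cfg$input_shape))
  T_x <- g$nodes[["cc"]]$node$T_x
  add_edge(g, "x", "enc_x")
  add_edge(g, "enc_x", "cc")
  for (t in seq_len(T_x)) {
    add_node(g, paste0("fold_", t), node_rotate("fold"))
    add_node(g, paste0("sig_w_", t), node_sigmoid())
    add_edge(g, "cc", paste0("fold_", t))
    add_edge(g, paste0("fold_", t), paste0("sig_w_", t))
  }
  w <- stats::rnorm(T_x, sd = 1 / sqrt(T_x))
  add_node(g, "dense", node_dense(w, bias = 0))
  for (t in seq_len(T_x)) add_edge(g, paste0("sig_w_", t), "dense")
  add_node(g, "sig_out", node_sigmoid())
  add_node(g, "dec", node_decrypt())
  add_edge(g, "dense", "sig_out")
  add_edge(g, "sig_out", "dec")
  add_node(g, "yhat", node_output())
  add_edge(g, "dec", "yhat")
  add_node(g, "mse", node_mse())
  add_node(g, "y", node_input())
  add_edge(g, "dec", "mse")
  add_edge(g, "y", "mse")
  g$cfg <- cfg
  g$kind <- "regression"
  g$pred_node <- "yhat"
  g$loss_node <- "mse"
  g$ingress <- c("x", "y")
  groups <- autohe(g, "enc_x")
  assign_parameters(g, groups, scale_power = cfg$scale_power,
                    special_mult = cfg$special_mult)
  g$groups <- groups
  g
}

## one full train step on a single example; weights stay plaintext (only the
## inference path is FHE-compatible; encrypted training is out of scope)
train_step <- function(g, x, y, lr) {
  clear_signals(g)
  neuronal_firing(g, c("x", "y"), list(x, y), c("forward", "forward"))
  loss_node <- g$nodes[[g$loss_node]]$node
  loss <- loss_node$loss
  if (!is.finite(loss))
    stop(fhe_condition("fhe_divergence_error",
                       sprintf("non-finite loss (seed %d): try a lower lr",
                               g$cfg$seed)))
  neuronal_firing(g, g$loss_node, list(1), "backward")
  sgd_update(g, lr)
  loss
}

#' Train a built network
#'
#' Per-example signal firing: the input and label are induced at the graph's
#' ingress nodes, the loss and its gradient are computed plaintext-side at
#' the (post-decryption) loss node, the gradient is fired through the
#' backward receptors, and plain SGD updates the (plaintext) weights.
#'
#' @param g a graph from [build_sphira()] or [build_constellation()].
#' @param x list or array of inputs (images `n x H x W`, windows
#'   `n x T_x x F`).
#' @param y numeric vector of 0-based class labels or regression targets.
#' @param epochs,lr override the graph config.
#' @param lr_decay inverse-time decay rate: the epoch-`t` learning rate is
#'   `lr / (1 + lr_decay * (t - 1))`. Zero (default) keeps it constant;
#'   per-example SGD otherwise plateaus at a gradient-noise floor.
#' @param verbose print per-epoch progress.
#' @return an object of class `fhe_fit` with the graph and per-epoch history
#'   (`loss`, and `accuracy` for classifiers).
#' @export
train <- function(g, x, y, epochs = NULL, lr = NULL, lr_decay = 0,
                  verbose = FALSE) {
  cfg <- g$cfg
  if (is.null(cfg)) stop(fhe_condition("fhe_state_error", "unbuilt graph"))
  epochs <- if (is.null(epochs)) cfg$epochs else epochs
  lr <- if (is.null(lr)) cfg$lr else lr
  xs <- input_list(x)
  n <- length(xs)
  stopifnot(n == length(y))
  set_training(g, TRUE)
  set_encryption(g, FALSE)     # training runs plaintext-side
  on.exit({ set_training(g, FALSE); set_encryption(g, TRUE) })
  hist_loss <- numeric()
  hist_acc <- numeric()
  for (ep in seq_len(epochs)) {
    lr_ep <- lr / (1 + lr_decay * (ep - 1))
    losses <- numeric(n)
    correct <- 0L
    for (i in seq_len(n)) {
      losses[i] <- train_step(g, xs[[i]], y[i], lr_ep)
      if (identical(g$kind, "classification")) {
        p <- g$nodes[[g$pred_node]]$node$last_output
        if (identical(as.integer(p), as.integer(y[i]))) correct <- correct + 1L
      }
    }
    hist_loss[ep] <- mean(losses)
    if (identical(g$kind, "classification")) hist_acc[ep] <- correct / n
    if (verbose)
      message(sprintf("epoch %d: loss %.4f%s", ep, hist_loss[ep],
                      if (length(hist_acc)) sprintf(" acc %.3f", hist_acc[ep])
                      else ""))
    if (!is.null(cfg$early_stop_acc) && identical(g$kind, "classification") &&
        hist_acc[ep] >= cfg$early_stop_acc) break
  }
  history <- data.frame(epoch = seq_along(hist_loss), loss = hist_loss)
  if (identical(g$kind, "classification")) history$accuracy <- hist_acc
  structure(list(graph = g, history = history, cfg = cfg), class = "fhe_fit")
}

input_list <- function(x) {
  if (is.list(x)) return(x)
  if (is.array(x) && length(dim(x)) == 3L)
    return(lapply(seq_len(dim(x)[1L]), function(i) x[i, , ]))
  if (is.matrix(x)) return(lapply(seq_len(nrow(x)), function(i) x[i, ]))
  as.list(x)
}

#' Run inference on a trained graph
#'
#' Plaintext and ciphertext inputs are interchangeable: a plain array is
#' encrypted at the encrypt node when encryption mode is on, while an
#' already-encrypted `ckks_ct` passes through.
#'
#' @param g a built (and usually trained) graph.
#' @param x one input (array, vector, or `ckks_ct`).
#' @param encrypted run the forward pass over ciphertexts (default) or
#'   plaintext.
#' @return predicted 0-based class (classification) or value (regression).
#' @export
infer <- function(g, x, encrypted = TRUE) {
  if (is.null(g$cfg)) stop(fhe_condition("fhe_state_error", "unbuilt graph"))
  set_encryption(g, encrypted)
  clear_signals(g)
  neuronal_firing(g, "x", list(x), "forward")
  out <- g$nodes[[g$pred_node]]$node$last_output
  if (identical(g$kind, "classification")) as.integer(out) else as.numeric(out)
}

#' @export
print.fhe_fit <- function(x, ...) {
  h <- x$history
  last <- h[nrow(h), ]
  cat(sprintf("<fhe_fit: %s, %d epoch(s), final loss %.4f%s>\n",
              x$graph$kind, nrow(h), last$loss,
              if (!is.null(h$accuracy))
                sprintf(", final accuracy %.3f", last$accuracy) else ""))
  invisible(x)
}

#' @export
predict.fhe_fit <- function(object, newdata, encrypted = FALSE, ...) {
  xs <- input_list(newdata)
  vapply(xs, function(xi) as.numeric(infer(object$graph, xi, encrypted)),
         numeric(1))
}

#' @export
plot.fhe_fit <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$loss, type = "b", xlab = "epoch", ylab = "loss",
                 main = "training loss", ...)
  invisible(x)
}

#' Activation-stability experiment
#'
#' Trains the classification network repeatedly from different weight
#' initialisations, once per activation variant, on one fixed synthetic
#' image set, and reports the final training accuracies. The dynamically
#' ranged ReLU approximation backpropagates its own range and can overshoot
#' its polynomial's useful interval, so across initialisations it is less
#' precise (higher accuracy variance, occasional divergence) than the static
#' sigmoid approximation at a comparable mean; a diverged run scores chance
#' accuracy. Defaults pick a regime in which training is non-trivial for
#' both variants.
#'
#' @param dataset an `image_dataset`; defaults to 200 two-class 8x8 images
#'   at pixel noise 0.35.
#' @param seeds weight-initialisation seeds, one run each.
#' @param epochs,lr training schedule applied identically to both variants.
#' @return list with numeric vectors `relu` and `sigmoid` of per-seed final
#'   training accuracies.
#' @export
compare_activation_stability <- function(dataset = NULL, seeds = 1:10,
                                         epochs = 5, lr = 0.2) {
  if (is.null(dataset))
    dataset <- gen_toy_images(200, K = 2, seed = 42, noise_sd = 0.35)
  one <- function(act, s) {
    g <- build_sphira(network_config(
      input_shape = dataset$shape, kernel_shape = c(3, 3), stride = 2,
      n_classes = dataset$K, seed = s, activation = act))
    tryCatch(
      utils::tail(train(g, dataset$images, dataset$labels,
                        epochs = epochs, lr = lr)$history$accuracy, 1),
      fhe_divergence_error = function(e) 1 / dataset$K)
  }
  list(relu = vapply(seeds, function(s) one("relu", s), numeric(1)),
       sigmoid = vapply(seeds, function(s) one("sigmoid", s), numeric(1)))
}
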