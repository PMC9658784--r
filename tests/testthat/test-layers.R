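# FHE-compatible layers: masquerading, convolution, dense, activations,
# losses and the prediction circuit

test_that("masquerade places the kernel at the window offset, zeros elsewhere", {
  k <- matrix(1:4, 2, 2)
  m <- masquerade(k, c(3, 3), c(0, 0))
  expect_equal(m[1:2, 1:2], k)
  expect_equal(sum(m != 0), 4)
  m2 <- masquerade(k, c(3, 3), c(1, 1))
  expect_equal(m2[2:3, 2:3], k)
  expect_equal(m2[1, ], rep(0, 3))
  expect_error(masquerade(k, c(3, 3), c(2, 2)), class = "fhe_shape_error")
  expect_error(masquerade(k, c(3, 3), c(-1, 0)), class = "fhe_shape_error")
})

test_that("window counts follow valid placement with stride", {
  n1 <- node_cc(matrix(1, 2, 2), stride = 1, input_shape = c(3, 3))
  expect_equal(n1$T_x, 4L)                       # (3-2)/1+1 squared
  n2 <- node_cc(matrix(1, 2, 2), stride = 2, input_shape = c(4, 4))
  expect_equal(n2$T_x, 4L)                       # halved resolution
})

test_that("commuted bias makes the fold-sum reproduce sum(x*w) + b", {
  # one 4-long window, w = 1, b = 4: slots carry x_i*w_i + b/N = x_i + 1
  nd <- node_cc(array(c(1, 1, 1, 1), dim = 4), bias = 4, stride = 1,
                input_shape = 4)
  gen <- node_forward(nd, c(1, 2, 3, 4))
  out <- fhenet:::gen_next(gen)
  expect_equal(out, c(2, 3, 4, 5))
  expect_equal(sum(out), 14)                     # = sum(x*w) + b
})

test_that("masqueraded + folded convolution equals the direct oracle", {
  set.seed(11)
  for (case in 1:30) {
    H <- sample(4:7, 1); W <- sample(4:7, 1)
    kh <- sample(2:3, 1); kw <- sample(2:3, 1)
    st <- c(sample(1:2, 1), sample(1:2, 1))
    input <- matrix(stats::rnorm(H * W), H, W)
    kern <- matrix(stats::rnorm(kh * kw), kh, kw)
    b <- stats::rnorm(1)
    nd <- node_cc(kern, bias = b, stride = st, input_shape = c(H, W))
    gen <- node_forward(nd, input)
    got <- vapply(seq_len(nd$T_x),
                  function(t) sum(fhenet:::gen_next(gen)), numeric(1))
    expect_equal(got, direct_cross_correlation(input, kern, st, b),
                 tolerance = 1e-12)
  }
})

test_that("the convolution oracle holds over ciphertexts too", {
  set.seed(12)
  p <- parameterise_ckks(1)
  input <- matrix(stats::rnorm(16), 4, 4)
  kern <- matrix(stats::rnorm(4), 2, 2)
  nd <- node_cc(kern, bias = 0.5, stride = 2, input_shape = c(4, 4))
  ct <- encrypt(fhenet:::flatten_rm(input), p)
  gen <- node_forward(nd, ct)
  got <- vapply(seq_len(nd$T_x),
                function(t) decrypt(fold_sum(fhenet:::gen_next(gen))),
                numeric(1))
  expect_equal(got, direct_cross_correlation(input, kern, c(2, 2), 0.5),
               tolerance = 1e-12)
})

test_that("each node's declared cost equals the levels its forward consumes", {
  p <- parameterise_ckks(4)
  lvl <- function(ct) length(ct$chain_remaining)
  x <- encrypt(c(0.3, -0.2, 0.5, 0.1), p)
  cc <- node_cc(matrix(1, 2, 2), stride = 2, input_shape = c(2, 2))
  out <- fhenet:::gen_next(node_forward(cc, x))
  expect_equal(lvl(x) - lvl(out), node_cost(cc))
  dn <- node_dense(rep(0.5, 4))
  expect_equal(lvl(x) - lvl(node_forward(dn, x)), node_cost(dn))
  dn2 <- node_dense(c(0.5, 0.5))
  out2 <- node_forward(dn2, list(x, x))
  expect_equal(lvl(x) - lvl(out2), node_cost(dn2))
  rl <- node_relu()
  expect_equal(lvl(x) - lvl(node_forward(rl, x)), node_cost(rl))
  sg <- node_sigmoid()
  expect_equal(lvl(x) - lvl(node_forward(sg, x)), node_cost(sg))
  rt <- node_rotate("fold")
  expect_equal(lvl(node_forward(rt, x)), lvl(x))   # rotation costs nothing
})

test_that("convolution gradients match central finite differences", {
  set.seed(21)
  input <- matrix(stats::rnorm(16), 4, 4)
  kern0 <- matrix(stats::rnorm(4), 2, 2)
  b0 <- 0.3
  st <- c(1, 1)
  # scalar objective: sum over windows of (fold of window output)^2
  obj <- function(kv, bias, x = input) {
    nd <- node_cc(matrix(kv, 2, 2), bias = bias, stride = st,
                  input_shape = c(4, 4))
    gen <- node_forward(nd, x)
    sum(vapply(seq_len(nd$T_x),
               function(t) sum(fhenet:::gen_next(gen))^2, numeric(1)))
  }
  nd <- node_cc(kern0, bias = b0, stride = st, input_shape = c(4, 4))
  gen <- node_forward(nd, input)
  folds <- vapply(seq_len(nd$T_x),
                  function(t) sum(fhenet:::gen_next(gen)), numeric(1))
  grads <- lapply(seq_len(nd$T_x),
                  function(t) rep(2 * folds[t], 16))   # dL/d(out slots)
  dx <- node_backward(nd, grads)
  gk <- num_grad(function(kv) obj(kv, b0), as.numeric(kern0))
  expect_equal(as.numeric(nd$grad_kernel), gk, tolerance = 1e-4)
  gb <- (obj(as.numeric(kern0), b0 + 1e-5) - obj(as.numeric(kern0), b0 - 1e-5)) / 2e-5
  expect_equal(nd$grad_bias, gb, tolerance = 1e-4)
  gx <- num_grad(function(xv) obj(as.numeric(kern0), b0,
                                  x = matrix(xv, 4, 4, byrow = FALSE)),
                 as.numeric(input))
  ## dx is in row-major slot order; compare against column-major num_grad
  dx_cm <- as.numeric(matrix(dx, 4, 4, byrow = TRUE))
  expect_equal(dx_cm, gx, tolerance = 1e-4)
  # zero gradients leave zero updates
  nd2 <- node_cc(kern0, bias = b0, stride = st, input_shape = c(4, 4))
  gen <- node_forward(nd2, input)
  for (t in seq_len(nd2$T_x)) fhenet:::gen_next(gen)
  node_backward(nd2, lapply(seq_len(nd2$T_x), function(t) numeric(16)))
  expect_true(all(nd2$grad_kernel == 0) && nd2$grad_bias == 0)
})

test_that("backward without a cached forward is a state error", {
  nd <- node_cc(matrix(1, 2, 2), stride = 1, input_shape = c(3, 3))
  expect_error(node_backward(nd, list(numeric(9))), class = "fhe_state_error")
})

test_that("dense forward sums weighted branches with commuted bias", {
  dn <- node_dense(c(1, 1), bias = 2)
  # two scalar branches: z = (3*1 + 1) + (4*1 + 1) = 9
  expect_equal(node_forward(dn, list(3, 4)), 9)
  dnv <- node_dense(rep(1, 4), bias = 4)
  # packed input: un-summed x*w + b/N; a fold completes the affine map
  v <- node_forward(dnv, c(1, 2, 3, 4))
  expect_equal(v, c(2, 3, 4, 5))
  expect_equal(sum(v), sum(c(1, 2, 3, 4)) + 4)
  expect_error(node_forward(node_dense(c(1, 1)), list(1, 2, 3)),
               class = "fhe_shape_error")
  expect_error(node_forward(node_dense(c(1, 1)),
                            list(c(1, 2), c(1, 2, 3))),
               class = "fhe_shape_error")
})

test_that("dense gradients match finite differences (sequence and packed)", {
  set.seed(31)
  xs <- list(0.7, -0.4, 1.2)
  w0 <- stats::rnorm(3); b0 <- 0.2
  obj_seq <- function(w, b) {
    nd <- node_dense(w, b)
    node_forward(nd, xs)^2
  }
  nd <- node_dense(w0, b0)
  z <- node_forward(nd, xs)
  gen <- node_backward(nd, 2 * z)
  expect_equal(nd$grad_w, num_grad(function(w) obj_seq(w, b0), w0),
               tolerance = 1e-4)
  gb <- (obj_seq(w0, b0 + 1e-5) - obj_seq(w0, b0 - 1e-5)) / 2e-5
  expect_equal(nd$grad_bias, gb, tolerance = 1e-4)
  # upstream gradients are distributed per branch: dL/dx_i = g * w_i
  gxs <- vapply(1:3, function(i) fhenet:::gen_next(gen), numeric(1))
  gx_num <- num_grad(function(x) {
    nd2 <- node_dense(w0, b0); node_forward(nd2, as.list(x))^2
  }, unlist(xs))
  expect_equal(gxs, gx_num, tolerance = 1e-4)

  x0 <- stats::rnorm(4); w4 <- stats::rnorm(4)
  obj_packed <- function(w, b, x = x0) {
    nd <- node_dense(w, b); sum(node_forward(nd, x))^2
  }
  nd4 <- node_dense(w4, 0.1)
  z4 <- node_forward(nd4, x0)
  g <- rep(2 * sum(z4), 4)
  dx <- node_backward(nd4, g)
  expect_equal(nd4$grad_w, num_grad(function(w) obj_packed(w, 0.1), w4),
               tolerance = 1e-4)
  expect_equal(dx, num_grad(function(x) obj_packed(w4, 0.1, x), x0),
               tolerance = 1e-4)
})

test_that("ReLU approximation evaluates its closed form", {
  expect_equal(relu_approx(0, 1), 1 / (3 * pi))
  expect_equal(relu_approx(1, 1), 5 / (3 * pi) + 0.5)
  expect_equal(relu_approx_derivative(0, 1), 0.5)
  # positivity at the range edges
  for (q in c(0.5, 1, 3)) {
    expect_gt(relu_approx(q, q), 0)
    expect_gt(relu_approx(-q, q), 0)
  }
  expect_error(relu_approx(1, 0), class = "fhe_value_error")
  expect_error(relu_approx_derivative(1, -1), class = "fhe_value_error")
})

test_that("ReLU derivative matches numerical differentiation within 1e-6", {
  xs <- seq(-2, 2, length.out = 41)
  for (q in c(0.5, 1, 2)) {
    num <- (relu_approx(xs + 1e-6, q) - relu_approx(xs - 1e-6, q)) / 2e-6
    expect_equal(relu_approx_derivative(xs, q), num, tolerance = 1e-6)
  }
  # slope of the quadratic term doubles when q halves
  d1 <- relu_approx_derivative(1, 1) - 0.5
  d2 <- relu_approx_derivative(1, 0.5) - 0.5
  expect_equal(d2, 2 * d1)
})

test_that("ReLU approximation error is largest at 0 and grows beyond q", {
  # frozen regression constant: max |Ra - R| on [-q, q] equals q/(3*pi)
  for (q in c(0.5, 1, 2)) {
    xs <- seq(-q, q, length.out = 10001)
    err <- max(abs(relu_approx(xs, q) - relu_exact(xs)))
    expect_equal(err, q * 0.1061032954, tolerance = 1e-8)
  }
  # monotone growth in |x| beyond the range
  q <- 1
  beyond <- seq(1, 3, length.out = 50)
  errs <- abs(relu_approx(beyond, q) - relu_exact(beyond))
  expect_true(all(diff(errs) > 0))
})

test_that("dynamic range tracking converges to the batch magnitude", {
  nd <- node_relu(q = 1, alpha = 0.1)
  for (i in 1:200) relu_range_update(nd, c(-3, 2))
  expect_equal(nd$q, 3, tolerance = 1e-6)
  nd1 <- node_relu(q = 1, alpha = 1)
  relu_range_update(nd1, c(0.5, -4))
  expect_equal(nd1$q, 4)
  nd0 <- node_relu(q = 1, alpha = 0)
  relu_range_update(nd0, c(100))
  expect_equal(nd0$q, 1)
})

test_that("sigmoid approximation matches its pinned values and derivative", {
  expect_identical(sigmoid_approx(0), 0.5)
  expect_equal(sigmoid_approx(1), 0.693)
  xs <- seq(-5, 5, length.out = 101)
  num <- (sigmoid_approx(xs + 1e-6) - sigmoid_approx(xs - 1e-6)) / 2e-6
  expect_equal(sigmoid_approx_derivative(xs), num, tolerance = 1e-6)
  # frozen regression constant: max |sigmoid - approx| on [-5, 5]
  grid <- seq(-5, 5, length.out = 10001)
  expect_equal(max(abs(sigmoid_exact(grid) - sigmoid_approx(grid))),
               0.0510309834, tolerance = 1e-8)
})

test_that("activation nodes gradient-check through their receptors", {
  set.seed(41)
  x0 <- stats::rnorm(5)
  for (mk in list(function() node_relu(q = 1.3),
                  function() node_sigmoid())) {
    nd <- mk()
    y <- node_forward(nd, x0)
    g <- 2 * y
    dx <- node_backward(nd, g)
    num <- num_grad(function(x) {
      nd2 <- mk(); sum(node_forward(nd2, x)^2)
    }, x0)
    expect_equal(dx, num, tolerance = 1e-4)
  }
})

test_that("softmax is a stabilised probability map, plaintext-only", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(sum(softmax(stats::rnorm(10))), 1)
  expect_equal(softmax(rep(3, 10)), rep(0.1, 10))
  a <- c(1, 2, 3)
  expect_equal(softmax(a + 100), softmax(a))       # shift invariance
  expect_equal(softmax(c(1000, 0)), c(1, 0))       # no overflow
  ct <- encrypt(1:3, parameterise_ckks(0))
  expect_error(softmax(ct), class = "fhe_compat_error")
})

test_that("cross-entropy loss and combined gradient behave as closed forms", {
  y <- onehot_encode(2, 10)
  expect_equal(cce_loss(y, y)$loss, 0, tolerance = 1e-9)
  u <- rep(0.1, 10)
  expect_equal(cce_loss(u, y)$loss, log(10))
  expect_equal(cce_loss(u, y)$grad, u - y)
  # gradient of -sum(y*log(softmax(a))) wrt a is softmax(a) - y
  a <- c(0.3, -1, 0.8)
  y3 <- onehot_encode(1, 3)
  num <- num_grad(function(v) cce_loss(softmax(v), y3)$loss, a)
  expect_equal(softmax(a) - y3, num, tolerance = 1e-6)
  expect_warning(cce_loss(c(0.5, 0.2), c(1, 0)), "sum to 1")
})

test_that("mse loss and gradient", {
  expect_equal(mse_loss(c(1, 2), c(1, 2))$loss, 0)
  expect_equal(mse_loss(3, 1)$loss, 4)
  expect_equal(mse_loss(3, 1)$grad, 4)
  yh <- c(0.2, 0.8); y <- c(0, 1)
  num <- num_grad(function(v) mse_loss(v, y)$loss, yh)
  expect_equal(mse_loss(yh, y)$grad, num, tolerance = 1e-6)
  expect_error(mse_loss(1:3, 1:2), class = "fhe_shape_error")
})

test_that("prediction circuit: argmax one-hot with low-index ties", {
  expect_equal(argmax_onehot(c(0.1, 0.7, 0.2)), c(0, 1, 0))
  expect_equal(onehot_decode(argmax_onehot(c(0.1, 0.7, 0.2))), 1L)
  expect_equal(argmax_onehot(c(0.5, 0.5)), c(1, 0))   # tie -> lowest index
  for (k in 0:4) expect_equal(onehot_decode(onehot_encode(k, 5)), k)
  ct <- encrypt(1:3, parameterise_ckks(0))
  expect_error(argmax_onehot(ct), class = "fhe_compat_error")
})

test_that("mape follows its definition and rejects zero targets", {
  expect_equal(mape(c(1, 2), c(1, 2)), 0)
  expect_equal(mape(100, 90), 10)
  expect_equal(mape(c(50, 200), c(55, 180)), 10)
  expect_error(mape(c(0, 1), c(1, 1)), class = "fhe_value_error")
})
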