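# shared fixtures: tiny graphs and generators used across test files

# chain A -> B -> C with supplied forward functions
make_chain <- function(fns, costs = rep(0L, length(fns))) {
  g <- compgraph()
  nms <- paste0("n", seq_along(fns))
  for (i in seq_along(fns))
    add_node(g, nms[i], node_generic(costs[i], fns[[i]]))
  for (i in seq_len(length(fns) - 1L)) add_edge(g, nms[i], nms[i + 1L])
  g
}

# diamond A -> (B, C) -> D, with an activation counter on every node
make_diamond <- function() {
  g <- compgraph()
  counters <- new.env()
  mk <- function(nm, fn = identity) {
    counters[[nm]] <- 0L
    node_generic(0L, function(s) {
      counters[[nm]] <- counters[[nm]] + 1L
      fn(s)
    })
  }
  add_node(g, "A", mk("A"))
  add_node(g, "B", mk("B", function(s) s + 1))
  add_node(g, "C", mk("C", function(s) s * 2))
  add_node(g, "D", mk("D", function(s) s))   # receives list(B, C)
  add_edge(g, "A", "B"); add_edge(g, "A", "C")
  add_edge(g, "B", "D"); add_edge(g, "C", "D")
  attr(g, "counters") <- counters
  g
}

# the two-source / rotation-sink parameterisation example: x1 passes two
# unit-cost computations, x0 joins at the second, r0 rotates, s0 decrypts
make_meeting_graph <- function() {
  g <- compgraph()
  add_node(g, "x0", node_encrypt())
  add_node(g, "x1", node_encrypt())
  add_node(g, "c0", node_generic(1L))
  add_node(g, "c1", node_generic(1L))
  add_node(g, "r0", node_rotate("refresh"))
  add_node(g, "s0", node_decrypt())
  add_edge(g, "x1", "c0"); add_edge(g, "c0", "c1")
  add_edge(g, "x0", "c1"); add_edge(g, "c1", "r0")
  add_edge(g, "r0", "s0")
  g
}

# random acyclic multi-directed graph over a topological node order;
# a few nodes are rotation boundaries, costs in 0..3, up to 3 parallel edges
random_mdg <- function(seed, max_nodes = 12L) {
  set.seed(seed)
  n_src <- sample(1:2, 1L)
  n <- sample((n_src + 3L):max_nodes, 1L)
  g <- compgraph()
  nms <- paste0("v", seq_len(n))
  types <- c(rep("src", n_src),
             sample(c("comp", "comp", "comp", "rot"), n - n_src,
                    replace = TRUE))
  for (i in seq_len(n)) {
    nd <- switch(types[i],
                 src = node_encrypt(),
                 comp = node_generic(sample(0:3, 1L)),
                 rot = node_rotate("refresh"))
    add_node(g, nms[i], nd)
  }
  ## edges respect the topological order (acyclic); every non-source node
  ## has at least one parent; up to 3 parallel edges per pair
  for (j in (n_src + 1L):n) {
    parents <- sample(seq_len(j - 1L), min(j - 1L, sample(1:3, 1L)))
    for (i in parents) {
      mult <- sample(1:3, 1L, prob = c(0.8, 0.15, 0.05))
      for (q in seq_len(mult)) add_edge(g, nms[i], nms[j])
    }
  }
  list(g = g, sources = nms[seq_len(n_src)])
}

# central finite differences of a scalar-valued function
num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# direct valid cross-correlation oracle (independent of the masquerade path)
direct_cross_correlation <- function(input, kernel, stride, bias = 0) {
  ind <- dim(input); kd <- dim(kernel)
  offs_r <- seq(0, ind[1] - kd[1], by = stride[1])
  offs_c <- seq(0, ind[2] - kd[2], by = stride[2])
  out <- numeric(0)
  for (r in offs_r) for (cc in offs_c) {
    patch <- input[r + seq_len(kd[1]), cc + seq_len(kd[2]), drop = FALSE]
    out <- c(out, sum(patch * kernel) + bias)
  }
  out
}

mini_sphira_cfg <- function(seed = 42, activation = "relu", ...) {
  network_config(input_shape = c(8, 8), kernel_shape = c(3, 3), stride = 2,
                 n_classes = 2, seed = seed, activation = activation, ...)
}

mini_constellation_cfg <- function(seed = 42, ...) {
  network_config(input_shape = c(14, 12), kernel_shape = c(3, 12),
                 stride = 1, seed = seed, ...)
}
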