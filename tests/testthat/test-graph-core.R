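# signal propagation over multi-directed graphs

test_that("a single node fires once on its bootstrap signal", {
  seen <- new.env()
  g <- compgraph()
  add_node(g, "A", node_generic(0L, function(s) { seen$x <- s; s * 2 }))
  neuronal_firing(g, "A", list(3), "forward")
  expect_equal(seen$x, 3)
  expect_equal(g$nodes[["A"]]$node$last_output, 6)
})

test_that("a chain composes its receptor functions in order", {
  g <- make_chain(list(identity, function(s) s + 1, function(s) s * 10))
  neuronal_firing(g, "n1", list(2), "forward")
  # n3 receives f2(f1(2)) = (2 + 1) * 10
  expect_equal(g$nodes[["n3"]]$node$last_output, 30)
})

test_that("unknown node names and receptors raise typed errors", {
  g <- make_chain(list(identity))
  expect_error(neuronal_firing(g, "ghost", list(1), "forward"),
               class = "fhe_name_error")
  expect_error(neuronal_firing(g, "n1", list(1), "sideways"),
               class = "fhe_receptor_error")
})

test_that("a node with an incomplete inbound set is a silent no-op", {
  g <- compgraph()
  add_node(g, "A", node_generic())
  add_node(g, "B", node_generic())
  add_node(g, "D", node_generic(0L, function(s) Reduce(`+`, s)))
  add_edge(g, "A", "D"); add_edge(g, "B", "D")
  neuronal_firing(g, "A", list(1), "forward")
  expect_null(g$nodes[["D"]]$node$last_output)
  neuronal_firing(g, "B", list(10), "forward")
  expect_equal(g$nodes[["D"]]$node$last_output, 11)
})

test_that("diamond topology activates the join node exactly once", {
  g <- make_diamond()
  neuronal_firing(g, "A", list(5), "forward")
  cnt <- attr(g, "counters")
  expect_equal(cnt$A, 1L)
  expect_equal(cnt$B, 1L)
  expect_equal(cnt$C, 1L)
  expect_equal(cnt$D, 1L)
  # D's input is the ordered pair (B out, C out) regardless of firing path
  expect_equal(g$nodes[["D"]]$node$last_output, list(5 + 1, 5 * 2))
})

test_that("multi-edge inputs stack in edge insertion order", {
  g <- compgraph()
  add_node(g, "A", node_generic())
  add_node(g, "B", node_generic(0L, function(s) s * 100))
  add_node(g, "D", node_generic(0L, function(s) s))
  # two parallel A->D edges plus a B->D edge, in a fixed insertion order
  add_edge(g, "A", "D"); add_edge(g, "B", "D"); add_edge(g, "A", "D")
  neuronal_firing(g, c("A", "B"), list(1, 2), c("forward", "forward"))
  expect_equal(g$nodes[["D"]]$node$last_output, list(1, 200, 1))
})

test_that("single in-edge signals are unwrapped, not length-1 lists", {
  g <- make_chain(list(identity, function(s) {
    expect_false(is.list(s))
    s
  }))
  neuronal_firing(g, "n1", list(7), "forward")
  expect_equal(g$nodes[["n2"]]$node$last_output, 7)
})

test_that("generators distribute per-edge and broadcast otherwise", {
  g <- compgraph()
  add_node(g, "S", node_generic(0L, function(s) signal_generator(list(s, s * 10))))
  add_node(g, "E1", node_generic()); add_node(g, "E2", node_generic())
  add_edge(g, "S", "E1"); add_edge(g, "S", "E2")
  neuronal_firing(g, "S", list(2), "forward")
  expect_equal(g$nodes[["E1"]]$node$last_output, 2)
  expect_equal(g$nodes[["E2"]]$node$last_output, 20)

  gb <- compgraph()
  add_node(gb, "S", node_generic())
  add_node(gb, "E1", node_generic()); add_node(gb, "E2", node_generic())
  add_node(gb, "E3", node_generic())
  for (e in c("E1", "E2", "E3")) add_edge(gb, "S", e)
  neuronal_firing(gb, "S", list(4), "forward")
  for (e in c("E1", "E2", "E3"))
    expect_equal(gb$nodes[[e]]$node$last_output, 4)
})

test_that("an exhausted generator raises an arity error", {
  g <- compgraph()
  add_node(g, "S", node_generic(0L, function(s) signal_generator(list(s))))
  add_node(g, "E1", node_generic()); add_node(g, "E2", node_generic())
  add_edge(g, "S", "E1"); add_edge(g, "S", "E2")
  expect_error(neuronal_firing(g, "S", list(1), "forward"),
               class = "fhe_arity_error")
})

test_that("consumed signals clear so a second pass starts clean", {
  g <- make_chain(list(identity, identity))
  neuronal_firing(g, "n1", list(1), "forward")
  e <- g$edges[[1]]
  expect_null(e$signals[["forward"]])
  # second pass works identically
  neuronal_firing(g, "n1", list(2), "forward")
  expect_equal(g$nodes[["n2"]]$node$last_output, 2)
})

test_that("edge weight equals the directed-to node's cost", {
  g <- compgraph()
  add_node(g, "A", node_generic(0L))
  add_node(g, "B", node_generic(3L))
  add_edge(g, "A", "B")
  expect_equal(g$edges[[1]]$weight, 3L)
})

test_that("self-loops pass untreated while non-self cycles error", {
  g <- compgraph()
  add_node(g, "A", node_generic())
  add_edge(g, "A", "A")
  expect_silent(neuronal_firing(g, "A", list(1), "forward"))

  g2 <- compgraph()
  add_node(g2, "A", node_generic())
  add_node(g2, "B", node_generic())
  add_edge(g2, "A", "B"); add_edge(g2, "B", "A")
  expect_error(neuronal_firing(g2, "A", list(1), "forward"),
               class = "fhe_cycle_error")
})

test_that("duplicate node names and edge keys are rejected", {
  g <- compgraph()
  add_node(g, "A", node_generic())
  expect_error(add_node(g, "A", node_generic()), "already present")
  add_node(g, "B", node_generic())
  add_edge(g, "A", "B", key = "k")
  expect_error(add_edge(g, "A", "B", key = "k"), "duplicate edge key")
  expect_silent(add_edge(g, "A", "B"))   # auto-keyed parallel edge
})

test_that("two firings of the same graph produce identical activation traces", {
  run <- function() {
    g <- make_diamond()
    trace_firing(g)
    neuronal_firing(g, "A", list(1.5), "forward")
    g$trace
  }
  expect_identical(run(), run())
})

test_that("errors inside a receptor carry the node name as context", {
  g <- make_chain(list(identity, function(s) stop("boom")))
  expect_error(neuronal_firing(g, "n1", list(1), "forward"), "\\[node n2\\]")
})

test_that("nodes can expose extra receptors through the registry", {
  seen <- new.env()
  nd <- node_generic(0L, identity)
  nd$receptors <- list(pulse = function(node, s) { seen$x <- s * 100; NULL })
  g <- compgraph()
  add_node(g, "A", nd)
  neuronal_firing(g, "A", list(2), "pulse")
  expect_equal(seen$x, 200)
})

test_that("backend plugins must satisfy the full operation contract", {
  ok <- replicate(7, function(...) NULL)
  names(ok) <- c("encrypt", "decrypt", "add", "multiply", "relinearise",
                 "rescale", "refresh")
  expect_s3_class(fhe_backend(as.list(ok)), "fhe_backend")
  expect_error(fhe_backend(as.list(ok)[-1]), class = "fhe_value_error")
})
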