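#' Multi-directed computation graphs
#'
#' A `compgraph` is a mutable (environment-backed) multi-directed graph whose
#' nodes are computational objects ("neurons") and whose edges carry signals
#' between them. Parallel edges between the same pair of nodes are distinct
#' entities with independent signal slots. Each edge's weight equals the
#' multiplicative-depth cost of the node it points *to*, so that longest-path
#' analysis over edge weights yields the depth a ciphertext experiences.
#'
#' @return An empty graph of class `compgraph`.
#' @export
compgraph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()       # name -> list(node = <fhe_node env>, meta = <env>)
  g$node_order <- character()
  g$edges <- list()       # edge envs, insertion order
  g$in_idx <- list()      # name -> integer vector of edge indices
  g$out_idx <- list()
  g$trace <- NULL         # optional activation log
  class(g) <- "compgraph"
  g
}

#' @export
print.compgraph <- function(x, ...) {
  cat(sprintf("<compgraph: %d nodes, %d edges>\n",
              length(x$nodes), length(x$edges)))
  invisible(x)
}

#' @export
summary.compgraph <- function(object, ...) {
  types <- vapply(object$nodes, function(rec) class(rec$node)[1], character(1))
  cat(sprintf("compgraph with %d nodes, %d edges\n",
              length(object$nodes), length(object$edges)))
  print(table(types))
  invisible(object)
}

#' Add a node to a computation graph
#'
#' @param g a `compgraph`.
#' @param name unique node name.
#' @param node a node object created by one of the `node_*()` constructors.
#' @export
add_node <- function(g, name, node) {
  stopifnot(inherits(g, "compgraph"), is.character(name), length(name) == 1L)
  if (name %in% g$node_order)
    stop("node name already present: ", name, call. = FALSE)
  if (!inherits(node, "fhe_node"))
    stop("'node' must be an fhe_node object", call. = FALSE)
  meta <- new.env(parent = emptyenv())
  meta$sources <- NULL
  g$nodes[[name]] <- list(node = node, meta = meta)
  g$node_order <- c(g$node_order, name)
  g$in_idx[[name]] <- integer()
  g$out_idx[[name]] <- integer()
  invisible(g)
}

#' Add a directed edge
#'
#' The edge weight is set to the destination node's multiplicative-depth cost.
#' Parallel edges are allowed and kept distinct; `key` defaults to the next
#' free integer for the (src, dst) pair.
#'
#' @param g a `compgraph`.
#' @param src,dst node names.
#' @param key optional edge key, unique per (src, dst) pair.
#' @export
add_edge <- function(g, src, dst, key = NULL) {
  for (nm in c(src, dst))
    if (!nm %in% g$node_order) stop("unknown node: ", nm, call. = FALSE)
  existing <- intersect(g$out_idx[[src]], g$in_idx[[dst]])
  keys <- vapply(g$edges[existing], function(e) e$key, character(1))
  if (is.null(key)) {
    key <- as.character(length(existing))
  } else {
    key <- as.character(key)
    if (key %in% keys)
      stop("duplicate edge key for (", src, ", ", dst, "): ", key, call. = FALSE)
  }
  e <- new.env(parent = emptyenv())
  e$src <- src
  e$dst <- dst
  e$key <- key
  e$weight <- node_cost(g$nodes[[dst]]$node)
  e$signals <- list()     # receptor name -> signal (or absent)
  i <- length(g$edges) + 1L
  g$edges[[i]] <- e
  g$out_idx[[src]] <- c(g$out_idx[[src]], i)
  g$in_idx[[dst]] <- c(g$in_idx[[dst]], i)
  g$ecache <- NULL
  invisible(g)
}

## Per-node adjacency cache (graphs are static once built; invalidated by
## add_edge). Holds traversal edge lists, their backprop-eligible subsets and
## successor/predecessor name vectors.
edge_cache <- function(g) {
  if (!is.null(g$ecache)) return(g$ecache)
  ec <- new.env(parent = emptyenv())
  bp <- vapply(g$node_order,
               function(nm) node_backprop(g$nodes[[nm]]$node), logical(1))
  names(bp) <- g$node_order
  for (nm in g$node_order) {
    ins <- Filter(function(e) e$src != e$dst, g$edges[g$in_idx[[nm]]])
    outs <- Filter(function(e) e$dst != e$src, g$edges[g$out_idx[[nm]]])
    ins_bp <- Filter(function(e) bp[[e$src]], ins)
    outs_bp <- Filter(function(e) bp[[e$dst]], outs)
    ec[[nm]] <- list(
      ins = ins, outs = outs, ins_bp = ins_bp, outs_bp = outs_bp,
      succ = unique(vapply(outs, function(e) e$dst, character(1))),
      pred = unique(vapply(ins, function(e) e$src, character(1))),
      pred_bp = unique(vapply(ins_bp, function(e) e$src, character(1))))
  }
  g$ecache <- ec
  ec
}

## Edge accessors (insertion order). Self-loop edges are excluded from
## traversal: the node's own configuration handles loop termination.
in_edges <- function(g, n, include_self = FALSE) {
  es <- g$edges[g$in_idx[[n]]]
  if (!include_self) es <- Filter(function(e) e$src != e$dst, es)
  es
}

out_edges <- function(g, n, include_self = FALSE) {
  es <- g$edges[g$out_idx[[n]]]
  if (!include_self) es <- Filter(function(e) e$dst != e$src, es)
  es
}

#' @rdname add_edge
#' @param n a node name.
#' @export
successors <- function(g, n) edge_cache(g)[[n]]$succ

#' @rdname add_edge
#' @export
predecessors <- function(g, n) edge_cache(g)[[n]]$pred

#' Clear all edge signals
#'
#' @param g a `compgraph`.
#' @export
clear_signals <- function(g) {
  for (e in g$edges) e$signals <- list()
  invisible(g)
}

## ---------------------------------------------------------------------------
## Signal generators: a node may return a generator so each successor edge
## receives an independent value (in edge order) instead of a broadcast.

#' Construct a signal generator
#'
#' @param items list of values handed out one per successor edge, in order.
#' @export
signal_generator <- function(items) {
  gen <- new.env(parent = emptyenv())
  gen$items <- items
  gen$i <- 0L
  class(gen) <- "signal_generator"
  gen
}

is_generator <- function(x) inherits(x, "signal_generator")

gen_next <- function(gen) {
  gen$i <- gen$i + 1L
  if (gen$i > length(gen$items))
    stop(fhe_condition("fhe_arity_error",
                       "signal generator exhausted before all out-edges were served"))
  gen$items[[gen$i]]
}

## ---------------------------------------------------------------------------
## Neuronal firing (depth-first, blocking, node-centric propagation)

## Backward signals flow against edge direction: when firing the "backward"
## receptor, signals are gathered from a node's out-edges and emitted onto its
## in-edges, and recursion visits predecessors. Edges whose far endpoint does
## not participate in backprop (prediction branch, label encoders) are skipped
## in the backward direction so the loss gradient is never blocked waiting on
## a branch that by construction produces none.
gather_edges <- function(g, n, r) {
  ec <- edge_cache(g)[[n]]
  if (identical(r, "backward")) ec$outs_bp else ec$ins
}

emit_edges <- function(g, n, r) {
  ec <- edge_cache(g)[[n]]
  if (identical(r, "backward")) ec$ins_bp else ec$outs
}

next_nodes <- function(g, n, r) {
  ec <- edge_cache(g)[[n]]
  if (identical(r, "backward")) ec$pred_bp else ec$succ
}

#' Fire a computation graph
#'
#' Sequentially stimulates the named nodes with the given signals on the given
#' receptors, propagating each signal depth-first through the graph. A node
#' activates only once all its gathered edges carry data; incomplete nodes are
#' silently skipped (they activate later, when the remaining signals arrive).
#'
#' @param g a `compgraph`, modified in place.
#' @param n character vector of node names.
#' @param s list of signals (one per node).
#' @param r character vector of receptor names ("forward" or "backward").
#' @return the stimulated graph, invisibly.
#' @export
neuronal_firing <- function(g, n, s, r) {
  if (!is.list(s)) s <- list(s)
  if (length(n) != length(s) || length(n) != length(r))
    stop("n, s and r must have equal length", call. = FALSE)
  for (i in seq_along(n)) signal_carrier(g, n[[i]], r[[i]], s[[i]])
  invisible(g)
}

#' Propagate a single signal from one node
#'
#' @param g a `compgraph`.
#' @param n node name at which to start.
#' @param r receptor name.
#' @param bootstrap optional signal injected directly into the node,
#'   bypassing edge gathering (used for ingress nodes and loss seeding).
#' @export
signal_carrier <- function(g, n, r, bootstrap = NULL) {
  .signal_carrier(g, n, r, bootstrap, path = character())
}

.signal_carrier <- function(g, n, r, bootstrap, path) {
  if (!n %in% g$node_order)
    stop(fhe_condition("fhe_name_error", paste0("unknown node: ", n)))
  if (n %in% path)
    stop(fhe_condition("fhe_cycle_error",
                       paste0("cycle detected during traversal at node: ", n)))
  s <- get_inbound_signal(g, n, r, bootstrap)
  if (is.null(s)) return(invisible(NULL))
  s2 <- apply_signal(g, n, r, s)
  ## consume inbound signals so the next pass starts clean
  if (is.null(bootstrap))
    for (e in gather_edges(g, n, r)) e$signals[[r]] <- NULL
  if (is.null(s2)) return(invisible(NULL))
  if (!is.null(g$trace)) g$trace[[length(g$trace) + 1L]] <- c(n, r)
  set_outbound_signals(g, n, r, s2)
  for (succ in next_nodes(g, n, r))
    .signal_carrier(g, succ, r, NULL, c(path, n))
  invisible(NULL)
}

#' Accumulate the inbound signal of a node
#'
#' Returns `bootstrap` when given; otherwise the single gathered edge's signal
#' unwrapped, or the ordered list of all gathered signals, or `NULL` when any
#' gathered edge lacks a signal (the blocking rule: a node activates only when
#' all predecessor edges carry data).
#'
#' @inheritParams signal_carrier
#' @export
get_inbound_signal <- function(g, n, r, bootstrap = NULL) {
  if (!is.null(bootstrap)) return(bootstrap)
  es <- gather_edges(g, n, r)
  if (length(es) == 0L) return(NULL)
  s <- vector("list", length(es))
  for (i in seq_along(es)) {
    sig <- es[[i]]$signals[[r]]
    if (is.null(sig)) return(NULL)
    s[[i]] <- sig
  }
  if (length(s) == 1L) return(s[[1L]])
  s
}

#' Activate a node on a gathered signal
#'
#' @inheritParams signal_carrier
#' @param s the gathered signal (not NULL).
#' @export
apply_signal <- function(g, n, r, s) {
  if (is.null(s)) return(NULL)
  node <- g$nodes[[n]]$node
  withCallingHandlers(
    node_receptor(node, r, s),
    error = function(e) {
      if (is.null(attr(e, "fhe_node_context"))) {
        e$message <- paste0("[node ", n, "] ", conditionMessage(e))
        attr(e, "fhe_node_context") <- n
        stop(e)
      }
    }
  )
}

#' Set outbound edges with an activation signal
#'
#' A generator result is distributed one item per out-edge in edge order
#' (erroring if exhausted early); any other result is broadcast to every
#' out-edge.
#'
#' @inheritParams apply_signal
#' @export
set_outbound_signals <- function(g, n, r, s) {
  if (is.null(s)) return(invisible(NULL))
  for (e in emit_edges(g, n, r)) {
    e$signals[[r]] <- if (is_generator(s)) gen_next(s) else s
  }
  invisible(NULL)
}

## ---------------------------------------------------------------------------

fhe_condition <- function(class, message) {
  structure(class = c(class, "fhe_error", "error", "condition"),
            list(message = message, call = NULL))
}

#' Enable or disable activation tracing
#'
#' When enabled, every successful node activation appends `(node, receptor)`
#' to `g$trace`, which is useful for asserting deterministic firing histories.
#'
#' @param g a `compgraph`.
#' @param on logical.
#' @export
trace_firing <- function(g, on = TRUE) {
  g$trace <- if (on) list() else NULL
  invisible(g)
}
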