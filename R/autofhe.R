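#' Automatic FHE parameterisation over computation graphs
#'
#' Deriving levelled-CKKS parameters from a network graph reduces to a
#' longest-path problem: each ciphertext source must survive the highest
#' multiplicative depth it can experience before the next key rotation or
#' decryption ("concern" nodes), and sources whose ciphertexts interact at
#' any node must share parameters and key (a "parameter group").
#' [autohe_discover()] labels every reachable node with the maximal
#' accumulated cost from each source; [autohe()] merges the labels into
#' groups; [parameterise_ckks()] turns a group cost into concrete scheme
#' parameters; [assign_parameters()] pushes them onto the graph's encrypt and
#' rotation nodes.
#'
#' @name autofhe
NULL

concern_default <- c("rotate_node", "decrypt_node")

is_concern <- function(node, concern) inherits(node, concern)

#' Recursive source-and-cost discovery
#'
#' Walks the graph from node `n`, labelling each visited node's
#' `meta$sources[[s]]` with the maximal accumulated multiplicative depth from
#' source `s`. Cost accumulates as `c + node_cost(successor)` along every
#' edge (an edge's weight is the cost of the node it points to). Nodes of a
#' concern type stop the current source and restart as new sources at cost
#' zero: the segment after a rotation is freshly parameterised.
#'
#' @param g a `compgraph`, labelled in place.
#' @param n node to continue from.
#' @param s source label (a node name).
#' @param concern character vector of node classes acting as
#'   rotation/decryption boundaries.
#' @param c accumulated cost so far.
#' @export
autohe_discover <- function(g, n, s, concern = concern_default, c = 0L) {
  .autohe_discover(g, n, s, concern, c, path = character())
}

.autohe_discover <- function(g, n, s, concern, c, path) {
  if (!n %in% g$node_order)
    stop(fhe_condition("fhe_name_error", paste0("unknown node: ", n)))
  if (n %in% path)
    stop(fhe_condition("fhe_cycle_error",
                       paste0("cycle among non-concern nodes at: ", n)))
  meta <- g$nodes[[n]]$meta
  if (is.null(meta$sources)) meta$sources <- list()
  if (!identical(s, n)) {
    prev <- meta$sources[[s]]
    if (is.null(prev) || prev < c) meta$sources[[s]] <- as.integer(c)
  }
  if (!identical(s, n) && is_concern(g$nodes[[n]]$node, concern)) {
    ## restart: the concern node becomes a new source at cost zero
    .autohe_discover(g, n, n, concern, 0L, path = character())
  } else {
    for (succ in successors(g, n)) {
      if (succ == n) next
      nxt <- c + node_cost(g$nodes[[succ]]$node)
      .autohe_discover(g, succ, s, concern, nxt, c(path, n))
    }
  }
  invisible(g)
}

## collect all source labels over the graph, in deterministic order:
## caller-supplied sources first, then labels by node insertion order
all_labels <- function(g, sources) {
  labs <- sources
  for (nm in g$node_order) {
    src <- g$nodes[[nm]]$meta$sources
    if (!is.null(src)) labs <- c(labs, names(src))
  }
  unique(labs)
}

#' Group ciphertext sources and their maximal costs
#'
#' Runs discovery from each named source, then merges sources into parameter
#' groups: two labels that co-occur on any node's source map interact there
#' and must share parameters. Group cost is the maximum labelled cost over
#' all nodes mentioning any member. Merging is a union-find over the
#' co-occurrence relation, iterated in caller order then node insertion
#' order, so the output is deterministic. Rotation boundaries discovered
#' along the way join the result as sources of their own segments.
#'
#' @param g a `compgraph`.
#' @param n character vector of ciphertext ingress node names.
#' @param concern node classes treated as rotation/decryption boundaries.
#' @return an object of class `param_groups`: a list with `membership`
#'   (named integer vector, source -> group index) and `group_cost`
#'   (integer vector indexed by group).
#' @export
autohe <- function(g, n, concern = concern_default) {
  for (i in n) {
    if (!i %in% g$node_order)
      stop(fhe_condition("fhe_name_error", paste0("unknown source: ", i)))
    autohe_discover(g, i, i, concern, 0L)
  }
  labs <- all_labels(g, n)
  label_costs <- lapply(g$node_order, function(nm) g$nodes[[nm]]$meta$sources)
  group_labels(labs, label_costs)
}

## union-find grouping shared by autohe() and the brute-force oracle:
## labs in deterministic order; label_costs is a list of named source->cost
## maps, one per node, in node insertion order
group_labels <- function(labs, label_costs) {
  parent <- seq_along(labs)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  cost <- stats::setNames(rep(0L, length(labs)), labs)
  for (src in label_costs) {
    if (is.null(src) || length(src) == 0L) next
    ks <- names(src)
    for (k in ks) cost[[k]] <- max(cost[[k]], as.integer(src[[k]]))
    if (length(ks) > 1L)
      for (j in 2:length(ks)) {
        ra <- find(match(ks[1L], labs)); rb <- find(match(ks[j], labs))
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
  }
  roots <- vapply(seq_along(labs), find, integer(1))
  gidx <- match(roots, unique(roots))
  membership <- stats::setNames(as.integer(gidx), labs)
  group_cost <- vapply(seq_along(unique(roots)), function(gi)
    as.integer(max(cost[gidx == gi])), integer(1))
  structure(list(membership = membership, group_cost = group_cost),
            class = "param_groups")
}

#' @export
print.param_groups <- function(x, ...) {
  for (gi in seq_along(x$group_cost)) {
    cat(sprintf("group %d (cost %d): %s\n", gi, x$group_cost[gi],
                paste(names(x$membership)[x$membership == gi], collapse = ", ")))
  }
  invisible(x)
}

#' Brute-force grouping oracle
#'
#' Independent reference for [autohe()] on small graphs: enumerates every
#' simple path from each source, truncated at the first concern node (which
#' then joins the worklist as a new source), takes path cost as the sum of
#' directed-to node costs, labels nodes with per-source maxima, and groups
#' labels by connected components of the co-occurrence relation.
#'
#' @inheritParams autohe
#' @return a `param_groups` object comparable with [autohe()]'s.
#' @export
brute_force_group_cost <- function(g, n, concern = concern_default) {
  labels <- new.env(parent = emptyenv())   # node -> named numeric max costs
  lab <- function(nm, s, c) {
    cur <- if (is.null(labels[[nm]])) numeric() else labels[[nm]]
    if (is.null(cur[s]) || is.na(cur[s]) || cur[s] < c) cur[s] <- c
    labels[[nm]] <- cur
  }
  queue <- n
  done <- character()
  while (length(queue)) {
    s <- queue[[1L]]; queue <- queue[-1L]
    if (s %in% done) next
    done <- c(done, s)
    ## DFS over all simple paths from s
    walk <- function(at, c, path) {
      for (succ in successors(g, at)) {
        if (succ == at) next
        if (succ %in% path)
          stop(fhe_condition("fhe_cycle_error",
                             paste0("cycle among non-concern nodes at: ", succ)))
        cc <- c + node_cost(g$nodes[[succ]]$node)
        lab(succ, s, cc)
        if (is_concern(g$nodes[[succ]]$node, concern)) {
          queue <<- c(queue, succ)
        } else {
          walk(succ, cc, c(path, at))
        }
      }
    }
    walk(s, 0L, character())
  }
  labs <- n
  for (nm in g$node_order)
    if (!is.null(labels[[nm]])) labs <- c(labs, names(labels[[nm]]))
  labs <- unique(labs)
  ## grouping by iterated set merging (independent of autohe's union-find):
  ## start from per-node co-occurrence sets plus singletons, merge any two
  ## sets that share a member until a fixed point
  sets <- c(lapply(labs, function(l) l),
            Filter(length, lapply(g$node_order,
                                  function(nm) names(labels[[nm]]))))
  repeat {
    merged <- FALSE
    for (i in seq_along(sets)) {
      if (i > length(sets)) break
      j <- i + 1L
      while (j <= length(sets)) {
        if (length(intersect(sets[[i]], sets[[j]]))) {
          sets[[i]] <- union(sets[[i]], sets[[j]])
          sets[[j]] <- NULL
          merged <- TRUE
        } else j <- j + 1L
      }
    }
    if (!merged) break
  }
  ## order groups by first appearance of any member in labs
  first_pos <- vapply(sets, function(s) min(match(s, labs)), integer(1))
  sets <- sets[order(first_pos)]
  max_cost <- stats::setNames(rep(0L, length(labs)), labs)
  for (nm in g$node_order) {
    src <- labels[[nm]]
    for (k in names(src))
      max_cost[[k]] <- max(max_cost[[k]], as.integer(src[[k]]))
  }
  membership <- stats::setNames(integer(length(labs)), labs)
  group_cost <- integer(length(sets))
  for (gi in seq_along(sets)) {
    membership[sets[[gi]]] <- gi
    group_cost[gi] <- max(max_cost[sets[[gi]]])
  }
  structure(list(membership = membership, group_cost = group_cost),
            class = "param_groups")
}

#' Canonical form of a parameter grouping
#'
#' Sorted (members, cost) pairs, for comparing groupings produced by
#' different routes.
#'
#' @param x a `param_groups` object.
#' @export
canonical_groups <- function(x) {
  out <- lapply(seq_along(x$group_cost), function(gi)
    list(members = sort(names(x$membership)[x$membership == gi]),
         cost = x$group_cost[gi]))
  out[order(vapply(out, function(o) o$members[1L], character(1)))]
}

#' Assign FHE parameters to a graph from its groups
#'
#' All sources in one group receive the identical parameter object built from
#' the group's cost, and encrypt/rotation nodes among the sources are
#' configured with those parameters and a per-group key id.
#'
#' @param g a `compgraph`.
#' @param groups a `param_groups` from [autohe()].
#' @param parameteriser function(cost) -> `fhe_params`; defaults to
#'   [parameterise_ckks()] with the given scale.
#' @param scale_power,special_mult forwarded to the default parameteriser.
#' @return named list source -> `fhe_params`, invisibly.
#' @export
assign_parameters <- function(g, groups, parameteriser = NULL,
                              scale_power = 40, special_mult = 1.5) {
  if (is.null(parameteriser))
    parameteriser <- function(cost)
      parameterise_ckks(cost, scale_power, special_mult)
  by_group <- lapply(groups$group_cost, parameteriser)
  out <- list()
  for (s in names(groups$membership)) {
    gi <- groups$membership[[s]]
    if (is.na(gi))
      stop(fhe_condition("fhe_consistency_error",
                         paste0("source missing from groups: ", s)))
    out[[s]] <- by_group[[gi]]
    if (s %in% g$node_order) {
      nd <- g$nodes[[s]]$node
      if (inherits(nd, c("encrypt_node", "rotate_node"))) {
        nd$params <- by_group[[gi]]
        nd$key_id <- paste0("key_g", gi)
      }
    }
  }
  invisible(out)
}
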