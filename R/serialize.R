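#' Graph serialisation (JSON node-link)
#'
#' Graphs are written as human-diffable JSON: a node list with type tags and
#' parameter blobs, and an edge list of (src, dst, key) triples in insertion
#' order (edge order is semantic: it fixes signal stacking and generator
#' distribution). Learnable weights round-trip exactly.
#'
#' @param g a `compgraph`.
#' @param path output file.
#' @export
write_graph_json <- function(g, path) {
  nodes <- lapply(g$node_order, function(nm) {
    nd <- g$nodes[[nm]]$node
    rec <- list(name = nm, type = sub("_node$", "", class(nd)[1]))
    if (inherits(nd, "generic_node")) rec$cost <- nd$cost
    if (inherits(nd, "onehot_encode_node")) rec$K <- nd$K
    if (inherits(nd, "encrypt_node") || inherits(nd, "rotate_node")) {
      rec$key_id <- nd$key_id
      if (inherits(nd, "rotate_node")) rec$mode <- nd$mode
      if (!is.null(nd$params))
        rec$params <- list(cost = nd$params$cost,
                           scale_power = nd$params$scale_power,
                           special_mult = nd$params$special_mult)
    }
    if (inherits(nd, "cc_node")) {
      kdim <- dim(nd$kernel); if (is.null(kdim)) kdim <- length(nd$kernel)
      rec$kernel <- list(dim = kdim, values = as.numeric(nd$kernel))
      rec$bias <- nd$bias
      rec$stride <- nd$stride
      rec$input_shape <- nd$input_shape
    }
    if (inherits(nd, "dense_node")) {
      rec$w <- as.numeric(nd$w)
      rec$bias <- nd$bias
    }
    if (inherits(nd, "relu_node")) {
      rec$q <- nd$q; rec$alpha <- nd$alpha; rec$q_update <- nd$q_update
    }
    rec
  })
  edges <- lapply(g$edges, function(e) list(src = e$src, dst = e$dst,
                                            key = e$key))
  meta <- list(kind = g$kind, pred_node = g$pred_node,
               loss_node = g$loss_node, ingress = g$ingress,
               cfg = if (!is.null(g$cfg)) unclass(g$cfg))
  jsonlite::write_json(list(nodes = nodes, edges = edges, meta = meta),
                       path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

rebuild_node <- function(rec) {
  params_of <- function(p)
    if (is.null(p)) NULL else
      parameterise_ckks(p$cost, p$scale_power, p$special_mult)
  switch(rec$type,
    input = node_input(),
    output = node_output(),
    generic = node_generic(cost = rec$cost),
    encrypt = node_encrypt(params = params_of(rec$params),
                           key_id = rec$key_id),
    decrypt = node_decrypt(),
    rotate = node_rotate(mode = rec$mode, params = params_of(rec$params),
                         key_id = rec$key_id),
    cc = node_cc(array(unlist(rec$kernel$values),
                       dim = unlist(rec$kernel$dim)),
                 bias = rec$bias, stride = unlist(rec$stride),
                 input_shape = unlist(rec$input_shape)),
    dense = node_dense(unlist(rec$w), bias = rec$bias),
    relu = node_relu(q = rec$q, alpha = rec$alpha, q_update = rec$q_update),
    sigmoid = node_sigmoid(),
    softmax = node_softmax(),
    cce = node_cce(),
    mse = node_mse(),
    argmax = node_argmax(),
    onehot_encode = node_onehot_encode(rec$K),
    onehot_decode = node_onehot_decode(),
    stop(fhe_condition("fhe_parse_error",
                       paste0("unknown node type: ", rec$type))))
}

#' @rdname write_graph_json
#' @export
read_graph_json <- function(path) {
  doc <- jsonlite::read_json(path)
  g <- compgraph()
  for (rec in doc$nodes) add_node(g, rec$name, rebuild_node(rec))
  for (e in doc$edges) add_edge(g, e$src, e$dst, key = e$key)
  m <- doc$meta
  if (!is.null(m$kind)) g$kind <- m$kind
  if (!is.null(m$pred_node)) g$pred_node <- m$pred_node
  if (!is.null(m$loss_node)) g$loss_node <- m$loss_node
  if (!is.null(m$ingress)) g$ingress <- unlist(m$ingress)
  if (!is.null(m$cfg)) {
    cfg <- m$cfg
    cfg[] <- lapply(cfg, function(v) if (is.list(v)) unlist(v) else v)
    class(cfg) <- "network_config"
    g$cfg <- cfg
  }
  g
}
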