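# Minimal reverse-mode autodiff tape.
#
# A tape records one feed-forward computation; nodes are created strictly in
# execution order, so reverse creation order is a valid topological order for
# backpropagation. A node is a list(id, val). Ops accept either nodes or plain
# arrays (constants); constants get parent id 0 and receive no gradient.

tape_new <- function() {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  e$parents <- vector("list", 256L)
  e$vjps <- vector("list", 256L)
  e
}

is_node <- function(x) is.list(x) && !is.null(x$.tapenode)

nd_val <- function(x) if (is_node(x)) x$val else x
nd_id <- function(x) if (is_node(x)) x$id else 0L

# Register a node. `vjp` maps the gradient at this node to a list of
# gradients aligned with `parents` (entries for id-0 parents are ignored and
# may be NULL).
tp_node <- function(tape, val, parents = integer(0), vjp = NULL) {
  # Force all arguments before claiming an id: argument expressions may
  # themselves create nodes, and creation order must match dependency order
  # for the reverse sweep to be a valid topological order.
  force(val)
  parents <- as.integer(parents)
  force(vjp)
  tape$n <- tape$n + 1L
  n <- tape$n
  if (n > length(tape$parents)) {
    length(tape$parents) <- 2L * n
    length(tape$vjps) <- 2L * n
  }
  tape$parents[[n]] <- as.integer(parents)
  tape$vjps[[n]] <- vjp
  list(.tapenode = TRUE, id = n, val = val)
}

tp_leaf <- function(tape, val) tp_node(tape, val)

# Backpropagate from scalar node `node`; returns the list of gradients
# indexed by node id (NULL where no gradient flowed).
tp_backward <- function(tape, node, seed = 1) {
  grads <- vector("list", tape$n)
  grads[[node$id]] <- seed
  for (id in seq(node$id, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    ps <- tape$parents[[id]]
    if (length(ps) == 0L) next
    gl <- tape$vjps[[id]](g)
    for (j in seq_along(ps)) {
      p <- ps[j]
      if (p == 0L) next
      gj <- gl[[j]]
      if (is.null(gj)) next
      grads[[p]] <- if (is.null(grads[[p]])) gj else grads[[p]] + gj
    }
    grads[[id]] <- NULL # free memory as we go
  }
  grads
}

# Turn a flat named list of parameter arrays into leaf nodes on `tape`.
tp_leaves <- function(tape, params) lapply(params, function(p) tp_leaf(tape, p))

# Collect gradients for a set of leaves produced by tp_leaves(); missing
# gradients (parameter unused downstream) come back as zero arrays.
tp_leaf_grads <- function(grads, leaves) {
  out <- lapply(leaves, function(l) {
    g <- if (l$id <= length(grads)) grads[[l$id]] else NULL
    if (is.null(g)) {
      z <- l$val
      z[] <- 0
      z
    } else {
      dim(g) <- dim(l$val)
      g
    }
  })
  names(out) <- names(leaves)
  out
}
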