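## Packing featurized molecular graphs into contiguous blocks for batched
## message passing, mirroring the block-diagonal batching of graph-network
## libraries: node rows are concatenated, edges carry local indices plus a
## per-graph offset, and a graph-id vector drives pooling.

#' Pack a list of molecular graphs for batched computation
#'
#' @param graphs List of `mol_graph` objects from [smiles_to_graph()].
#' @return Object of class `graph_pack`.
#' @export
pack_graphs <- function(graphs) {
  stopifnot(length(graphs) > 0)
  nn <- vapply(graphs, function(g) nrow(g$node_features), integer(1))
  ne <- vapply(graphs, function(g) nrow(g$edges), integer(1))
  X <- do.call(rbind, lapply(graphs, `[[`, "node_features"))
  EA <- do.call(rbind, lapply(graphs, `[[`, "edge_features"))
  offs <- cumsum(c(0L, nn[-length(nn)]))
  efrom <- unlist(lapply(seq_along(graphs), function(i) {
    if (ne[i] == 0) integer(0) else graphs[[i]]$edges[, "from"] + offs[i]
  }))
  eto <- unlist(lapply(seq_along(graphs), function(i) {
    if (ne[i] == 0) integer(0) else graphs[[i]]$edges[, "to"] + offs[i]
  }))
  gid <- rep(seq_along(graphs), nn)
  deg <- unlist(lapply(graphs, `[[`, "degrees"))
  structure(list(X = X, edge_attr = EA, efrom = as.integer(efrom),
                 eto = as.integer(eto), gid = gid, deg = deg,
                 n_nodes = sum(nn), n_edges = sum(ne),
                 n_graphs = length(graphs),
                 node_ranges = cbind(start = offs + 1L, end = offs + nn),
                 edge_ranges = {
                   eo <- cumsum(c(0L, ne[-length(ne)]))
                   cbind(start = eo + 1L, end = eo + ne)
                 }),
            class = "graph_pack")
}

#' @export
print.graph_pack <- function(x, ...) {
  cat(sprintf("<graph_pack> %d graphs, %d nodes, %d directed edges\n",
              x$n_graphs, x$n_nodes, x$n_edges))
  invisible(x)
}

# Extract a sub-batch of graphs (by graph index) with locally renumbered
# node/edge indices. Used for mini-batching during training.
subset_pack <- function(pack, gs) {
  nr <- pack$node_ranges[gs, , drop = FALSE]
  er <- pack$edge_ranges[gs, , drop = FALSE]
  node_idx <- unlist(lapply(seq_along(gs), function(i) {
    if (nr[i, 1] > nr[i, 2]) integer(0) else nr[i, 1]:nr[i, 2]
  }))
  edge_idx <- unlist(lapply(seq_along(gs), function(i) {
    if (er[i, 1] > er[i, 2]) integer(0) else er[i, 1]:er[i, 2]
  }))
  nn <- nr[, 2] - nr[, 1] + 1L
  ne_g <- er[, 2] - er[, 1] + 1L
  new_offs <- cumsum(c(0L, nn[-length(nn)]))
  # remap global node index -> position inside the sub-batch
  shift <- rep(new_offs - nr[, 1] + 1L, ne_g)
  structure(list(
    X = pack$X[node_idx, , drop = FALSE],
    edge_attr = pack$edge_attr[edge_idx, , drop = FALSE],
    efrom = pack$efrom[edge_idx] + shift,
    eto = pack$eto[edge_idx] + shift,
    gid = rep(seq_along(gs), nn),
    deg = pack$deg[node_idx],
    n_nodes = length(node_idx), n_edges = length(edge_idx),
    n_graphs = length(gs)
  ), class = "graph_pack")
}

# accumulate rows of `add` into `acc` at (possibly duplicated) row indices
index_add <- function(acc, rows, add) {
  if (length(rows) == 0) return(acc)
  s <- rowsum(add, group = rows, reorder = FALSE)
  tgt <- as.integer(rownames(s))
  acc[tgt, ] <- acc[tgt, , drop = FALSE] + s
  acc
}

# per-node segment max/min over edge-message rows.
# Returns value matrices (0 where a node has no incoming edges) and the
# argmax/argmin edge index per (node, feature) for backpropagation.
segment_extrema <- function(M, eto, n_nodes) {
  h <- ncol(M)
  mx <- matrix(-Inf, n_nodes, h)
  mn <- matrix(Inf, n_nodes, h)
  amax <- matrix(0L, n_nodes, h)
  amin <- matrix(0L, n_nodes, h)
  if (length(eto) > 0) {
    ord <- order(eto)
    sorted_to <- eto[ord]
    counts <- tabulate(eto, nbins = n_nodes)
    maxdeg <- max(counts)
    pos <- seq_along(sorted_to)
    first_of_grp <- c(TRUE, diff(sorted_to) != 0)
    slot <- pos - rep(pos[first_of_grp], diff(c(which(first_of_grp),
                                                length(pos) + 1L))) + 1L
    for (k in seq_len(maxdeg)) {
      sel <- slot == k
      if (!any(sel)) break
      nodes <- sorted_to[sel]
      edges <- ord[sel]
      rowsM <- M[edges, , drop = FALSE]
      cur_mx <- mx[nodes, , drop = FALSE]
      upd <- rowsM > cur_mx
      if (any(upd)) {
        cur_mx[upd] <- rowsM[upd]
        mx[nodes, ] <- cur_mx
        am <- amax[nodes, , drop = FALSE]
        am[upd] <- matrix(edges, length(nodes), h)[upd]
        amax[nodes, ] <- am
      }
      cur_mn <- mn[nodes, , drop = FALSE]
      updn <- rowsM < cur_mn
      if (any(updn)) {
        cur_mn[updn] <- rowsM[updn]
        mn[nodes, ] <- cur_mn
        am <- amin[nodes, , drop = FALSE]
        am[updn] <- matrix(edges, length(nodes), h)[updn]
        amin[nodes, ] <- am
      }
    }
  }
  mx[!is.finite(mx)] <- 0
  mn[!is.finite(mn)] <- 0
  list(max = mx, min = mn, amax = amax, amin = amin)
}
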