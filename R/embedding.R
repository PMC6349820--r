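#' Edge weights for a single cell
#'
#' Combines a cell's expression vector `v` with the signed adjacency: an
#' activating edge i -> j gets weight `v[i] * v[j]`, an inhibitory edge
#' `v[i] / v[j]`, and non-edges are 0. A positive edge is thus highly
#' active when source and target are both high; a negative edge is highly
#' active when the source is high and the target low — edge activity reads
#' as the confidence that the interaction is operative in that cell.
#'
#' @param v named or ordered expression vector aligned with the adjacency
#'   node order; all values must be > 0 (see [clip_floor()]).
#' @param adj signed adjacency matrix from [adjacency()].
#' @return n x n weighted adjacency matrix
#' @export
edge_weights <- function(v, adj) {
  n <- nrow(adj)
  if (length(v) != n)
    stopf("expression vector length %d but adjacency is %d x %d",
          length(v), n, n)
  if (any(v <= 0))
    stopf("edge_weights requires strictly positive values; clip upstream")
  W <- matrix(0, n, n, dimnames = dimnames(adj))
  idx <- which(adj != 0, arr.ind = TRUE)
  if (nrow(idx)) {
    s <- adj[idx]
    W[idx] <- v[idx[, 1]] * v[idx[, 2]]^s
  }
  W
}

#' Vectorize a weighted adjacency along the network's edge order
#'
#' Flattens the n x n weighted matrix to a length-m vector by keeping the
#' entries at edge positions, in the network's fixed edge order (the
#' semantic equivalent of reshaping to n^2 and squeezing out the zeros of
#' the adjacency).
#'
#' @param W weighted adjacency (from [edge_weights()])
#' @param net the generating [signed_network()]
#' @return numeric vector of length `n_edges(net)` named by edge labels
#' @export
vectorize <- function(W, net) {
  n <- length(net$nodes)
  if (!all(dim(W) == c(n, n)))
    stopf("W must be %d x %d", n, n)
  i <- match(net$edges$source, net$nodes)
  j <- match(net$edges$target, net$nodes)
  on_edge <- matrix(FALSE, n, n)
  on_edge[cbind(i, j)] <- TRUE
  if (any(W[!on_edge] != 0))
    stopf("nonzero entries of W off the network's edge pattern")
  out <- W[cbind(i, j)]
  names(out) <- edge_labels(net)
  out
}

#' Embed cells as edge-activity vectors
#'
#' Applies the signed edge-weight rule to every cell, producing the
#' cells x edges matrix on which archetype analysis operates. Features are
#' matched to network nodes by exact name, so the feature column order of
#' the input is irrelevant; extra features are ignored.
#'
#' @param expr expression matrix (cells x features, column names =
#'   features, strictly positive values; see [clip_floor()]).
#' @param net a [signed_network()]; every node must appear among the
#'   feature names.
#' @return object of class `edge_activity`: list with `values` (cells x m
#'   matrix, columns named `source->target(sign)`), `edges` (the network's
#'   edge data.frame) and `cell_ids`.
#' @examples
#' net <- signed_network(data.frame(source = "A", target = "B", sign = 1))
#' expr <- matrix(c(2, 3), 1, dimnames = list("c1", c("A", "B")))
#' embed_cells(expr, net)$values   # 2 * 3 = 6
#' @export
embed_cells <- function(expr, net) {
  expr <- as_expression_matrix(expr)
  missing <- setdiff(net$nodes, colnames(expr))
  if (length(missing))
    stopf("network nodes missing from expression features: %s",
          paste(missing, collapse = ", "))
  V <- expr[, net$nodes, drop = FALSE]
  if (any(V <= 0))
    stopf("embed_cells requires strictly positive values; apply clip_floor()")
  i <- match(net$edges$source, net$nodes)
  j <- match(net$edges$target, net$nodes)
  pos <- net$edges$sign > 0
  m <- nrow(net$edges)
  E <- matrix(0, nrow(V), m)
  if (any(pos))  E[, pos]  <- V[, i[pos],  drop = FALSE] * V[, j[pos],  drop = FALSE]
  if (any(!pos)) E[, !pos] <- V[, i[!pos], drop = FALSE] / V[, j[!pos], drop = FALSE]
  colnames(E) <- edge_labels(net)
  rownames(E) <- rownames(expr)
  structure(list(values = E, edges = net$edges,
                 cell_ids = rownames(expr)),
            class = "edge_activity")
}

#' @export
print.edge_activity <- function(x, ...) {
  cat(sprintf("edge_activity: %d cells x %d edges\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Write an edge-activity matrix as TSV
#' @param ea an `edge_activity` object from [embed_cells()]
#' @param path output path
#' @export
write_edge_activity <- function(ea, path) {
  write_expression(ea$values, path)
}
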