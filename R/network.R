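#' Signed directed regulatory networks
#'
#' A `signed_network` holds an ordered node list and an ordered edge list
#' `(source, target, sign)` with signs in \{-1, +1\}. The edge order is fixed
#' at construction and defines the vectorization order used by
#' [embed_cells()], so embeddings are reproducible bit-for-bit when a model
#' is serialized together with its network.
#'
#' Invariants enforced: node labels are unique; every edge endpoint is a
#' listed node; at most one edge per ordered `(source, target)` pair; signs
#' are exactly -1 or +1. Self-loops are permitted (autoregulation is
#' biologically real) and `i -> j` and `j -> i` are distinct edges.
#'
#' @param edges data.frame with columns `source`, `target`, `sign`.
#' @param nodes optional character vector of node labels; defaults to the
#'   labels appearing in `edges`, in order of first appearance.
#' @return An object of class `signed_network` with elements `nodes`
#'   (character) and `edges` (data.frame `source`, `target`, `sign`).
#' @seealso [read_edge_list()], [adjacency()], [prune_isolated()],
#'   [write_graphml()]
#' @examples
#' net <- signed_network(data.frame(source = "A", target = "B", sign = 1))
#' adjacency(net)
#' @export
signed_network <- function(edges, nodes = NULL) {
  if (!is.data.frame(edges))
    stopf("`edges` must be a data.frame")
  need <- c("source", "target", "sign")
  if (!all(need %in% names(edges)))
    stopf("`edges` must have columns source, target, sign")
  edges <- data.frame(source = as.character(edges$source),
                      target = as.character(edges$target),
                      sign   = as.integer(edges$sign),
                      stringsAsFactors = FALSE)
  if (nrow(edges) > 0 && !all(edges$sign %in% c(-1L, 1L)))
    stopf("edge signs must be exactly -1 or +1")
  if (is.null(nodes)) {
    nodes <- unique(c(rbind(edges$source, edges$target)))
  } else {
    nodes <- as.character(nodes)
  }
  if (anyDuplicated(nodes))
    stopf("node labels must be unique")
  missing <- setdiff(unique(c(edges$source, edges$target)), nodes)
  if (length(missing))
    stopf("edge endpoints not in node list: %s", paste(missing, collapse = ", "))
  key <- paste(edges$source, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    pair <- strsplit(dup, "\r", fixed = TRUE)[[1]]
    stopf("duplicate edge for ordered pair (%s, %s)", pair[1], pair[2])
  }
  structure(list(nodes = nodes, edges = edges), class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("signed_network: %d nodes, %d edges (%d activating, %d inhibitory)\n",
              length(x$nodes), nrow(x$edges),
              sum(x$edges$sign == 1L), sum(x$edges$sign == -1L)))
  invisible(x)
}

#' Number of edges in a signed network
#' @param net a [signed_network()]
#' @return integer edge count
#' @export
n_edges <- function(net) nrow(net$edges)

# canonical per-edge column labels, e.g. "A->B(+)"
edge_labels <- function(net) {
  paste0(net$edges$source, "->", net$edges$target,
         "(", ifelse(net$edges$sign > 0, "+", "-"), ")")
}

#' Read a signed edge list from delimited text
#'
#' Expects columns `source`, `target`, `sign` (header optional if exactly
#' three columns); lines starting with `#` are comments. Sign tokens
#' `+`, `-`, `+1`, `-1`, `1`, `activation`, `inhibition` (case-insensitive)
#' are accepted. Edge order is the file order. A repeated `(source, target)`
#' pair is a hard error -- with conflicting signs a silent "last wins" rule
#' would corrupt every downstream edge weight.
#'
#' @param path path to a delimited text file.
#' @param sep field separator, default tab; `""` splits on whitespace.
#' @return a [signed_network()]
#' @export
read_edge_list <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = FALSE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, strip.white = TRUE)
  if (ncol(df) < 3)
    stopf("edge list must have >= 3 columns (source, target, sign): %s", path)
  df <- df[, 1:3]
  names(df) <- c("source", "target", "sign")
  # tolerate a header row
  if (nrow(df) > 0 && tolower(df$source[1]) == "source" &&
      tolower(df$target[1]) == "target")
    df <- df[-1, , drop = FALSE]
  df$sign <- parse_sign(df$sign)
  if (anyNA(df$sign)) {
    bad <- which(is.na(df$sign))[1]
    stopf("unparseable sign token '%s' at data line %d of %s",
          as.character(utils::read.table(path, header = FALSE, sep = sep,
                                         comment.char = "#",
                                         stringsAsFactors = FALSE)[, 3][bad]),
          bad, path)
  }
  key <- paste(df$source, df$target, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[key %in% key[duplicated(key)], ]
    pr <- unique(paste0(d$source, "->", d$target))[1]
    signs <- unique(d$sign[paste0(d$source, "->", d$target) == pr])
    if (length(signs) > 1)
      stopf("conflicting signs for repeated edge %s", pr)
    stopf("duplicate edge %s", pr)
  }
  signed_network(df)
}

parse_sign <- function(x) {
  tok <- tolower(trimws(as.character(x)))
  out <- rep(NA_integer_, length(tok))
  out[tok %in% c("+", "+1", "1", "activation", "activating")] <- 1L
  out[tok %in% c("-", "-1", "−1", "inhibition", "inhibitory", "inhibiting")] <- -1L
  out
}

#' Write a signed edge list as TSV
#' @param net a [signed_network()]
#' @param path output path
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Signed adjacency matrix
#'
#' Encodes the network as an n x n matrix with `A[i, j]` equal to the edge
#' sign when node `i` regulates node `j` and 0 otherwise. Rows index
#' regulators, columns targets.
#'
#' @param net a [signed_network()]
#' @return integer matrix with dimnames `net$nodes`
#' @export
adjacency <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges) > 0) {
    i <- match(net$edges$source, net$nodes)
    j <- match(net$edges$target, net$nodes)
    A[cbind(i, j)] <- net$edges$sign
  }
  A
}

#' Drop unconnected nodes
#'
#' Removes nodes with total degree zero (no incoming or outgoing edges),
#' e.g. inert reporters or cell-cycle markers profiled alongside the
#' network features. The edge list is unchanged. Idempotent.
#'
#' @param net a [signed_network()]
#' @param feature_names optional feature names of an expression matrix; the
#'   returned `kept_features` is their intersection with the surviving
#'   nodes, for subsetting the matrix.
#' @return list with `network` (pruned) and `kept_features`
#' @export
prune_isolated <- function(net, feature_names = NULL) {
  used <- unique(c(net$edges$source, net$edges$target))
  keep <- net$nodes[net$nodes %in% used]
  pruned <- signed_network(net$edges, nodes = keep)
  kept_features <- if (is.null(feature_names)) keep
                   else feature_names[feature_names %in% keep]
  list(network = pruned, kept_features = kept_features)
}

#' Export a network to GraphML
#'
#' Writes the network with edge attributes `sign` (integer) and, when
#' supplied, `weight` (double, aligned with the network's edge order);
#' suitable for rendering archetypes and representative networks in
#' standard graph viewers. Round-trips through [read_graphml()].
#'
#' @param net a [signed_network()]
#' @param path output path
#' @param edge_weights optional numeric vector of length `n_edges(net)`
#' @export
write_graphml <- function(net, path, edge_weights = NULL) {
  if (!is.null(edge_weights) && length(edge_weights) != nrow(net$edges))
    stopf("edge_weights has length %d but the network has %d edges",
          length(edge_weights), nrow(net$edges))
  g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                     vertices = data.frame(name = net$nodes))
  if (!is.null(edge_weights))
    igraph::E(g)$weight <- as.numeric(edge_weights)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a network from GraphML
#'
#' Inverse of [write_graphml()]: recovers nodes, edges, signs and (if
#' present) edge weights, preserving edge order.
#'
#' @param path GraphML file written by [write_graphml()]
#' @return a [signed_network()]; if the file carries weights they are
#'   attached as attribute `"weights"`.
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_data_frame(g, what = "edges")
  net <- signed_network(data.frame(source = el$from, target = el$to,
                                   sign = as.integer(el$sign)),
                        nodes = igraph::V(g)$name)
  if ("weight" %in% names(el))
    attr(net, "weights") <- as.numeric(el$weight)
  net
}
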