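#' Fit PCA on edge activities (eigen-networks)
#'
#' Principal component analysis of the centered, unit-variance edge-activity
#' matrix via [stats::prcomp()]. Each loading vector assigns a signed weight
#' to every network edge and can therefore be drawn back onto the network as
#' a regulatory activity archetype ("eigen-network"); any cell's edge
#' activity is a weighted sum of these archetypes around the training mean.
#'
#' Scaling is applied to edge features (after embedding), with the n - 1
#' standard-deviation denominator. Component signs are fixed by making the
#' largest-magnitude loading of each component positive, so archetypes are
#' reproducible across runs and row permutations.
#'
#' When there are fewer cells than edges the sample correlation matrix is
#' rank-deficient and only `min(n_cells - 1, m)` components are returned;
#' the trailing exact-zero eigenvalues are dropped, so explained-variance
#' fractions still sum to 1.
#'
#' @param E an `edge_activity` object from [embed_cells()] or a plain
#'   numeric matrix (cells x edges).
#' @param drop_constant drop zero-variance edge columns with a warning
#'   instead of erroring.
#' @return object of class `eignet_pca`: `center`, `scale` (per edge),
#'   `loadings` (m x r orthonormal columns), `evf` (explained-variance
#'   fractions, non-increasing, sum 1), `sdev`, `edges`, `n_train`.
#' @export
fit_pca <- function(E, drop_constant = FALSE) {
  edges <- NULL
  if (inherits(E, "edge_activity")) { edges <- E$edges; E <- E$values }
  if (nrow(E) < 2) stopf("fit_pca needs at least 2 cells")
  sc <- zscale(E, drop_constant = drop_constant)
  keep <- colnames(sc$values)
  if (!is.null(edges)) edges <- edges[colnames(E) %in% keep, , drop = FALSE]
  p <- stats::prcomp(sc$values, center = FALSE, scale. = FALSE)
  r <- min(nrow(E) - 1, ncol(sc$values))
  L <- p$rotation[, seq_len(r), drop = FALSE]
  sdev <- p$sdev[seq_len(r)]
  # deterministic sign: largest-|loading| entry of each component positive
  for (k in seq_len(ncol(L))) {
    piv <- which.max(abs(L[, k]))
    if (L[piv, k] < 0) L[, k] <- -L[, k]
  }
  structure(list(center = sc$center, scale = sc$scale, loadings = L,
                 sdev = sdev, evf = sdev^2 / sum(sdev^2),
                 edges = edges, n_train = nrow(E)),
            class = "eignet_pca")
}

#' @export
print.eignet_pca <- function(x, ...) {
  cat(sprintf("eigen-network PCA: %d edges, %d components (n_train = %d)\n",
              length(x$center), ncol(x$loadings), x$n_train))
  cat(sprintf("  variance explained by first 3: %.1f%%\n",
              100 * sum(x$evf[seq_len(min(3, length(x$evf)))])))
  invisible(x)
}

#' Components needed to reach a variance fraction
#' @param model an `eignet_pca`
#' @param frac target cumulative explained-variance fraction in (0, 1]
#' @return smallest k whose cumulative explained fraction >= `frac`
#' @export
n_components_for_variance <- function(model, frac) {
  if (!(frac > 0 && frac <= 1)) stopf("frac must be in (0, 1]")
  cum <- cumsum(model$evf)
  which(cum >= frac - 1e-12)[1]
}

#' Project edge activities onto trained eigen-networks
#'
#' Applies the training center/scale and loadings to new data; test data is
#' never refit. Scores are the per-cell weights of each archetype.
#'
#' @param model an `eignet_pca`
#' @param E `edge_activity` or matrix with the model's edge columns
#' @param k number of components to retain (default all)
#' @return cells x k score matrix (columns `PC1..PCk`)
#' @export
project <- function(model, E, k = NULL) {
  if (inherits(E, "edge_activity")) E <- E$values
  if (is.null(k)) k <- ncol(model$loadings)
  if (k > ncol(model$loadings))
    stopf("k = %d exceeds the %d available components", k, ncol(model$loadings))
  if (!identical(colnames(E), names(model$center)))
    stopf("edge columns do not match the trained model (order and labels must agree)")
  Z <- sweep(sweep(E, 2, model$center, "-"), 2, model$scale, "/")
  S <- Z %*% model$loadings[, seq_len(k), drop = FALSE]
  colnames(S) <- paste0("PC", seq_len(k))
  S
}

#' Extract one eigen-network as a weighted signed network
#'
#' Returns the network with each edge carrying its loading entry for the
#' requested component, i.e. the archetype's signed deviation pattern
#' around the training mean; export with [write_graphml()] for rendering.
#'
#' @param model an `eignet_pca`
#' @param component component index
#' @param net the [signed_network()] the model was trained on
#' @return the network with a `weight` column added to `$edges` (and the
#'   weights as attribute `"weights"`)
#' @export
eigen_network <- function(model, component, net) {
  if (component > ncol(model$loadings))
    stopf("component %d not available", component)
  w <- model$loadings[, component]
  lbl <- edge_labels(net)
  if (!identical(lbl, rownames(model$loadings)) &&
      !identical(lbl, names(model$center)))
    stopf("network edge order does not match the trained model")
  out <- net
  out$edges$weight <- as.numeric(w)
  attr(out, "weights") <- as.numeric(w)
  out
}

#' Reconstruct an edge-activity vector from archetype weights
#'
#' Inverse of the scaled projection: `center + scale * (loadings[, 1:k] %*%
#' weights)`. With a cluster centroid's score vector this yields the
#' representative regulatory network of that state; with `weights = 0` it
#' returns the training mean edge vector.
#'
#' @param model an `eignet_pca`
#' @param weights numeric score/weight vector of length `k`
#' @param k number of components (default `length(weights)`)
#' @return named edge-activity vector of length m
#' @export
reconstruct_edges <- function(model, weights, k = length(weights)) {
  if (length(weights) != k)
    stopf("weights has length %d but k = %d", length(weights), k)
  if (k > ncol(model$loadings))
    stopf("k = %d exceeds the %d available components", k, ncol(model$loadings))
  z <- model$loadings[, seq_len(k), drop = FALSE] %*% as.numeric(weights)
  out <- model$center + model$scale * as.numeric(z)
  names(out) <- names(model$center)
  out
}
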