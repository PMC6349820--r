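#' Fit an eigen-network model of single-cell identities
#'
#' The full training pipeline in one call: floor-clip the expression
#' matrix, embed every cell as a signed edge-activity vector over the
#' regulatory network, fit PCA in edge space (the eigen-network
#' archetypes), project onto the first `k` components, choose the number
#' of Gaussian mixture components by BIC (unless `K` is given), and fit
#' the mixture that defines density, surprisal and reject-option
#' classification for this reference population.
#'
#' @param expr cells x features expression matrix on the analysis scale
#'   (apply [logicle()] first for raw cytometry intensities); column names
#'   must cover the network nodes.
#' @param network a [signed_network()].
#' @param k number of retained components (archetypes), default 3 — in
#'   edge-activity data the leading few components carry the biological
#'   state structure while higher components mostly add noise.
#' @param K number of mixture components; `NULL` (default) selects from
#'   `K_range` by `selection`.
#' @param K_range candidate component counts for selection, default 1:9.
#' @param selection `"min_bic"` (default) or `"elbow"`, see
#'   [select_components()].
#' @param reject_percentile Mahalanobis percentile of the reject option,
#'   default 0.90.
#' @param clip_eps positive floor applied to `expr` before embedding.
#' @param seed RNG seed (mixture initialization subsample); recorded in
#'   the model.
#' @param keep_data keep the training edge-activity matrix and scores in
#'   the fitted object (needed by [residuals.eignet()] and score plots).
#' @return object of class `eignet` with elements `network`, `pca`
#'   (see [fit_pca()]), `k`, `gmm` (see [fit_gmm()]), `selection` (NULL
#'   when `K` was given), `seed`, `call`, and `train` (list: `n_cells`,
#'   `scores`, `edge_values` when `keep_data`, training `classification`).
#' @seealso [predict.eignet()], [score_cells()], [representative_networks()],
#'   [write_eignet()]
#' @examples
#' sc <- default_scenario(seed = 1)
#' pop <- simulate_population(sc$network, sc$states, 600, seed = 2)
#' fit <- eignet(pop$values, sc$network, K = 4, seed = 1)
#' fit
#' @export
eignet <- function(expr, network, k = 3, K = NULL, K_range = 1:9,
                   selection = c("min_bic", "elbow"),
                   reject_percentile = 0.90, clip_eps = 1e-6, seed = 1L,
                   keep_data = TRUE) {
  selection <- match.arg(selection)
  cl <- match.call()
  expr <- as_expression_matrix(expr)
  expr <- suppressMessages(clip_floor(expr, clip_eps))
  ea <- embed_cells(expr, network)
  pca <- fit_pca(ea)
  if (k > ncol(pca$loadings))
    stopf("k = %d exceeds the %d available components", k, ncol(pca$loadings))
  scores <- project(pca, ea, k = k)
  sel <- NULL
  if (is.null(K)) {
    sel <- select_components(scores, K_range = K_range,
                             strategy = selection, seed = seed)
    K <- sel$chosen
  }
  gmm <- fit_gmm(scores, K, seed = seed,
                 reject_percentile = reject_percentile)
  cls <- classify_cells(gmm, scores)
  train <- list(n_cells = nrow(expr), scores = scores,
                classification = cls)
  if (keep_data) train$edge_values <- ea$values
  structure(list(network = network, pca = pca, k = k, gmm = gmm,
                 selection = sel, reject_percentile = reject_percentile,
                 clip_eps = clip_eps, seed = as.integer(seed), call = cl,
                 train = train),
            class = "eignet")
}

#' @export
print.eignet <- function(x, ...) {
  cat("Eigen-network model\n")
  cat(sprintf("  network: %d nodes, %d edges\n",
              length(x$network$nodes), nrow(x$network$edges)))
  cat(sprintf("  archetypes: %d of %d components (%.1f%% variance)\n",
              x$k, ncol(x$pca$loadings),
              100 * sum(x$pca$evf[seq_len(x$k)])))
  cat(sprintf("  mixture: K = %d%s, reject percentile %.2f\n", x$gmm$K,
              if (!is.null(x$selection))
                sprintf(" (selected by %s over K = %s)",
                        x$selection$strategy,
                        paste(range(x$selection$candidates), collapse = ".."))
              else "", x$reject_percentile))
  cat(sprintf("  trained on %d cells (seed %d)\n",
              x$train$n_cells, x$seed))
  invisible(x)
}

#' @export
summary.eignet <- function(object, ...) {
  lab <- object$train$classification$label
  out <- list(
    n_cells = object$train$n_cells,
    n_nodes = length(object$network$nodes),
    n_edges = nrow(object$network$edges),
    k = object$k,
    variance_explained = sum(object$pca$evf[seq_len(object$k)]),
    evf = object$pca$evf[seq_len(object$k)],
    K = object$gmm$K,
    weights = object$gmm$weights,
    bic = if (!is.null(object$selection)) object$selection$bic else object$gmm$bic,
    train_label_fractions = table(lab) / length(lab),
    train_median_surprisal =
      stats::median(surprisal(object$gmm, object$train$scores)),
    seed = object$seed)
  class(out) <- "summary.eignet"
  out
}

#' @export
print.summary.eignet <- function(x, ...) {
  cat(sprintf("Eigen-network model: %d cells, %d nodes, %d edges\n",
              x$n_cells, x$n_nodes, x$n_edges))
  cat(sprintf("  %d archetypes explain %.1f%% of edge-activity variance\n",
              x$k, 100 * x$variance_explained))
  cat(sprintf("  mixture K = %d; component weights: %s\n", x$K,
              paste(sprintf("%.3f", x$weights), collapse = " ")))
  cat("  training label fractions (incl. REJECT):\n")
  print(round(x$train_label_fractions, 4))
  cat(sprintf("  median training surprisal: %.2f bits\n",
              x$train_median_surprisal))
  invisible(x)
}

#' Score new cells with a trained eigen-network model
#'
#' Applies the training pipeline (clip, embed, project with training
#' center/scale — never refit) to new expression data and returns per-cell
#' label, surprisal and posteriors as one data frame, the package's
#' standard per-cell output table.
#'
#' @param object a fitted [eignet()] model
#' @param expr cells x features expression matrix
#' @return data.frame: `cell_id`, `label`, `surprisal_bits`,
#'   `posterior_1..K`, plus the retained scores `PC1..PCk`
#' @export
score_cells <- function(object, expr) {
  stopifnot(inherits(object, "eignet"))
  expr <- as_expression_matrix(expr)
  expr <- suppressMessages(clip_floor(expr, object$clip_eps))
  ea <- embed_cells(expr, object$network)
  s <- project(object$pca, ea, k = object$k)
  cls <- classify_cells(object$gmm, s)
  surp <- surprisal(object$gmm, s)
  out <- data.frame(cell_id = if (is.null(rownames(expr)))
                      as.character(seq_len(nrow(expr))) else rownames(expr),
                    label = cls$label,
                    surprisal_bits = as.numeric(surp),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(cls$posterior), as.data.frame(s))
}

#' Predict method for eigen-network models
#'
#' @param object a fitted [eignet()] model
#' @param newdata cells x features expression matrix; defaults to the
#'   training data when kept.
#' @param type `"class"` (labels with reject option), `"posterior"`,
#'   `"score"` (archetype weights), `"surprisal"` (bits), `"density"`, or
#'   `"full"` (the [score_cells()] data frame).
#' @param ... unused
#' @return see `type`
#' @export
predict.eignet <- function(object, newdata = NULL,
                           type = c("class", "posterior", "score",
                                    "surprisal", "density", "full"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    s <- object$train$scores
    ids <- rownames(s)
    if (type == "full" || is.null(s))
      stopf("supply `newdata` (training data not kept)")
  } else {
    newdata <- as_expression_matrix(newdata)
    if (type == "full") return(score_cells(object, newdata))
    expr <- suppressMessages(clip_floor(newdata, object$clip_eps))
    s <- project(object$pca, embed_cells(expr, object$network),
                 k = object$k)
  }
  switch(type,
         class = classify_cells(object$gmm, s)$label,
         posterior = classify_cells(object$gmm, s)$posterior,
         score = s,
         surprisal = as.numeric(surprisal(object$gmm, s)),
         density = gmm_density(object$gmm, s),
         full = score_cells(object, newdata))
}

#' Archetype loadings of a fitted model
#' @param object a fitted [eignet()] model
#' @param ... unused
#' @return m x k matrix of eigen-network edge loadings
#' @export
coef.eignet <- function(object, ...) {
  object$pca$loadings[, seq_len(object$k), drop = FALSE]
}

#' @export
logLik.eignet <- function(object, ...) {
  val <- object$gmm$loglik
  attr(val, "df") <- with(object$gmm,
    (K - 1) + K * d + K * d * (d + 1) / 2)
  attr(val, "nobs") <- object$gmm$n
  class(val) <- "logLik"
  val
}

#' Training reconstruction residuals
#'
#' Residuals of the rank-`k` archetype reconstruction of the training
#' edge-activity matrix (edge-activity units): what the retained
#' eigen-networks fail to capture.
#'
#' @param object a fitted [eignet()] model (with `keep_data = TRUE`)
#' @param ... unused
#' @return cells x edges matrix of residuals
#' @export
residuals.eignet <- function(object, ...) {
  E <- object$train$edge_values
  if (is.null(E))
    stopf("training data not kept; refit with keep_data = TRUE")
  recon <- t(apply(object$train$scores, 1, function(w)
    reconstruct_edges(object$pca, w, k = object$k)))
  E - recon
}

#' Plot a fitted eigen-network model
#'
#' `which = "bic"` draws the BIC trace of the component selection (when
#' available); `which = "scores"` draws the training cells in the first
#' two archetype dimensions colored by classified label.
#'
#' @param x a fitted [eignet()] model
#' @param which `"bic"`, `"scores"` or both
#' @param ... passed to the underlying plot calls
#' @export
plot.eignet <- function(x, which = c("bic", "scores"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  if ("bic" %in% which && !is.null(x$selection)) {
    b <- x$selection$bic
    graphics::plot(as.integer(names(b)), b, type = "b", pch = 19,
                   xlab = "mixture components K", ylab = "BIC", ...)
    graphics::abline(v = x$selection$chosen, lty = 2)
  }
  if ("scores" %in% which && !is.null(x$train$scores)) {
    s <- x$train$scores
    lab <- x$train$classification$label
    graphics::plot(s[, 1], s[, 2], col = as.integer(lab), pch = ".",
                   xlab = colnames(s)[1], ylab = colnames(s)[2], ...)
    graphics::legend("topright", legend = levels(lab), pch = 19,
                     col = seq_along(levels(lab)), cex = 0.8)
  }
  invisible(x)
}

#' Simulate cells from a fitted model
#'
#' Draws archetype-score vectors from the fitted Gaussian mixture — the
#' model's generative picture of the reference population.
#'
#' @param object a fitted [eignet()] model
#' @param nsim number of replicate draws
#' @param seed RNG seed
#' @param n cells per draw, default the training size
#' @param ... unused
#' @return a list of `nsim` data frames with columns `component`,
#'   `PC1..PCk` (a single data frame when `nsim = 1`)
#' @export
simulate.eignet <- function(object, nsim = 1, seed = NULL,
                            n = object$train$n_cells, ...) {
  seeds <- if (is.null(seed)) rep(list(NULL), nsim)
           else as.list(seed + seq_len(nsim) - 1L)
  sims <- lapply(seeds, function(s) {
    d <- gmm_simulate(object$gmm, n, seed = s)
    data.frame(component = d$component, d$x)
  })
  if (nsim == 1) sims[[1]] else sims
}

#' Representative networks of the fitted states
#'
#' Reconstructs, for each mixture component, the edge-activity vector of
#' its centroid from the retained eigen-networks ([reconstruct_edges()]),
#' i.e. the characteristic regulatory network of that cell state. The GMM
#' component means live in score space, so the centroid's scores are its
#' archetype weights.
#'
#' @param object a fitted [eignet()] model
#' @return list of length K of weighted [signed_network()]s (edge `weight`
#'   column = reconstructed edge activity)
#' @export
representative_networks <- function(object) {
  stopifnot(inherits(object, "eignet"))
  lapply(seq_len(object$gmm$K), function(kk) {
    v <- reconstruct_edges(object$pca, object$gmm$means[kk, ],
                           k = object$k)
    out <- object$network
    out$edges$weight <- as.numeric(v)
    attr(out, "weights") <- as.numeric(v)
    out
  })
}
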