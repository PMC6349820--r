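#' Serialize a fitted eigen-network model to JSON
#'
#' Writes the complete model — network (nodes, ordered signed edges), PCA
#' center/scale/loadings/variance fractions, retained k, mixture
#' parameters, selection trace, reject percentile, clip floor and seed —
#' as a single JSON document at full double precision. Runs with the same
#' data and seed produce byte-identical files; training data is not
#' serialized.
#'
#' @param object a fitted [eignet()] model
#' @param path output path
#' @return `path`, invisibly
#' @seealso [read_eignet()]
#' @export
write_eignet <- function(object, path) {
  stopifnot(inherits(object, "eignet"))
  doc <- list(
    format = "eignet-model",
    format_version = 1L,
    package_version = as.character(utils::packageVersion("eignet")),
    seed = object$seed,
    k = object$k,
    reject_percentile = object$reject_percentile,
    clip_eps = object$clip_eps,
    n_train = object$train$n_cells,
    network = list(nodes = object$network$nodes,
                   edges = object$network$edges),
    pca = list(center = unname(object$pca$center),
               scale = unname(object$pca$scale),
               loadings = unname(object$pca$loadings),
               sdev = object$pca$sdev,
               evf = object$pca$evf,
               n_train = object$pca$n_train),
    gmm = list(K = object$gmm$K,
               weights = object$gmm$weights,
               means = unname(object$gmm$means),
               covariances = lapply(seq_len(object$gmm$K), function(k)
                 unname(object$gmm$covariances[, , k])),
               d = object$gmm$d,
               loglik = object$gmm$loglik,
               n = object$gmm$n,
               bic = object$gmm$bic),
    selection = if (!is.null(object$selection))
      list(candidates = object$selection$candidates,
           bic = unname(object$selection$bic),
           chosen = object$selection$chosen,
           strategy = object$selection$strategy))
  # I(17) significant digits: doubles survive the JSON round trip exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a fitted eigen-network model from JSON
#'
#' Inverse of [write_eignet()]. The returned model scores and classifies
#' new data exactly as the original; the training matrices themselves are
#' not stored, so [residuals.eignet()] is unavailable on a restored model.
#'
#' @param path a JSON file written by [write_eignet()]
#' @return an object of class `eignet`
#' @export
read_eignet <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "eignet-model"))
    stopf("'%s' is not an eignet model file", path)
  network <- signed_network(doc$network$edges, nodes = doc$network$nodes)
  lbl <- edge_labels(network)
  L <- unname(as.matrix(doc$pca$loadings))
  rownames(L) <- lbl
  colnames(L) <- paste0("PC", seq_len(ncol(L)))
  pca <- structure(list(center = stats::setNames(doc$pca$center, lbl),
                        scale = stats::setNames(doc$pca$scale, lbl),
                        loadings = L,
                        sdev = doc$pca$sdev,
                        evf = doc$pca$evf,
                        edges = network$edges,
                        n_train = doc$pca$n_train),
                   class = "eignet_pca")
  d <- doc$gmm$d
  covs <- array(NA_real_, dim = c(d, d, doc$gmm$K))
  cl <- doc$gmm$covariances
  for (k in seq_len(doc$gmm$K)) {
    # jsonlite simplifies the list of K d x d matrices to a K x d x d array
    covs[, , k] <- if (is.array(cl) && length(dim(cl)) == 3) cl[k, , ]
                   else as.matrix(cl[[k]])
  }
  means <- unname(as.matrix(doc$gmm$means))
  if (d == 1) means <- matrix(as.numeric(means), ncol = 1)
  gmm <- structure(list(K = doc$gmm$K, weights = doc$gmm$weights,
                        means = means, covariances = covs, d = d,
                        loglik = doc$gmm$loglik, n = doc$gmm$n,
                        bic = doc$gmm$bic,
                        reject_percentile = doc$reject_percentile),
                   class = "eignet_gmm")
  sel <- NULL
  if (!is.null(doc$selection)) {
    sel <- structure(list(candidates = doc$selection$candidates,
                          bic = stats::setNames(doc$selection$bic,
                                                doc$selection$candidates),
                          chosen = doc$selection$chosen,
                          strategy = doc$selection$strategy),
                     class = "eignet_fitsel")
  }
  structure(list(network = network, pca = pca, k = doc$k, gmm = gmm,
                 selection = sel,
                 reject_percentile = doc$reject_percentile,
                 clip_eps = doc$clip_eps, seed = doc$seed,
                 call = NULL,
                 train = list(n_cells = doc$n_train, scores = NULL,
                              classification = NULL)),
            class = "eignet")
}
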