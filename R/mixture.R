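#' Fit a full-covariance Gaussian mixture on PC scores
#'
#' Fits a K-component mixture with unrestricted per-component covariances
#' (mclust's "VVV" family — the most general parameterization) by EM via
#' [mclust::Mclust()], with mclust's deterministic model-based hierarchical
#' initialization. For more than 2000 cells mclust initializes on a random
#' subsample, so `seed` is applied immediately before fitting to make the
#' fit reproducible.
#'
#' The fitted mixture is an estimate of the joint density P(x) of the
#' training population in archetype-score space; [gmm_density()],
#' [surprisal()] and [classify_cells()] operate on it.
#'
#' @param scores cells x d score matrix (see [project()])
#' @param K number of components (>= 1)
#' @param seed RNG seed controlling the initialization subsample
#' @param reject_percentile Mahalanobis percentile for the reject option
#'   used by [classify_cells()], default 0.90
#' @return object of class `eignet_gmm`: `K`, `weights` (length-K simplex),
#'   `means` (K x d), `covariances` (d x d x K), `d`, `loglik`, `n`, `bic`
#'   (minimized convention, see [select_components()]), `reject_percentile`.
#' @export
fit_gmm <- function(scores, K, seed = 1L, reject_percentile = 0.90) {
  scores <- as.matrix(scores)
  d <- ncol(scores); n <- nrow(scores)
  if (K < 1) stopf("K must be >= 1")
  if (n < 10 * K * d)
    warnf("few cells (%d) for K = %d components in %d dimensions", n, K, d)
  fit <- with_seed(seed,
    mclust::Mclust(scores, G = K, modelNames = "VVV", verbose = FALSE))
  if (is.null(fit)) stopf("mixture fit failed for K = %d", K)
  pars <- fit$parameters
  means <- t(pars$mean)
  if (d == 1) means <- matrix(pars$mean, ncol = 1)
  covs <- pars$variance$sigma
  if (is.null(covs)) {  # G = 1 cases store sigma differently
    covs <- array(pars$variance$Sigma, dim = c(d, d, K))
  }
  dimnames(covs) <- NULL
  weights <- pars$pro
  if (is.null(weights)) weights <- 1
  structure(list(K = K, weights = as.numeric(weights),
                 means = unname(means), covariances = covs, d = d,
                 loglik = as.numeric(fit$loglik), n = n,
                 bic = -as.numeric(fit$bic),
                 reject_percentile = reject_percentile),
            class = "eignet_gmm")
}

#' @export
print.eignet_gmm <- function(x, ...) {
  cat(sprintf("Gaussian mixture: K = %d components in %d dimensions (n = %d)\n",
              x$K, x$d, x$n))
  cat("  weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  invisible(x)
}

#' Choose the number of mixture components by BIC
#'
#' Fits the candidate K values and scores each with the Bayesian
#' information criterion in the minimized convention
#' `BIC = k_params * log(n) - 2 * loglik` (mclust reports the negated,
#' maximized form; it is converted here). Strategy `"min_bic"` takes the
#' argmin; `"elbow"` takes the candidate at which the discrete curvature
#' `BIC(K-1) - 2 BIC(K) + BIC(K+1)` of the trace is largest, i.e. the bend
#' after which extra components only buy marginal improvement.
#'
#' @param scores cells x d score matrix
#' @param K_range candidate component counts, default 1:9
#' @param strategy `"min_bic"` or `"elbow"`
#' @param seed RNG seed (initialization subsample)
#' @return object of class `eignet_fitsel`: `candidates`, `bic` (named
#'   numeric, NA where the fit failed), `chosen`, `strategy`
#' @export
select_components <- function(scores, K_range = 1:9,
                              strategy = c("min_bic", "elbow"), seed = 1L) {
  strategy <- match.arg(strategy)
  scores <- as.matrix(scores)
  if (!length(K_range)) stopf("K_range must be nonempty")
  fit <- with_seed(seed,
    mclust::Mclust(scores, G = K_range, modelNames = "VVV", verbose = FALSE))
  bic_tab <- rep(NA_real_, length(K_range))
  names(bic_tab) <- K_range
  raw <- fit$BIC[, "VVV"]
  bic_tab[match(names(raw), names(bic_tab))] <- -as.numeric(raw)
  if (anyNA(bic_tab))
    warnf("mixture fit failed for K in {%s}; excluded from selection",
          paste(K_range[is.na(bic_tab)], collapse = ", "))
  ok <- which(!is.na(bic_tab))
  if (!length(ok)) stopf("all mixture fits failed")
  chosen <- if (strategy == "min_bic" || length(ok) < 3) {
    K_range[ok[which.min(bic_tab[ok])]]
  } else {
    b <- bic_tab[ok]
    curv <- b[seq_len(length(b) - 2)] - 2 * b[seq(2, length(b) - 1)] +
            b[seq(3, length(b))]
    K_range[ok[which.max(curv) + 1]]
  }
  structure(list(candidates = K_range, bic = bic_tab,
                 chosen = chosen, strategy = strategy, seed = seed),
            class = "eignet_fitsel")
}

#' @export
print.eignet_fitsel <- function(x, ...) {
  cat(sprintf("component selection (%s): chosen K = %d\n", x$strategy, x$chosen))
  print(round(x$bic, 1))
  invisible(x)
}

# per-component log N(x; mu, Sigma) for a matrix of points, via Cholesky
component_logdens <- function(model, x) {
  x <- matrix_points(model, x)
  n <- nrow(x); d <- model$d
  out <- matrix(NA_real_, n, model$K)
  for (k in seq_len(model$K)) {
    ch <- chol(model$covariances[, , k])
    z <- forwardsolve(t(ch), t(x) - model$means[k, ])
    out[, k] <- -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
  }
  out
}

matrix_points <- function(model, x) {
  if (is.null(dim(x))) {
    if (length(x) != model$d)
      stopf("point has dimension %d but the model has d = %d",
            length(x), model$d)
    x <- matrix(x, 1)
  }
  x <- as.matrix(x)
  if (ncol(x) != model$d)
    stopf("points have dimension %d but the model has d = %d",
          ncol(x), model$d)
  x
}

#' Mixture probability density
#'
#' `P(x) = sum_k weight_k * N(x; mean_k, cov_k)`, evaluated stably through
#' per-component Cholesky factors and log-sum-exp.
#'
#' @param model an `eignet_gmm`
#' @param x a point (length d) or matrix of points (rows)
#' @param log return the natural-log density
#' @return density value(s), finite and >= 0
#' @export
gmm_density <- function(model, x, log = FALSE) {
  ld <- component_logdens(model, x) +
        matrix(log(model$weights), nrow = NROW(matrix_points(model, x)),
               ncol = model$K, byrow = TRUE)
  mx <- apply(ld, 1, max)
  out <- mx + log(rowSums(exp(ld - mx)))
  if (log) out else exp(out)
}

#' Surprisal (information content) of an observation
#'
#' `S(x) = -log2 P(x)` in bits: low for cells whose archetype weights look
#' like the training population, high for atypical cells. The density is
#' floored at `floor` before the log so surprisal stays finite; floored
#' points are flagged in the `"floored"` attribute.
#'
#' @param model an `eignet_gmm`
#' @param x a point or matrix of points in score space
#' @param floor density floor, default 1e-300
#' @return surprisal in bits, with logical attribute `floored`
#' @export
surprisal <- function(model, x, floor = 1e-300) {
  p <- gmm_density(model, x)
  floored <- p < floor
  out <- -log2(pmax(p, floor))
  attr(out, "floored") <- floored
  out
}

#' Squared Mahalanobis distances to each component
#' @param model an `eignet_gmm`
#' @param x a point or matrix of points
#' @return n x K matrix of squared distances
#' @export
mahalanobis_sq <- function(model, x) {
  x <- matrix_points(model, x)
  out <- matrix(NA_real_, nrow(x), model$K)
  for (k in seq_len(model$K)) {
    ch <- chol(model$covariances[, , k])
    z <- forwardsolve(t(ch), t(x) - model$means[k, ])
    out[, k] <- colSums(z^2)
  }
  out
}

#' Classify points with a reject option
#'
#' Each point is assigned to the component with the highest posterior
#' probability unless it lies outside the `reject_percentile` Mahalanobis
#' ellipsoid (chi-squared d-dof quantile) of every component, in which case
#' it is labelled `REJECT` — capturing cells whose network activity is
#' unlike all training states. Posterior ties break to the lowest component
#' index; rejected points still carry their posteriors.
#'
#' @param model an `eignet_gmm`
#' @param x a point or matrix of points in score space
#' @param reject_percentile override the model's reject percentile
#' @return list of class `eignet_classification`: `label` (factor with
#'   levels `1..K`, `REJECT`), `posterior` (n x K), `d2` (n x K squared
#'   Mahalanobis distances)
#' @export
classify_cells <- function(model, x, reject_percentile = model$reject_percentile) {
  x <- matrix_points(model, x)
  ld <- component_logdens(model, x) +
        matrix(log(model$weights), nrow(x), model$K, byrow = TRUE)
  mx <- apply(ld, 1, max)
  post <- exp(ld - mx)
  post <- post / rowSums(post)
  d2 <- mahalanobis_sq(model, x)
  cut <- stats::qchisq(reject_percentile, df = model$d)
  reject <- apply(d2 > cut, 1, all)
  best <- max.col(post, ties.method = "first")
  lab <- ifelse(reject, "REJECT", as.character(best))
  lab <- factor(lab, levels = c(as.character(seq_len(model$K)), "REJECT"))
  colnames(post) <- paste0("posterior_", seq_len(model$K))
  structure(list(label = lab, posterior = post, d2 = d2),
            class = "eignet_classification")
}

#' @export
print.eignet_classification <- function(x, ...) {
  cat("classification of", length(x$label), "cells:\n")
  print(table(x$label))
  invisible(x)
}

#' Draw samples from a fitted Gaussian mixture
#' @param model an `eignet_gmm`
#' @param n number of points
#' @param seed RNG seed
#' @return list with `x` (n x d matrix) and `component` (integer labels)
#' @export
gmm_simulate <- function(model, n, seed = NULL) {
  with_seed(seed, {
    comp <- sample.int(model$K, n, replace = TRUE, prob = model$weights)
    x <- matrix(NA_real_, n, model$d)
    for (k in seq_len(model$K)) {
      idx <- which(comp == k)
      if (!length(idx)) next
      ch <- chol(model$covariances[, , k])
      z <- matrix(stats::rnorm(length(idx) * model$d), length(idx))
      x[idx, ] <- sweep(z %*% ch, 2, model$means[k, ], "+")
    }
    colnames(x) <- paste0("PC", seq_len(model$d))
    list(x = x, component = comp)
  })
}
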