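make_edge_data <- function(n = 200, m = 5, seed = 1) {
  set.seed(seed)
  E <- matrix(stats::rnorm(n * m), n, m) %*%
       matrix(stats::rnorm(m * m, sd = 0.7), m, m)
  E <- sweep(E, 2, stats::runif(m, 1, 3), "+")
  colnames(E) <- paste0("e", seq_len(m))
  E
}

test_that("PCA loadings match an independent eigendecomposition of the correlation matrix", {
  E <- make_edge_data()
  mod <- fit_pca(E)
  eig <- eigen(stats::cor(E), symmetric = TRUE)
  expect_equal(abs(unname(mod$loadings)), abs(eig$vectors), tolerance = 1e-8)
  expect_equal(unname(mod$evf), eig$values / sum(eig$values),
               tolerance = 1e-8)
  expect_equal(sum(mod$evf), 1, tolerance = 1e-8)
  expect_true(all(diff(mod$evf) <= 1e-12))
  # orthonormal columns
  expect_equal(crossprod(mod$loadings), diag(ncol(E)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # sign convention: largest-|loading| entry positive
  for (k in seq_len(ncol(E)))
    expect_gt(mod$loadings[which.max(abs(mod$loadings[, k])), k], 0)
})

test_that("diagonal 2D toy data yields the symmetric first component", {
  set.seed(2)
  x <- stats::rnorm(500)
  E <- cbind(e1 = x + stats::rnorm(500, sd = 0.05),
             e2 = x + stats::rnorm(500, sd = 0.05))
  mod <- fit_pca(E)
  expect_equal(unname(mod$loadings[, 1]), c(1, 1) / sqrt(2), tolerance = 0.01)
  expect_gt(mod$evf[1], 0.99)
})

test_that("component count for a variance target uses the cumulative fraction", {
  mod <- structure(list(evf = c(0.6, 0.3, 0.1)), class = "eignet_pca")
  expect_equal(n_components_for_variance(mod, 0.95), 3)
  expect_equal(n_components_for_variance(mod, 1.0), 3)
  expect_equal(n_components_for_variance(mod, 0.6), 1)
  mod2 <- structure(list(evf = c(0.96, 0.03, 0.01)), class = "eignet_pca")
  expect_equal(n_components_for_variance(mod2, 0.95), 1)
  expect_error(n_components_for_variance(mod, 0), "frac")
})

test_that("projection applies training parameters and inverts at full rank", {
  E <- make_edge_data(n = 120, m = 6, seed = 3)
  mod <- fit_pca(E)
  S <- project(mod, E)
  expect_equal(unname(colMeans(S)), rep(0, 6), tolerance = 1e-10)
  # full-rank reconstruction recovers the data
  recon <- t(apply(S, 1, function(w) reconstruct_edges(mod, w)))
  expect_equal(unname(recon), unname(E), tolerance = 1e-8)
  # a held-out cell matches the hand computation ((v - mu) / sigma) %*% L
  v <- E[1, ] * 1.3 + 0.2
  hand <- ((v - mod$center) / mod$scale) %*% mod$loadings[, 1:2]
  got <- project(mod, matrix(v, 1, dimnames = list("h", names(v))), k = 2)
  expect_equal(unname(got), unname(hand), tolerance = 1e-10)
  expect_error(project(mod, E[, 6:1]), "match")
})

test_that("reconstruction from zero weights returns the training mean", {
  E <- make_edge_data(n = 80, m = 4, seed = 4)
  mod <- fit_pca(E)
  expect_equal(reconstruct_edges(mod, numeric(0), k = 0) + 0 * mod$center,
               mod$center, tolerance = 1e-12)
  expect_equal(unname(reconstruct_edges(mod, rep(0, 2))),
               unname(mod$center), tolerance = 1e-12)
  expect_error(reconstruct_edges(mod, rep(0, 2), k = 3), "length")
})

test_that("eigen-networks carry unit-norm loading weights and survive GraphML", {
  net <- random_network(6, 12, 0.3, seed = 5)
  pop <- simulate_population(net, list(
    state_spec("a", stats::setNames(rep(1.5, 6), net$nodes), 0.3, 0.5),
    state_spec("b", stats::setNames(rep(0.6, 6), net$nodes), 0.3, 0.5)),
    300, seed = 6)
  mod <- fit_pca(embed_cells(pop$values, net))
  en <- eigen_network(mod, 1, net)
  expect_equal(en$edges$weight, unname(mod$loadings[, 1]))
  expect_equal(sum(en$edges$weight^2), 1, tolerance = 1e-8)
  f <- tempfile(fileext = ".graphml")
  write_graphml(en, f, edge_weights = en$edges$weight)
  expect_equal(attr(read_graphml(f), "weights"), en$edges$weight,
               tolerance = 1e-12)
})

test_that("PCA output is invariant to row permutation and projection decorrelates", {
  E <- make_edge_data(n = 150, m = 5, seed = 7)
  mod <- fit_pca(E)
  mod_perm <- fit_pca(E[sample(nrow(E)), ])
  expect_equal(mod_perm$loadings, mod$loadings, tolerance = 1e-8)
  # idempotence under the scaling convention: training scores are already
  # exactly decorrelated, so a refit has nothing left to rotate jointly
  S <- project(mod, E)
  expect_equal(unname(stats::cor(S)), diag(5), tolerance = 1e-8)
  mod2 <- fit_pca(S)
  expect_equal(unname(mod2$evf), rep(1 / 5, 5), tolerance = 1e-8)
})
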