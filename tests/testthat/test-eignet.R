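# model-interface tests use a small fixed-K fit to stay fast
small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- default_scenario(seed = 11)
      pop <- simulate_population(sc$network, sc$states, 800, seed = 12)
      cache <<- list(sc = sc, pop = pop,
                     fit = eignet(pop$values, sc$network, K = 4, seed = 1))
    }
    cache
  }
})

test_that("the fitted model prints, summarizes and exposes coefficients", {
  x <- small_fit()
  expect_s3_class(x$fit, "eignet")
  expect_output(print(x$fit), "Eigen-network model")
  s <- summary(x$fit)
  expect_output(print(s), "archetypes explain")
  expect_equal(s$K, 4)
  expect_equal(sum(s$weights), 1, tolerance = 1e-8)
  expect_equal(dim(coef(x$fit)), c(124, 3))
  ll <- logLik(x$fit)
  expect_equal(attr(ll, "nobs"), 800)
  expect_equal(attr(ll, "df"), 3 + 4 * 3 + 4 * 6)
})

test_that("predict types are mutually consistent and match score_cells", {
  x <- small_fit()
  new <- simulate_population(x$sc$network, x$sc$states, 150, seed = 20)
  full <- score_cells(x$fit, new$values)
  expect_equal(nrow(full), 150)
  expect_identical(predict(x$fit, new$values, type = "class"), full$label)
  expect_equal(predict(x$fit, new$values, type = "surprisal"),
               full$surprisal_bits)
  sc <- predict(x$fit, new$values, type = "score")
  expect_equal(unname(sc[, 1]), full$PC1)
  post <- predict(x$fit, new$values, type = "posterior")
  expect_equal(rowSums(post), rep(1, 150), tolerance = 1e-8)
  expect_equal(predict(x$fit, new$values, type = "density"),
               2^(-full$surprisal_bits), tolerance = 1e-10)
  # in-sample predictions reuse the training scores
  expect_identical(predict(x$fit, type = "class"),
                   x$fit$train$classification$label)
})

test_that("residuals shrink as retained components grow", {
  x <- small_fit()
  r3 <- residuals(x$fit)
  expect_equal(dim(r3), c(800, 124))
  fit_full <- eignet(x$pop$values, x$sc$network, k = 10, K = 4, seed = 1)
  expect_lt(mean(residuals(fit_full)^2), mean(r3^2))
})

test_that("simulate draws from the fitted mixture reproducibly", {
  x <- small_fit()
  s1 <- simulate(x$fit, seed = 4, n = 500)
  s2 <- simulate(x$fit, seed = 4, n = 500)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 500)
  expect_equal(names(s1), c("component", "PC1", "PC2", "PC3"))
  both <- simulate(x$fit, nsim = 2, seed = 4, n = 50)
  expect_length(both, 2)
  # simulated scores classify back into their own components mostly
  cls <- classify_cells(x$fit$gmm, as.matrix(s1[, -1]))
  keep <- cls$label != "REJECT"
  expect_gt(mean(as.integer(as.character(cls$label[keep]))
                 == s1$component[keep]), 0.9)
})

test_that("representative networks reconstruct centroid edge activity", {
  x <- small_fit()
  reps <- representative_networks(x$fit)
  expect_length(reps, 4)
  v <- reconstruct_edges(x$fit$pca, x$fit$gmm$means[2, ], k = 3)
  expect_equal(reps[[2]]$edges$weight, unname(v))
  f <- tempfile(fileext = ".graphml")
  write_graphml(reps[[1]], f, edge_weights = reps[[1]]$edges$weight)
  expect_equal(attr(read_graphml(f), "weights"), reps[[1]]$edges$weight,
               tolerance = 1e-12)
})

test_that("a pure naive population concentrates in its mixture component", {
  x <- small_fit()
  naive <- x$sc$states[[3]]
  only <- simulate_population(x$sc$network,
                              list(state_spec(naive$name, naive$mean,
                                              naive$sdlog, 1)),
                              400, seed = 21)
  lab <- predict(x$fit, only$values, type = "class")
  kept <- lab[lab != "REJECT"]
  top <- names(which.max(table(kept)))
  expect_gte(mean(lab == top), 0.95 * mean(lab != "REJECT"))
  # and the dominant component is the one nearest the naive archetype
  arch_scores <- project(x$fit$pca,
                         matrix(state_archetype(x$sc$network, naive), 1,
                                dimnames = list("a", names(x$fit$pca$center))),
                         k = 3)
  d2 <- mahalanobis_sq(x$fit$gmm, arch_scores)
  expect_equal(top, as.character(which.min(d2)))
})

test_that("serialization round-trips scoring behavior exactly", {
  x <- small_fit()
  f <- tempfile(fileext = ".json")
  write_eignet(x$fit, f)
  back <- read_eignet(f)
  new <- simulate_population(x$sc$network, x$sc$states, 100, seed = 30)
  a <- score_cells(x$fit, new$values)
  b <- score_cells(back, new$values)
  expect_equal(b, a, tolerance = 1e-12)
  # JSON does not preserve the sign of negative zero; values are otherwise exact
  expect_equal(back$pca$loadings, x$fit$pca$loadings, tolerance = 1e-15)
  expect_equal(back$gmm$covariances, x$fit$gmm$covariances, tolerance = 1e-15)
})

test_that("plot method renders without error", {
  x <- small_fit()
  f <- tempfile(fileext = ".png")
  grDevices::png(f)
  expect_no_error(plot(x$fit, which = "scores"))
  grDevices::dev.off()
  expect_true(file.exists(f))
})
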