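test_that("a single-component fit recovers the sample mean and MLE covariance", {
  set.seed(1)
  x <- matrix(stats::rnorm(600, sd = 2), ncol = 2)
  g <- fit_gmm(x, K = 1, seed = 1)
  expect_equal(g$weights, 1)
  expect_equal(as.numeric(g$means), colMeans(x), tolerance = 1e-8)
  n <- nrow(x)
  expect_equal(g$covariances[, , 1], stats::cov(x) * (n - 1) / n,
               tolerance = 1e-6)
})

test_that("well-separated blobs are recovered to within 0.1 of the true means", {
  set.seed(2)
  mu <- rbind(c(0, 0), c(10, 10))   # 10 sigma apart
  x <- rbind(matrix(stats::rnorm(2000), ncol = 2),
             sweep(matrix(stats::rnorm(2000), ncol = 2), 2, mu[2, ], "+"))
  g <- fit_gmm(x, K = 2, seed = 1)
  est <- g$means[order(g$means[, 1]), ]
  expect_lt(max(abs(est - mu)), 0.1)
  expect_equal(sum(g$weights), 1, tolerance = 1e-10)
  # BIC stored in the minimized convention: k log n - 2 logL
  n_par <- (2 - 1) + 2 * 2 + 2 * 3
  expect_equal(g$bic, n_par * log(nrow(x)) - 2 * g$loglik, tolerance = 1e-6)
})

test_that("BIC selection finds one component for Gaussian data and the blob count otherwise", {
  set.seed(3)
  single <- matrix(stats::rnorm(1500), ncol = 3)
  sel1 <- select_components(single, K_range = 1:4, seed = 1)
  expect_equal(sel1$chosen, 1)
  expect_equal(length(sel1$bic), 4)
  expect_true(all(is.finite(sel1$bic)))

  two <- rbind(matrix(stats::rnorm(1000), ncol = 2),
               matrix(stats::rnorm(1000, mean = 8), ncol = 2))
  sel2 <- select_components(two, K_range = 1:5, seed = 1)
  expect_equal(sel2$chosen, 2)
  # the elbow of the same trace is also at the true component count
  sel2e <- select_components(two, K_range = 1:5, strategy = "elbow", seed = 1)
  expect_equal(sel2e$chosen, 2)
})

test_that("mixture density matches closed forms and the mclust evaluation", {
  # K = 1, identity covariance, d = 3: peak density (2 pi)^(-3/2)
  g <- manual_gmm(1, matrix(0, 1, 3), array(diag(3), c(3, 3, 1)))
  expect_equal(gmm_density(g, c(0, 0, 0)), (2 * pi)^(-1.5), tolerance = 1e-12)
  expect_lt(gmm_density(g, c(3, 0, 0)), gmm_density(g, c(1, 0, 0)))

  # d = 1 two-component density integrates to ~1 by quadrature
  g1 <- manual_gmm(c(0.3, 0.7), matrix(c(-1, 2), 2, 1),
                   array(c(0.5, 1.5), c(1, 1, 2)))
  grid <- seq(-12, 14, by = 0.01)
  expect_equal(sum(gmm_density(g1, matrix(grid, ncol = 1))) * 0.01, 1,
               tolerance = 1e-3)

  # cross-check a fitted model against mclust's own density routine:
  # fit_gmm(seed) wraps the same deterministic fit, so the parameters agree
  set.seed(4)
  x <- rbind(matrix(stats::rnorm(400), ncol = 2),
             matrix(stats::rnorm(400, mean = 4), ncol = 2))
  ref <- mclust::Mclust(x, G = 2, modelNames = "VVV", verbose = FALSE)
  g2 <- fit_gmm(x, K = 2, seed = 1)
  expect_equal(t(g2$means), unname(ref$parameters$mean), tolerance = 1e-12)
  ours <- gmm_density(g2, x)
  theirs <- mclust::dens(data = x, modelName = "VVV",
                         parameters = ref$parameters)
  expect_equal(ours, as.numeric(theirs), tolerance = 1e-8)
})

test_that("surprisal is -log2 density with the documented closed forms", {
  g <- manual_gmm(1, matrix(0, 1, 3), array(diag(3), c(3, 3, 1)))
  expect_equal(as.numeric(surprisal(g, c(0, 0, 0))), 1.5 * log2(2 * pi),
               tolerance = 1e-10)
  # a point where the density is exactly 0.25 carries 2 bits
  sigma <- 1 / (0.25 * sqrt(2 * pi))
  g1 <- manual_gmm(1, matrix(0, 1, 1), array(sigma^2, c(1, 1, 1)))
  expect_equal(as.numeric(surprisal(g1, 0)), 2, tolerance = 1e-10)
  # consistency with density wherever above the floor
  x <- matrix(stats::rnorm(30, sd = 2), ncol = 3)
  expect_equal(as.numeric(surprisal(g, x)), -log2(gmm_density(g, x)),
               tolerance = 1e-12)
  # monotone along a ray from the mean
  ray <- outer(seq(0, 5, by = 0.5), c(1, 1, 0) / sqrt(2))
  expect_true(all(diff(as.numeric(surprisal(g, ray))) > 0))
  # the floor keeps surprisal finite far away
  far <- as.numeric(surprisal(g, c(1e6, 0, 0)))
  expect_true(is.finite(far))
  expect_true(attr(surprisal(g, c(1e6, 0, 0)), "floored"))
})

test_that("classification takes the argmax posterior with a chi-square reject option", {
  g <- manual_gmm(c(0.5, 0.5), rbind(c(0, 0), c(6, 0)),
                  array(rep(diag(2), 2), c(2, 2, 2)))
  cls <- classify_cells(g, rbind(c(0, 0), c(6, 0), c(100, 100)))
  expect_equal(as.character(cls$label), c("1", "2", "REJECT"))
  expect_equal(rowSums(cls$posterior), rep(1, 3), tolerance = 1e-8)
  # rejected rows still carry posteriors
  expect_false(anyNA(cls$posterior[3, ]))
  # ties break to the lowest component index
  tie <- manual_gmm(c(0.5, 0.5), rbind(c(0, 0), c(0, 0)),
                    array(rep(diag(2), 2), c(2, 2, 2)))
  expect_equal(as.character(classify_cells(tie, c(0, 0))$label), "1")
  # the boundary is the chi-square quantile of the Mahalanobis distance
  r <- sqrt(stats::qchisq(0.9, df = 2))
  g1 <- manual_gmm(1, matrix(0, 1, 2), array(diag(2), c(2, 2, 1)))
  expect_equal(as.character(classify_cells(g1, c(r - 1e-6, 0))$label), "1")
  expect_equal(as.character(classify_cells(g1, c(r + 1e-6, 0))$label),
               "REJECT")
})

test_that("inliers are rejected at most ~10% and far outliers essentially always", {
  set.seed(5)
  g <- manual_gmm(c(0.6, 0.4), rbind(c(0, 0, 0), c(5, 5, 5)),
                  array(rep(diag(3), 2), c(3, 3, 2)))
  sim <- gmm_simulate(g, 10000, seed = 11)
  cls <- classify_cells(g, sim$x)
  rate <- mean(cls$label == "REJECT")
  expect_lte(rate, 0.10 + 3 * sqrt(0.1 * 0.9 / 10000))
  # points at >= 8 sigma from every mean
  dirs <- matrix(stats::rnorm(300 * 3), 300)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  far <- sweep(dirs * 40, 2, c(2.5, 2.5, 2.5), "+")
  stopifnot(all(mahalanobis_sq(g, far) >= 64))
  expect_gte(mean(classify_cells(g, far)$label == "REJECT"), 0.99)
})

test_that("fits and selections are reproducible under a fixed seed", {
  set.seed(6)
  x <- rbind(matrix(stats::rnorm(3000), ncol = 2),
             matrix(stats::rnorm(3000, mean = 6), ncol = 2))
  g1 <- fit_gmm(x, K = 2, seed = 9)
  g2 <- fit_gmm(x, K = 2, seed = 9)
  expect_identical(g1, g2)
  s1 <- select_components(x, K_range = 1:3, seed = 9)
  s2 <- select_components(x, K_range = 1:3, seed = 9)
  expect_identical(s1, s2)
})
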