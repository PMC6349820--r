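# Shared fixtures and independent oracles, built in code.

# A -> B activating, B -> C inhibitory
tiny_net <- function() {
  signed_network(data.frame(source = c("A", "B"),
                            target = c("B", "C"),
                            sign = c(1L, -1L)))
}

# Independent brute-force oracle for the embedding: loop over all n^2
# ordered pairs, apply the signed weight rule, then squeeze out non-edges
# in the network's edge order. Deliberately slow and index-based.
brute_force_embed <- function(v, net) {
  n <- length(net$nodes)
  A <- matrix(0, n, n)
  for (e in seq_len(nrow(net$edges))) {
    i <- which(net$nodes == net$edges$source[e])
    j <- which(net$nodes == net$edges$target[e])
    A[i, j] <- net$edges$sign[e]
  }
  flat <- numeric(0)
  pair <- character(0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    w <- if (A[i, j] == 0) 0
         else if (A[i, j] > 0) v[i] * v[j]
         else v[i] / v[j]
    flat <- c(flat, w)
    pair <- c(pair, paste(net$nodes[i], net$nodes[j]))
  }
  keep <- paste(net$edges$source, net$edges$target)
  unname(flat[match(keep, pair)])
}

random_instance <- function(seed, max_nodes = 10) {
  set.seed(seed)
  n <- sample(2:max_nodes, 1)
  m <- sample(seq(n - 1, n * (n - 1)), 1)
  net <- random_network(n, m, frac_inhibitory = stats::runif(1), seed = seed)
  v <- stats::runif(n, 0.1, 5)
  names(v) <- net$nodes
  list(net = net, v = v)
}

# hand-rolled GMM container for closed-form density checks
manual_gmm <- function(weights, means, covariances, reject_percentile = 0.9) {
  structure(list(K = length(weights), weights = weights, means = means,
                 covariances = covariances, d = ncol(means),
                 loglik = NA_real_, n = NA_integer_, bic = NA_real_,
                 reject_percentile = reject_percentile),
            class = "eignet_gmm")
}

# shared expensive fit on the default scenario (used by several
# acceptance checks); cached per test run
.acc_cache <- new.env(parent = emptyenv())
acceptance_fit <- function() {
  if (is.null(.acc_cache$fit)) {
    sc <- default_scenario(seed = 42)
    pop <- simulate_population(sc$network, sc$states, 5000, seed = 7)
    fit <- eignet(pop$values, sc$network, k = 3, K_range = 1:9,
                  selection = "min_bic", seed = 1)
    .acc_cache$scenario <- sc
    .acc_cache$pop <- pop
    .acc_cache$fit <- fit
  }
  list(scenario = .acc_cache$scenario, pop = .acc_cache$pop,
       fit = .acc_cache$fit)
}

write_tiny_edge_file <- function(path, lines = c(
  "# curated interactions",
  "A\tB\t+",
  "B\tC\t-")) {
  writeLines(lines, path)
  path
}
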