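#' Random signed regulatory network
#'
#' Samples a weakly connected signed directed network: a random spanning
#' arborescence guarantees connectivity, then the remaining edges are drawn
#' without replacement from the unused ordered pairs (i != j). Exactly
#' `round(frac_inhibitory * n_edges)` edges are inhibitory. Pure function
#' of its arguments and `seed`.
#'
#' @param n_nodes number of nodes
#' @param n_edges number of edges; must satisfy
#'   `n_nodes - 1 <= n_edges <= n_nodes * (n_nodes - 1)`
#' @param frac_inhibitory fraction of edges with sign -1, in \[0, 1\]
#' @param seed RNG seed
#' @return a [signed_network()] with nodes `n01, n02, ...`
#' @examples
#' net <- random_network(27, 124, 0.25, seed = 1)
#' sum(net$edges$sign == -1)   # 31
#' @export
random_network <- function(n_nodes, n_edges, frac_inhibitory = 0.25, seed = 1L) {
  if (frac_inhibitory < 0 || frac_inhibitory > 1)
    stopf("frac_inhibitory must be in [0, 1]")
  if (n_edges > n_nodes * (n_nodes - 1))
    stopf("n_edges = %d infeasible for %d nodes (max %d distinct ordered pairs)",
          n_edges, n_nodes, n_nodes * (n_nodes - 1))
  if (n_edges < n_nodes - 1)
    stopf("n_edges = %d cannot connect %d nodes", n_edges, n_nodes)
  with_seed(seed, {
    nodes <- sprintf("n%02d", seq_len(n_nodes))
    # spanning arborescence over a random node order
    perm <- sample.int(n_nodes)
    src <- perm[vapply(seq_len(n_nodes - 1),
                       function(i) sample.int(i, 1), 1L)]
    dst <- perm[seq(2, n_nodes)]
    used <- matrix(FALSE, n_nodes, n_nodes)
    used[cbind(src, dst)] <- TRUE
    free <- which(!used & !diag(TRUE, n_nodes))
    extra <- free[sample.int(length(free), n_edges - length(src))]
    i <- c(src, (extra - 1) %% n_nodes + 1)
    j <- c(dst, (extra - 1) %/% n_nodes + 1)
    sign <- rep(1L, n_edges)
    n_inh <- round(frac_inhibitory * n_edges)
    if (n_inh > 0) sign[sample.int(n_edges, n_inh)] <- -1L
    signed_network(data.frame(source = nodes[i], target = nodes[j],
                              sign = sign),
                   nodes = nodes)
  })
}

#' Specification of one latent cell state
#'
#' A state is a mean expression vector on the positive analysis scale plus
#' a per-node multiplicative lognormal noise level and a mixing proportion.
#'
#' @param name state label
#' @param mean named positive numeric vector (per node)
#' @param sdlog lognormal noise sd (log scale), scalar or per node
#' @param proportion mixing proportion in the population
#' @return object of class `state_spec`
#' @export
state_spec <- function(name, mean, sdlog = 0.15, proportion = NA_real_) {
  if (any(mean <= 0)) stopf("state means must be > 0")
  if (any(sdlog < 0)) stopf("sdlog must be >= 0")
  structure(list(name = name, mean = mean,
                 sdlog = rep_len(sdlog, length(mean)),
                 proportion = proportion),
            class = "state_spec")
}

#' Default four-state synthetic scenario
#'
#' Builds a complete study scenario with known ground truth: a 27-node,
#' 124-edge network (25% inhibitory edges) and four latent states —
#' a majority naive-like state (58%), a formative-like state (30%) with a
#' subset of nodes shifted up or down, an arrested/apoptotic state (10%)
#' with globally down-scaled means (x0.2) and one elevated apoptosis
#' marker node, and a rare primitive-endoderm-like state (2%) shifted on a
#' disjoint node subset. A fifth, somatic "MEF-like" state (strong
#' alternating up/down deviations from baseline) is supplied for
#' time-course simulations as an out-of-reference starting population,
#' together with a reprogramming-like schedule in which its mass drains
#' through a transient rare-state phase into arrested, formative and
#' finally naive states.
#'
#' Noise is multiplicative lognormal with sdlog 0.15 (about 15%
#' coefficient of variation) for every state.
#'
#' @param seed RNG seed fixing network topology and state means
#' @param n_nodes,n_edges,frac_inhibitory network dimensions
#' @return list with `network`, `states` (list of 4 [state_spec()]s with
#'   proportions summing to 1), `outlier_state` (MEF-like [state_spec()])
#'   and `schedule` (data.frame: `time` plus one proportion column per
#'   state, rows summing to 1)
#' @export
default_scenario <- function(seed = 42L, n_nodes = 27, n_edges = 124,
                             frac_inhibitory = 0.25) {
  network <- random_network(n_nodes, n_edges, frac_inhibitory, seed)
  with_seed(seed + 1000L, {
    base <- pmin(pmax(exp(stats::rnorm(n_nodes, log(1.2), 0.4)), 0.2), 4)
    names(base) <- network$nodes
    i_form <- sample.int(n_nodes, 8)
    i_pre <- sample(setdiff(seq_len(n_nodes), i_form), 8)
    formative <- base
    formative[i_form] <- formative[i_form] * rep_len(c(2.5, 0.4), 8)
    pre <- base
    pre[i_pre] <- pre[i_pre] * rep_len(c(3, 0.35), 8)
    arrested <- base * 0.2
    arrested[n_nodes] <- base[n_nodes] * 6   # apoptosis marker node
    mef <- base * rep_len(c(0.25, 3.5), n_nodes)
    states <- list(
      state_spec("arrested", arrested, 0.15, 0.10),
      state_spec("formative", formative, 0.15, 0.30),
      state_spec("naive", base, 0.15, 0.58),
      state_spec("pre", pre, 0.15, 0.02))
    schedule <- data.frame(
      time      = c(0, 4, 8, 12, 16, 20, 24, 30),
      mef       = c(1.00, 0.97, 0.92, 0.80, 0.60, 0.35, 0.15, 0.05),
      arrested  = c(0.00, 0.00, 0.00, 0.10, 0.25, 0.30, 0.30, 0.25),
      formative = c(0.00, 0.00, 0.00, 0.00, 0.05, 0.25, 0.40, 0.47),
      naive     = c(0.00, 0.00, 0.00, 0.00, 0.00, 0.02, 0.10, 0.20),
      pre       = c(0.00, 0.03, 0.08, 0.10, 0.10, 0.08, 0.05, 0.03))
    list(network = network, states = states,
         outlier_state = state_spec("mef", mef, 0.15, NA_real_),
         schedule = schedule)
  })
}

#' Simulate a cell population with known state labels
#'
#' Draws each cell's state from the mixing proportions, then sets its
#' per-node expression to the state mean times unit-mean lognormal noise
#' (`meanlog = -sdlog^2 / 2`), so empirical per-state means converge to the
#' specified means. Values are floored at `eps`.
#'
#' @param net a [signed_network()]; state means must be named by its nodes
#' @param states list of [state_spec()]s whose proportions sum to 1
#' @param n_cells number of cells
#' @param seed RNG seed
#' @param eps positive floor applied to the values
#' @return list with `values` (cells x nodes matrix, rownames
#'   `cell_00001...`) and `labels` (factor of state names)
#' @export
simulate_population <- function(net, states, n_cells, seed = 1L, eps = 1e-6) {
  props <- vapply(states, function(s) s$proportion, 1)
  if (abs(sum(props) - 1) > 1e-8)
    stopf("state proportions must sum to 1 (got %.4f)", sum(props))
  nm <- vapply(states, function(s) s$name, "")
  for (s in states)
    if (!identical(names(s$mean), net$nodes))
      stopf("state '%s' means are not aligned with the network nodes", s$name)
  with_seed(seed, {
    lab <- sample(nm, n_cells, replace = TRUE, prob = props)
    values <- draw_state_values(states[match(lab, nm)], length(net$nodes))
    colnames(values) <- net$nodes
    rownames(values) <- sprintf("cell_%05d", seq_len(n_cells))
    list(values = pmax(values, eps), labels = factor(lab, levels = nm))
  })
}

# stack one lognormal draw per cell given its state_spec (list parallel to
# rows); noise has unit mean
draw_state_values <- function(cell_states, n_nodes) {
  n <- length(cell_states)
  M <- do.call(rbind, lapply(cell_states, function(s) s$mean))
  SD <- do.call(rbind, lapply(cell_states, function(s) s$sdlog))
  noise <- exp(matrix(stats::rnorm(n * n_nodes), n, n_nodes) * SD - SD^2 / 2)
  M * noise
}

#' Simulate a reprogramming-like time course
#'
#' Draws an independent population at each scheduled time point with the
#' scheduled state proportions, recording ground-truth labels and times.
#'
#' @param net a [signed_network()]
#' @param states named list or list of [state_spec()]s covering every
#'   state column in `schedule` (proportions in the specs are ignored)
#' @param schedule data.frame with column `time` plus one column per state
#'   name; each row must sum to 1
#' @param n_cells_per_tp cells per time point
#' @param seed RNG seed
#' @param eps positive floor applied to the values
#' @return list with `values`, `labels`, `time` (per cell)
#' @export
simulate_timecourse <- function(net, states, schedule, n_cells_per_tp = 500,
                                seed = 1L, eps = 1e-6) {
  nm <- vapply(states, function(s) s$name, "")
  state_cols <- setdiff(names(schedule), "time")
  if (!all(state_cols %in% nm))
    stopf("schedule states missing from `states`: %s",
          paste(setdiff(state_cols, nm), collapse = ", "))
  P <- as.matrix(schedule[, state_cols, drop = FALSE])
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8))
    stopf("each schedule row must be a proportion vector summing to 1")
  with_seed(seed, {
    out_v <- vector("list", nrow(schedule))
    out_l <- vector("list", nrow(schedule))
    for (r in seq_len(nrow(schedule))) {
      lab <- sample(state_cols, n_cells_per_tp, replace = TRUE, prob = P[r, ])
      out_v[[r]] <- draw_state_values(states[match(lab, nm)],
                                      length(net$nodes))
      out_l[[r]] <- lab
    }
    values <- do.call(rbind, out_v)
    colnames(values) <- net$nodes
    rownames(values) <- sprintf("cell_%05d", seq_len(nrow(values)))
    list(values = pmax(values, eps),
         labels = factor(unlist(out_l), levels = nm),
         time = rep(schedule$time, each = n_cells_per_tp))
  })
}

#' Ground-truth archetype edge vector of a state
#'
#' The noise-free embedding of the state's mean expression — the edge
#' activity an average cell of that state would show. Used to score how
#' well centroid reconstructions recover the generating states.
#'
#' @param net a [signed_network()]
#' @param state a [state_spec()]
#' @return named edge-activity vector of length `n_edges(net)`
#' @export
state_archetype <- function(net, state) {
  vectorize(edge_weights(state$mean[net$nodes], adjacency(net)), net)
}
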