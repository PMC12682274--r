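# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: raw-formula evaluation, generic optimizers,
# exhaustive enumeration.

toy_path <- function(name) {
  system.file("extdata", name, package = "groomcircles")
}

toy_tables <- function() {
  list(
    interactions = read_interactions(toy_path("toy_interactions.csv")),
    metadata = read_metadata(toy_path("toy_metadata.csv"))
  )
}

# Bisection on the raw (non-stabilized) implicit equation, independent of
# solve_eta's stabilized evaluation and bracketing.
oracle_solve_eta <- function(t_bar, lower, upper) {
  g_raw <- function(eta) exp(eta) / (exp(eta) - 1) - 1 / eta
  uniroot(function(e) g_raw(e) - t_bar, lower = lower, upper = upper,
          tol = 1e-12)$root
}

# Numerical argmax of the log-likelihood by golden-section search.
oracle_ml_eta <- function(t_values, lower = -50, upper = 50) {
  optimize(function(e) log_likelihood(t_values, e),
           interval = c(lower, upper), maximum = TRUE, tol = 1e-10)$maximum
}

# Newman weighted modularity computed directly from the definition
# Q = sum_c (e_cc - a_c^2), from an undirected edge list.
oracle_modularity <- function(edges, membership) {
  # edges: data.frame(u, v, w); membership: named vector
  m <- sum(edges$w)
  comms <- unique(membership)
  q <- 0
  for (cc in comms) {
    inside <- membership[edges$u] == cc & membership[edges$v] == cc
    e_cc <- sum(edges$w[inside]) / m
    strength <- sum(edges$w[membership[edges$u] == cc]) +
      sum(edges$w[membership[edges$v] == cc])
    a_c <- strength / (2 * m)
    q <- q + e_cc - a_c^2
  }
  q
}

# All set partitions of n items as restricted-growth strings.
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, max_label) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(max_label + 1)) {
      recurse(c(prefix, lab), max(max_label, lab))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Exhaustive best modularity over every partition of a small graph.
oracle_best_modularity <- function(edges, vertices) {
  n <- length(vertices)
  best <- -Inf
  for (p in all_partitions(n)) {
    memb <- setNames(p, vertices)
    best <- max(best, oracle_modularity(edges, memb))
  }
  best
}

# igraph object from an undirected edge list, keeping isolated vertices.
graph_from_edges <- function(edges, vertices) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$u, to = edges$v),
    directed = FALSE, vertices = vertices
  )
  igraph::E(g)$weight <- edges$w
  g
}

# Two disconnected k-cliques with unit weights.
two_cliques <- function(k = 3) {
  pairs <- t(combn(k, 2))
  edges <- rbind(
    data.frame(u = paste0("x", pairs[, 1]), v = paste0("x", pairs[, 2]), w = 1),
    data.frame(u = paste0("y", pairs[, 1]), v = paste0("y", pairs[, 2]), w = 1)
  )
  vertices <- c(paste0("x", 1:k), paste0("y", 1:k))
  list(edges = edges, vertices = vertices,
       graph = graph_from_edges(edges, vertices),
       membership = setNames(rep(1:2, each = k), vertices))
}
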