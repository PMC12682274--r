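#' Symmetrize a directed grooming graph
#'
#' Modularity is defined on undirected graphs, so directed grooming weights
#' are collapsed by summation: the undirected weight of \{u, v\} is
#' directed(u to v) + directed(v to u). Isolated vertices are retained.
#' Total edge weight is conserved.
#'
#' @param graph A directed weighted igraph object.
#' @return An undirected weighted igraph object on the same vertex set.
#' @export
symmetrize <- function(graph) {
  if (!igraph::is_directed(graph)) return(graph)
  igraph::as_undirected(graph, mode = "collapse",
                        edge.attr.comb = list(weight = "sum", "ignore"))
}

#' Weighted Newman modularity of a partition
#'
#' \eqn{Q = \sum_c (e_{cc} - a_c^2)}, where \eqn{e_{cc}} is the fraction of
#' total edge weight inside community \eqn{c} and \eqn{a_c} the fraction of
#' weight incident to \eqn{c}: the excess of within-community weight over
#' the random expectation. \eqn{Q \le 1}; the all-in-one partition has
#' \eqn{Q = 0}.
#'
#' @param graph An undirected weighted igraph object with at least one edge.
#' @param membership Community labels: a vector (named by vertex or in
#'   vertex order) covering every vertex.
#' @return The modularity Q.
#' @examples
#' g <- igraph::make_full_graph(3) + igraph::make_full_graph(3)
#' igraph::E(g)$weight <- 1
#' modularity_q(g, c(1, 1, 1, 2, 2, 2)) # 0.5
#' @export
modularity_q <- function(graph, membership) {
  if (igraph::ecount(graph) == 0) {
    abort("modularity is undefined on a graph with no edges")
  }
  vn <- igraph::V(graph)$name
  if (!is.null(names(membership)) && !is.null(vn)) {
    if (!setequal(names(membership), vn)) {
      abort("`membership` names must cover every vertex exactly")
    }
    membership <- membership[vn]
  }
  if (length(membership) != igraph::vcount(graph) || anyNA(membership)) {
    abort("`membership` must assign every vertex exactly one label")
  }
  w <- igraph::E(graph)$weight %||% rep(1, igraph::ecount(graph))
  igraph::modularity(graph, as.integer(factor(membership)), weights = w)
}

#' Detect communities with a portfolio of heuristics
#'
#' Runs greedy agglomerative modularity optimization, Louvain-style
#' multilevel optimization, and the leading-eigenvector method on the
#' weighted undirected graph, all under the given seed, and returns the
#' partition with the largest weighted modularity.
#'
#' @param graph An undirected weighted igraph object (directed input is
#'   symmetrized first).
#' @param seed Integer seed making the stochastic heuristics reproducible.
#' @return An object of class `community_partition`: list with `membership`
#'   (named integer vector), `n_communities`, `q` and `method` (the winning
#'   heuristic).
#' @export
detect_communities <- function(graph, seed = 1L) {
  if (igraph::vcount(graph) == 0) abort("empty graph")
  if (igraph::is_directed(graph)) graph <- symmetrize(graph)
  if (igraph::ecount(graph) == 0) {
    # every vertex its own community; modularity undefined, reported as 0
    memb <- seq_len(igraph::vcount(graph))
    names(memb) <- igraph::V(graph)$name
    return(structure(
      list(membership = memb, n_communities = length(memb), q = 0,
           method = "singletons"),
      class = "community_partition"
    ))
  }
  w <- igraph::E(graph)$weight %||% rep(1, igraph::ecount(graph))
  runs <- list(
    fast_greedy = function() igraph::cluster_fast_greedy(graph, weights = w),
    louvain = function() igraph::cluster_louvain(graph, weights = w),
    leading_eigen = function() igraph::cluster_leading_eigen(graph, weights = w)
  )
  best <- NULL
  withr::with_seed(seed, {
    for (nm in names(runs)) {
      comm <- tryCatch(runs[[nm]](), error = function(e) NULL)
      if (is.null(comm)) next
      memb <- igraph::membership(comm)
      q <- modularity_q(graph, as.integer(memb))
      if (is.null(best) || q > best$q + 1e-12) {
        best <- list(membership = memb, q = q, method = nm)
      }
    }
  })
  # never return a split worse than the trivial all-in-one partition (Q = 0)
  if (best$q < 0) {
    memb <- rep(1L, igraph::vcount(graph))
    names(memb) <- igraph::V(graph)$name
    best <- list(membership = memb, q = 0, method = "all_in_one")
  }
  memb <- as.integer(best$membership)
  names(memb) <- igraph::V(graph)$name
  structure(
    list(membership = memb, n_communities = length(unique(memb)),
         q = best$q, method = best$method),
    class = "community_partition"
  )
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("Community partition: %d communities, Q = %.4f (%s)\n",
              x$n_communities, x$q, x$method))
  invisible(x)
}

#' @rdname detect_communities
#' @param x A `community_partition` object.
#' @param ... Unused.
#' @export
tidy.community_partition <- function(x, ...) {
  tibble(individual_id = names(x$membership), community = unname(x$membership))
}

#' Group-level structure summary: mean eta versus modularity
#'
#' For each group with at least one retained fitted ego, pairs the mean
#' estimated \eqn{\eta} with the modularity Q of the symmetrized grooming
#' graph (communities found by [detect_communities()]). Societies whose
#' members concentrate grooming on few partners (high \eqn{\eta}) tend to
#' segment into denser modules.
#'
#' @param networks Group-network tibble from [build_group_networks()].
#' @param fits Per-ego fit tibble from [fit_egos()] (columns `ego_id`,
#'   `group_id`, `eta`; a `species` column is carried through if present).
#' @param seed Seed for community detection.
#' @return A tibble: `group_id`, (`species`,) `n_egos`, `mean_eta`, `q`,
#'   `n_communities`.
#' @export
group_structure_table <- function(networks, fits, seed = 1L) {
  empty <- setdiff(networks$group_id, unique(fits$group_id))
  if (length(empty) > 0) {
    abort(paste0("group(s) with no retained fitted egos: ",
                 paste(empty, collapse = ", ")))
  }
  eta_summary <- fits %>%
    group_by(group_id) %>%
    summarise(
      n_egos = dplyr::n(),
      mean_eta = mean(eta),
      species = if ("species" %in% names(fits)) species[1] else NA_character_,
      .groups = "drop"
    )
  comm <- purrr::map(networks$graph, function(g) {
    detect_communities(symmetrize(g), seed = seed)
  })
  networks %>%
    mutate(
      q = purrr::map_dbl(comm, "q"),
      n_communities = purrr::map_int(comm, "n_communities")
    ) %>%
    select(group_id, q, n_communities) %>%
    inner_join(eta_summary, by = "group_id") %>%
    select(group_id, species, n_egos, mean_eta, q, n_communities)
}
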