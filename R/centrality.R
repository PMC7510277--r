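#' Shared top-ranked genes between two datasets
#'
#' Intersects the top-`k` gene sets of two rankings (one per independent
#' dataset). The intersection is ordered by the sum of the two ranks, best
#' first, ties broken by gene id.
#'
#' @param rank_a,rank_b Ranking tibbles (`gene`, `weight`), best first,
#'   e.g. from [tidy()] on an [mcbfs] fit.
#' @param k Top-set size (at most the length of each ranking;
#'   default 200).
#' @return Character vector of shared gene ids.
#' @export
shared_genes <- function(rank_a, rank_b, k = 200L) {
  rank_a <- validate_ranking(rank_a)
  rank_b <- validate_ranking(rank_b)
  k <- stopifnot_scalar_int(k, "k", min = 1L)
  if (k > nrow(rank_a) || k > nrow(rank_b)) {
    abort(sprintf("`k` = %d exceeds a ranking length (%d / %d).",
                  k, nrow(rank_a), nrow(rank_b)))
  }
  top_a <- rank_a$gene[seq_len(k)]
  top_b <- rank_b$gene[seq_len(k)]
  shared <- intersect(top_a, top_b)
  rank_sum <- match(shared, top_a) + match(shared, top_b)
  shared[order(rank_sum, shared)]
}

# ---- per-method node scores ------------------------------------------------
# All scores are named numeric vectors over every vertex, oriented so that
# larger means more central (eccentricity is reported as its reciprocal).
# Path-based scores are computed per connected component; singleton
# components score 0 by convention.

as_network <- function(net) {
  if (!igraph::is_igraph(net)) abort("`net` must be an igraph graph (see read_edge_list()).")
  if (igraph::is_directed(net)) net <- igraph::as_undirected(net, mode = "collapse")
  if (is.null(igraph::V(net)$name)) {
    net <- igraph::set_vertex_attr(net, "name", value = as.character(seq_len(igraph::vcount(net))))
  }
  igraph::simplify(net)
}

node_names <- function(net) igraph::V(net)$name

# distance matrix and number-of-shortest-paths matrix; unreachable pairs
# have d = Inf, nsp = 0
geodesic_counts <- function(net) {
  d <- igraph::distances(net)
  n <- nrow(d)
  adj <- d == 1
  nsp <- matrix(0, n, n, dimnames = dimnames(d))
  diag(nsp) <- 1
  if (n > 1L) {
    for (s in seq_len(n)) {
      ds <- d[s, ]
      lv <- 1
      repeat {
        at <- which(ds == lv)
        if (!length(at)) break
        prev <- ds == lv - 1
        for (t in at) {
          nsp[s, t] <- sum(nsp[s, prev & adj[, t]])
        }
        lv <- lv + 1
      }
    }
  }
  list(d = d, nsp = nsp)
}

#' Individual node-centrality scores
#'
#' The ten centrality measures used by the hub-gene ensemble, each as a
#' named score vector over all nodes, oriented so that larger is more
#' central. Definitions follow the Cytohubba family of measures:
#' * `centrality_degree()` — neighbour count.
#' * `centrality_closeness()` — reciprocal of the summed geodesic
#'   distance to the other nodes of the component (0 for singletons).
#' * `centrality_betweenness()` — unnormalized shortest-path betweenness
#'   over unordered pairs.
#' * `centrality_stress()` — number of shortest paths passing through the
#'   node.
#' * `centrality_eccentricity()` — reciprocal of the eccentricity within
#'   the component (0 for singletons).
#' * `centrality_radiality()` — `sum_w (diam + 1 - d(v, w)) / (n_c - 1)`
#'   over the node's component (diameter and size of that component).
#' * `centrality_mnc()` — maximum neighbourhood component: size of the
#'   largest connected component of the subgraph induced by the node's
#'   neighbours.
#' * `centrality_mcc()` — maximal clique centrality: `sum (|C| - 1)!`
#'   over the maximal cliques (size >= 2) containing the node, enumerated
#'   exactly; exponential worst case, intended for the few-hundred-node
#'   networks of this workflow.
#' * `centrality_bottleneck()` — for every root, a breadth-first
#'   shortest-path tree is built with the deterministic
#'   lowest-node-id parent rule; a node scores one point per root for
#'   which more than `n_c / 4` other tree nodes reach the root through it.
#' * `centrality_epc()` — edge percolated component: mean size, over
#'   seeded Monte-Carlo percolations keeping each edge independently with
#'   `retain_prob`, of the component containing the node.
#'
#' @param net An undirected igraph graph (see [read_edge_list]).
#' @param trials Number of percolation trials (default 1000).
#' @param retain_prob Edge retention probability in `[0, 1]`
#'   (default 0.5).
#' @param seed Integer seed for the percolation draws (required: EPC is
#'   the only stochastic measure and must be reproducible).
#' @return Named numeric vector of node scores.
#' @name centrality
NULL

#' @rdname centrality
#' @export
centrality_degree <- function(net) {
  net <- as_network(net)
  setNames(as.numeric(igraph::degree(net)), node_names(net))
}

#' @rdname centrality
#' @export
centrality_closeness <- function(net) {
  net <- as_network(net)
  d <- igraph::distances(net)
  score <- vapply(seq_len(nrow(d)), function(v) {
    dv <- d[v, -v]
    dv <- dv[is.finite(dv)]
    if (!length(dv)) 0 else 1 / sum(dv)
  }, numeric(1))
  setNames(score, node_names(net))
}

#' @rdname centrality
#' @export
centrality_betweenness <- function(net) {
  pair_path_scores(net)$betweenness
}

#' @rdname centrality
#' @export
centrality_stress <- function(net) {
  pair_path_scores(net)$stress
}

# betweenness and stress share the geodesic-count machinery
pair_path_scores <- function(net) {
  net <- as_network(net)
  gc <- geodesic_counts(net)
  d <- gc$d
  nsp <- gc$nsp
  n <- nrow(d)
  btw <- numeric(n)
  str <- numeric(n)
  if (n >= 3L) {
    for (v in seq_len(n)) {
      on_path <- outer(d[, v], d[v, ], `+`) == d & is.finite(d)
      cnt <- outer(nsp[, v], nsp[v, ]) * on_path
      cnt[v, ] <- 0
      cnt[, v] <- 0
      diag(cnt) <- 0
      str[v] <- sum(cnt) / 2
      frac <- cnt / pmax(nsp, 1)
      btw[v] <- sum(frac) / 2
    }
  }
  nm <- node_names(net)
  list(betweenness = setNames(btw, nm), stress = setNames(str, nm))
}

#' @rdname centrality
#' @export
centrality_eccentricity <- function(net) {
  net <- as_network(net)
  d <- igraph::distances(net)
  score <- vapply(seq_len(nrow(d)), function(v) {
    dv <- d[v, -v]
    dv <- dv[is.finite(dv)]
    if (!length(dv)) 0 else 1 / max(dv)
  }, numeric(1))
  setNames(score, node_names(net))
}

#' @rdname centrality
#' @export
centrality_radiality <- function(net) {
  net <- as_network(net)
  d <- igraph::distances(net)
  comp <- igraph::components(net)$membership
  score <- vapply(seq_len(nrow(d)), function(v) {
    members <- which(comp == comp[v])
    n_c <- length(members)
    if (n_c < 2L) return(0)
    dv <- d[v, setdiff(members, v)]
    diam <- max(d[members, members])
    sum(diam + 1 - dv) / (n_c - 1)
  }, numeric(1))
  setNames(score, node_names(net))
}

#' @rdname centrality
#' @export
centrality_mnc <- function(net) {
  net <- as_network(net)
  score <- vapply(seq_len(igraph::vcount(net)), function(v) {
    nb <- as.integer(igraph::neighbors(net, v))
    if (!length(nb)) return(0)
    sub <- igraph::induced_subgraph(net, nb)
    max(igraph::components(sub)$csize)
  }, numeric(1))
  setNames(score, node_names(net))
}

#' @rdname centrality
#' @export
centrality_mcc <- function(net) {
  net <- as_network(net)
  score <- setNames(numeric(igraph::vcount(net)), node_names(net))
  cliques <- igraph::max_cliques(net, min = 2L)
  for (cl in cliques) {
    score[as.integer(cl)] <- score[as.integer(cl)] + factorial(length(cl) - 1L)
  }
  score
}

#' @rdname centrality
#' @export
centrality_bottleneck <- function(net) {
  net <- as_network(net)
  nm <- node_names(net)
  n <- length(nm)
  d <- igraph::distances(net)
  comp <- igraph::components(net)$membership
  # ordering by name decides the "lowest id" parent deterministically
  name_rank <- rank(nm, ties.method = "first")
  adj <- lapply(seq_len(n), function(v) as.integer(igraph::neighbors(net, v)))
  score <- setNames(numeric(n), nm)
  for (r in seq_len(n)) {
    members <- which(comp == comp[r])
    n_c <- length(members)
    if (n_c < 2L) next
    # parent of w = lowest-id neighbour one step closer to the root
    desc <- setNames(numeric(n_c), members) # proper descendants in the BFS tree
    depth_order <- members[order(-d[r, members])]
    parent <- integer(n)
    for (w in depth_order) {
      if (w == r) next
      cand <- adj[[w]][d[r, adj[[w]]] == d[r, w] - 1]
      parent[w] <- cand[which.min(name_rank[cand])]
    }
    for (w in depth_order) {
      if (w == r) next
      desc[as.character(parent[w])] <- desc[as.character(parent[w])] +
        desc[as.character(w)] + 1
    }
    hits <- members[members != r & desc[as.character(members)] > n_c / 4]
    score[hits] <- score[hits] + 1
  }
  score
}

#' @rdname centrality
#' @export
centrality_epc <- function(net, trials = 1000L, retain_prob = 0.5, seed) {
  net <- as_network(net)
  trials <- stopifnot_scalar_int(trials, "trials", min = 1L)
  if (!is.numeric(retain_prob) || length(retain_prob) != 1L ||
      retain_prob < 0 || retain_prob > 1) {
    abort("`retain_prob` must be a probability in [0, 1].")
  }
  if (missing(seed) || is.null(seed)) abort("`seed` is required for the percolation draws.")
  n <- igraph::vcount(net)
  el <- igraph::as_edgelist(net, names = FALSE)
  total <- numeric(n)
  with_seed(seed, {
    for (trial in seq_len(trials)) {
      keep <- stats::runif(nrow(el)) < retain_prob
      total <- total + percolated_component_sizes(n, el[keep, , drop = FALSE])
    }
  })
  setNames(total / trials, node_names(net))
}

# union-find component sizes for a percolated edge set
percolated_component_sizes <- function(n, edges) {
  storage.mode(edges) <- "integer"
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      ra <- find(edges[e, 1L])
      rb <- find(edges[e, 2L])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  sizes <- tabulate(roots, nbins = n)
  sizes[roots]
}

CENTRALITY_METHODS <- c("degree", "mcc", "mnc", "closeness", "bottleneck",
                        "eccentricity", "radiality", "epc", "betweenness",
                        "stress")

#' Score every node with the centrality ensemble's methods
#'
#' Runs the requested centrality measures (all ten by default) and
#' assembles a node-by-method score table. All scores are oriented so
#' larger means more central.
#'
#' @inheritParams centrality
#' @param methods Character vector of method names among
#'   `r paste0('"', CENTRALITY_METHODS, '"', collapse = ", ")`.
#' @param epc_trials,epc_retain Percolation parameters passed to
#'   [centrality_epc].
#' @param seed Seed for the percolation draws; required when `"epc"` is
#'   among `methods`.
#' @return A tibble with column `node` plus one numeric column per method.
#' @export
centrality_table <- function(net, methods = CENTRALITY_METHODS,
                             epc_trials = 1000L, epc_retain = 0.5,
                             seed = NULL) {
  net <- as_network(net)
  if (igraph::vcount(net) == 0L) abort("the network has no nodes.")
  unknown <- setdiff(methods, CENTRALITY_METHODS)
  if (length(unknown)) {
    abort(sprintf("unknown centrality method(s): %s.", paste(unknown, collapse = ", ")))
  }
  scores <- lapply(methods, function(mth) {
    switch(mth,
      degree = centrality_degree(net),
      mcc = centrality_mcc(net),
      mnc = centrality_mnc(net),
      closeness = centrality_closeness(net),
      bottleneck = centrality_bottleneck(net),
      eccentricity = centrality_eccentricity(net),
      radiality = centrality_radiality(net),
      epc = centrality_epc(net, trials = epc_trials, retain_prob = epc_retain,
                           seed = seed %||% abort("`seed` is required when 'epc' is run.")),
      betweenness = centrality_betweenness(net),
      stress = centrality_stress(net)
    )
  })
  names(scores) <- methods
  dplyr::bind_cols(tibble(node = node_names(net)),
                   tibble::as_tibble(lapply(scores, unname)))
}

#' Weighted rank-average centrality ensemble
#'
#' Converts each method's scores to fractional ranks (most central =
#' rank 1, ties averaged) and aggregates them as a weighted mean rank.
#' Rank aggregation is used because the individual measures live on
#' incommensurable scales; it makes the ensemble invariant to any
#' strictly monotone rescaling of a method's scores.
#'
#' @param scores A tibble from [centrality_table] (column `node` plus one
#'   column per method).
#' @param weights Optional non-negative per-method weights (named, or in
#'   column order); default uniform. Normalized to sum 1.
#' @return A tibble of class `ensemble_ranking` with columns `node`,
#'   one `rank_<method>` column per method, and `aggregate` (weighted
#'   mean rank), sorted ascending by `aggregate`, ties by node id.
#' @export
ensemble_rank <- function(scores, weights = NULL) {
  if (!is.data.frame(scores) || !"node" %in% names(scores)) {
    abort("`scores` must be a centrality table with a `node` column.")
  }
  methods <- setdiff(names(scores), "node")
  if (!length(methods)) abort("no method columns to aggregate.")
  if (is.null(weights)) {
    weights <- rep(1 / length(methods), length(methods))
    names(weights) <- methods
  } else {
    if (is.null(names(weights))) names(weights) <- methods
    if (!setequal(names(weights), methods) || any(weights < 0) || sum(weights) == 0) {
      abort("`weights` must be non-negative, not all zero, one per method.")
    }
    weights <- weights[methods] / sum(weights)
  }
  ranks <- vapply(methods, function(mth) {
    rank(-scores[[mth]], ties.method = "average")
  }, numeric(nrow(scores)))
  aggregate <- as.vector(ranks %*% weights)
  out <- dplyr::bind_cols(
    tibble(node = scores$node),
    tibble::as_tibble(setNames(as.data.frame(ranks), paste0("rank_", methods))),
    tibble(aggregate = aggregate)
  )
  out <- out[order(out$aggregate, out$node), ]
  attr(out, "method_weights") <- weights
  class(out) <- c("ensemble_ranking", class(out))
  out
}

#' Most central nodes of an ensemble ranking
#'
#' @param ensemble An `ensemble_ranking` from [ensemble_rank].
#' @param k How many hubs (default 10).
#' @return Character vector of the `k` most central node ids.
#' @export
top_hubs <- function(ensemble, k = 10L) {
  if (!inherits(ensemble, "ensemble_ranking")) {
    abort("`ensemble` must come from ensemble_rank().")
  }
  k <- stopifnot_scalar_int(k, "k", min = 1L)
  if (k > nrow(ensemble)) {
    abort(sprintf("`k` = %d exceeds the %d ranked nodes.", k, nrow(ensemble)))
  }
  ensemble$node[seq_len(k)]
}

#' @describeIn ensemble_rank Aggregate rank per node as a bar chart (most
#'   central first), showing at most `top` nodes.
#' @param object An `ensemble_ranking`.
#' @param top Number of nodes displayed (default 20).
#' @param ... Unused.
#' @export
autoplot.ensemble_ranking <- function(object, top = 20L, ...) {
  df <- utils::head(as.data.frame(object), top)
  df$node <- factor(df$node, levels = rev(df$node))
  ggplot2::ggplot(df, ggplot2::aes(.data$aggregate, .data$node)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "aggregate rank (lower = more central)", y = NULL,
                  title = "Centrality ensemble ranking")
}
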