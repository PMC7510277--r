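triangle <- function() igraph::graph_from_literal(A - B, B - C, A - C)
path3 <- function() igraph::graph_from_literal(A - B, B - C)

test_that("worked examples: triangle, path and star", {
  tri <- triangle()
  expect_equal(centrality_degree(tri), c(A = 2, B = 2, C = 2))
  expect_equal(centrality_mcc(tri), c(A = 2, B = 2, C = 2)) # one 3-clique, 2! each
  expect_equal(centrality_mnc(tri), c(A = 2, B = 2, C = 2))

  p3 <- path3()
  expect_equal(centrality_betweenness(p3)[["B"]], 1)
  expect_equal(centrality_stress(p3)[["B"]], 1)
  expect_equal(centrality_closeness(p3)[["B"]], 0.5)
  expect_equal(centrality_mcc(p3)[["B"]], 2) # two maximal 2-cliques, 1! + 1!

  star <- igraph::make_star(4, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", "l1", "l2", "l3")
  expect_equal(centrality_mnc(star)[["hub"]], 1)

  # isolated node: component-based scores fall back to 0
  iso <- igraph::graph_from_literal(A - B) + igraph::vertices("Z")
  expect_equal(centrality_closeness(iso)[["Z"]], 0)
  expect_equal(centrality_radiality(iso)[["Z"]], 0)
  expect_equal(centrality_eccentricity(iso)[["Z"]], 0)
  expect_equal(centrality_mcc(iso)[["Z"]], 0)
})

test_that("bottleneck matches its tree-count definition on the worked examples", {
  p5 <- igraph::graph_from_literal(A - B, B - C, C - D, D - E)
  bn <- centrality_bottleneck(p5)
  expect_equal(bn[["C"]], 4) # a point from every other root
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- LETTERS[1:4]
  expect_equal(unname(centrality_bottleneck(k4)), rep(0, 4))
  two <- igraph::graph_from_literal(A - B)
  expect_equal(unname(centrality_bottleneck(two)), c(0, 0))
  expect_equal(centrality_bottleneck(p5), bf_bottleneck(adj_from_igraph(p5)))
})

test_that("combinatorial centralities match brute-force oracles on random graphs", {
  set.seed(401)
  for (i in 1:60) {
    n <- sample(3:7, 1)
    adj <- random_connected_graph(n, p_edge = runif(1, 0.3, 0.8))
    g <- igraph_from_adj(adj)
    bs <- bf_betweenness_stress(adj)
    expect_equal(centrality_betweenness(g), bs$betweenness)
    expect_equal(centrality_stress(g), bs$stress)
    expect_equal(centrality_closeness(g), bf_closeness(adj))
    expect_equal(centrality_eccentricity(g), bf_eccentricity(adj))
    expect_equal(centrality_radiality(g), bf_radiality(adj))
    expect_equal(centrality_mnc(g), bf_mnc(adj))
    expect_equal(centrality_mcc(g), bf_mcc(adj))
    expect_equal(centrality_degree(g), setNames(rowSums(adj), rownames(adj)))
    expect_equal(centrality_bottleneck(g), bf_bottleneck(adj))
  }
  # igraph's own betweenness as a second, independent cross-check
  set.seed(402)
  adj <- random_connected_graph(7, 0.4)
  g <- igraph_from_adj(adj)
  expect_equal(centrality_betweenness(g),
               igraph::betweenness(g)[names(centrality_betweenness(g))])
})

test_that("disconnected graphs score per component", {
  g <- igraph::graph_from_literal(A - B, B - C, X - Y) # path + separate edge
  adj <- adj_from_igraph(g)
  expect_equal(centrality_closeness(g), bf_closeness(adj))
  expect_equal(centrality_radiality(g), bf_radiality(adj))
  bs <- bf_betweenness_stress(adj)
  expect_equal(centrality_betweenness(g), bs$betweenness)
})

test_that("vertex-transitive graphs score all nodes equally under every method", {
  # bottleneck is excluded on the ring: its deterministic lowest-id parent
  # rule picks one of the two equal-length BFS branches, which is exactly
  # what makes it reproducible but not label-symmetric on even cycles
  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- LETTERS[1:6]
  tab <- centrality_table(ring,
                          methods = setdiff(mcbfs:::CENTRALITY_METHODS, "bottleneck"),
                          epc_retain = 1, seed = 5)
  for (mth in setdiff(names(tab), "node")) {
    expect_equal(stats::sd(tab[[mth]]), 0, info = paste("method", mth))
  }
  # on complete graphs every method, bottleneck included, is symmetric
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- LETTERS[1:5]
  tab5 <- centrality_table(k5, epc_retain = 1, seed = 5)
  for (mth in setdiff(names(tab5), "node")) {
    expect_equal(stats::sd(tab5[[mth]]), 0, info = paste("method", mth))
  }
})

test_that("EPC is reproducible, exact at the degenerate probabilities, and unbiased", {
  g <- igraph::graph_from_literal(A - B, B - C, C - D, A - C)
  e1 <- centrality_epc(g, trials = 50, retain_prob = 0.5, seed = 99)
  e2 <- centrality_epc(g, trials = 50, retain_prob = 0.5, seed = 99)
  expect_identical(e1, e2)

  comp_sizes <- igraph::components(g)$csize[igraph::components(g)$membership]
  expect_equal(unname(centrality_epc(g, trials = 3, retain_prob = 1, seed = 1)),
               unname(comp_sizes))
  expect_equal(unname(centrality_epc(g, trials = 3, retain_prob = 0, seed = 1)),
               rep(1, 4))

  # closed form on the 2-node graph: E[size] = 0.5 * 2 + 0.5 * 1 = 1.5
  two <- igraph::graph_from_literal(A - B)
  epc <- centrality_epc(two, trials = 1000, retain_prob = 0.5, seed = 7)
  se <- 0.5 / sqrt(1000)
  expect_lt(max(abs(epc - 1.5)), 3 * se)
  expect_error(centrality_epc(two, retain_prob = 1.5, seed = 1), "probability")
  expect_error(centrality_epc(two, retain_prob = 0.5), "seed")
})

test_that("the rank-average ensemble is monotone-invariant and respects weights", {
  set.seed(31)
  g <- simulate_graph(n_nodes = 30, hub_degree = 10, base_prob = 0.1, seed = 3)$network
  tab <- centrality_table(g, methods = c("degree", "closeness", "stress"))
  ens <- ensemble_rank(tab)
  # strictly monotone rescaling of one method's scores changes nothing
  tab2 <- tab
  tab2$degree <- exp(tab2$degree / 3)
  expect_equal(ensemble_rank(tab2)$node, ens$node)
  expect_equal(ensemble_rank(tab2)$aggregate, ens$aggregate)
  # single method: ensemble order is that method's order
  tab1 <- tab[, c("node", "degree")]
  e1 <- ensemble_rank(tab1)
  expect_equal(e1$node[1], tab$node[which.max(tab$degree)])
  expect_equal(sort(e1$aggregate), sort(rank(-tab$degree, ties.method = "average")))
  # all methods agreeing reproduce the common rank vector
  tab_same <- tibble::tibble(node = tab$node, m1 = tab$degree, m2 = tab$degree * 2)
  es <- ensemble_rank(tab_same)
  expect_equal(es$aggregate, sort(rank(-tab$degree, ties.method = "average")))
  # degenerate weights rejected
  expect_error(ensemble_rank(tab, weights = c(0, 0, 0)), "not all zero")
  expect_error(ensemble_rank(tab, weights = c(-1, 1, 1)), "non-negative")
})

test_that("shared_genes intersects top sets and orders by rank sum", {
  ra <- tibble::tibble(gene = c("g1", "g2", "g3", "g4"), weight = c(4, 3, 2, 1))
  rb <- tibble::tibble(gene = c("g2", "g3", "g4", "g1"), weight = c(4, 3, 2, 1))
  expect_equal(shared_genes(ra, rb, k = 3), c("g2", "g3"))
  expect_equal(shared_genes(ra, ra, k = 4), c("g1", "g2", "g3", "g4"))
  rc <- tibble::tibble(gene = c("x1", "x2"), weight = c(2, 1))
  expect_equal(shared_genes(ra[1:2, ], rc, k = 2), character(0))
  expect_error(shared_genes(ra, rb, k = 5), "exceeds")
})

test_that("the ensemble finds the planted hub and top_hubs slices it", {
  sim <- simulate_graph(seed = 7)
  tab <- centrality_table(sim$network, epc_trials = 200, seed = 7)
  ens <- ensemble_rank(tab)
  expect_equal(top_hubs(ens, 1), sim$hub)
  hubs10 <- top_hubs(ens, 10)
  expect_length(hubs10, 10L)
  expect_equal(top_hubs(ens, nrow(ens)), ens$node)
  expect_error(top_hubs(ens, nrow(ens) + 1), "exceeds")
})
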