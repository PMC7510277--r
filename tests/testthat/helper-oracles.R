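# Independent oracles used across the suite. Everything here is written
# against first principles (path enumeration, subset enumeration, generic
# numeric optimization) and never calls the implementation it checks.

# ---- tiny graph representation: adjacency matrix with dimnames ----------

adj_from_igraph <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g))
}

igraph_from_adj <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# distances by repeated matrix products: d(s,t) = smallest k with
# (adj^k)[s,t] > 0; Inf when unreachable
bf_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  diag(d) <- 0
  reach <- diag(n)
  pow <- diag(n)
  for (k in seq_len(n)) {
    pow <- pow %*% adj
    newly <- pow > 0 & !(reach > 0)
    d[newly] <- k
    reach <- reach + pow
  }
  d
}

# all shortest paths between s and t by exhaustive DFS over simple paths
bf_shortest_paths <- function(adj, s, t) {
  n <- nrow(adj)
  best <- list(len = Inf, paths = list())
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      len <- length(path) - 1L
      if (len < best$len) best <<- list(len = len, paths = list(path))
      else if (len == best$len) best$paths[[length(best$paths) + 1L]] <<- path
      return(invisible())
    }
    if (length(path) - 1L >= best$len) return(invisible())
    for (w in which(adj[v, ] > 0)) {
      if (!w %in% path) walk(c(path, w))
    }
  }
  walk(s)
  best
}

bf_betweenness_stress <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  str <- numeric(n)
  for (s in seq_len(n - 1L)) {
    for (t in seq(s + 1L, n)) {
      sp <- bf_shortest_paths(adj, s, t)
      if (!length(sp$paths)) next
      sigma <- length(sp$paths)
      for (v in setdiff(seq_len(n), c(s, t))) {
        through <- sum(vapply(sp$paths, function(p) v %in% p, logical(1)))
        str[v] <- str[v] + through
        btw[v] <- btw[v] + through / sigma
      }
    }
  }
  list(betweenness = setNames(btw, rownames(adj)),
       stress = setNames(str, rownames(adj)))
}

bf_closeness <- function(adj) {
  d <- bf_distances(adj)
  out <- vapply(seq_len(nrow(adj)), function(v) {
    dv <- d[v, -v]
    dv <- dv[is.finite(dv)]
    if (!length(dv)) 0 else 1 / sum(dv)
  }, numeric(1))
  setNames(out, rownames(adj))
}

bf_eccentricity <- function(adj) {
  d <- bf_distances(adj)
  out <- vapply(seq_len(nrow(adj)), function(v) {
    dv <- d[v, -v]
    dv <- dv[is.finite(dv)]
    if (!length(dv)) 0 else 1 / max(dv)
  }, numeric(1))
  setNames(out, rownames(adj))
}

bf_radiality <- function(adj) {
  d <- bf_distances(adj)
  n <- nrow(adj)
  out <- numeric(n)
  for (v in seq_len(n)) {
    members <- which(is.finite(d[v, ]))
    if (length(members) < 2L) next
    diam <- max(d[members, members])
    out[v] <- sum(diam + 1 - d[v, setdiff(members, v)]) / (length(members) - 1L)
  }
  setNames(out, rownames(adj))
}

# components of a small graph by reachability
bf_component_sizes <- function(adj) {
  d <- bf_distances(adj)
  vapply(seq_len(nrow(adj)), function(v) sum(is.finite(d[v, ])), numeric(1))
}

bf_mnc <- function(adj) {
  n <- nrow(adj)
  out <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] > 0)
    if (!length(nb)) return(0)
    sub <- adj[nb, nb, drop = FALSE]
    max(bf_component_sizes(sub))
  }, numeric(1))
  setNames(out, rownames(adj))
}

# maximal cliques (size >= 2) by exhaustive subset enumeration
bf_mcc <- function(adj) {
  n <- nrow(adj)
  score <- setNames(numeric(n), rownames(adj))
  is_clique <- function(S) all(adj[S, S][upper.tri(matrix(0, length(S), length(S)))] > 0)
  for (mask in seq_len(2^n - 1L)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(S) < 2L || !is_clique(S)) next
    maximal <- all(vapply(setdiff(seq_len(n), S), function(w) {
      !all(adj[w, S] > 0)
    }, logical(1)))
    if (maximal) score[S] <- score[S] + factorial(length(S) - 1L)
  }
  score
}

# bottleneck by direct simulation of the lowest-name-parent BFS trees,
# with the exclusive descendant count
bf_bottleneck <- function(adj) {
  n <- nrow(adj)
  nms <- rownames(adj)
  d <- bf_distances(adj)
  score <- setNames(numeric(n), nms)
  for (r in seq_len(n)) {
    members <- which(is.finite(d[r, ]))
    if (length(members) < 2L) next
    parent <- rep(NA_integer_, n)
    for (w in members) {
      if (w == r) next
      cand <- which(adj[w, ] > 0 & d[r, ] == d[r, w] - 1)
      parent[w] <- cand[order(nms[cand])][1L]
    }
    desc <- function(v) {
      kids <- which(!is.na(parent) & parent == v)
      if (!length(kids)) return(0L)
      sum(vapply(kids, function(k) desc(k) + 1L, integer(1)))
    }
    for (w in members) {
      if (w == r) next
      if (desc(w) > length(members) / 4) score[w] <- score[w] + 1
    }
  }
  score
}

# random connected graph on n named nodes (resamples until connected)
random_connected_graph <- function(n, p_edge = 0.5) {
  repeat {
    adj <- matrix(0L, n, n)
    upper <- which(upper.tri(adj))
    adj[upper] <- as.integer(runif(length(upper)) < p_edge)
    adj <- adj + t(adj)
    dimnames(adj) <- list(LETTERS[seq_len(n)], LETTERS[seq_len(n)])
    if (all(is.finite(bf_distances(adj)))) return(adj)
  }
}

# ---- generic numeric optimizers for the update-rule oracles --------------

# minimize b'W + delta ||W||^2 subject to sum(W) = 1 by solving the KKT
# linear system of the quadratic program (no closed-form shortcut)
qp_simplex_eq <- function(b, delta) {
  p <- length(b)
  K <- rbind(cbind(2 * delta * diag(p), rep(1, p)), c(rep(1, p), 0))
  solve(K, c(-b, 1))[seq_len(p)]
}

# minimize <P, B> + rho * sum(P log P) over the simplex by damped Newton
# on the reduced coordinates (P_m eliminated)
entropy_simplex_min <- function(B, rho, max_iter = 200L) {
  m <- length(B)
  if (m == 1L) return(1)
  q <- rep(1 / m, m - 1L)
  for (it in seq_len(max_iter)) {
    pm <- 1 - sum(q)
    grad <- B[-m] - B[m] + rho * (log(q) - log(pm))
    if (max(abs(grad)) < 1e-13) break
    H <- rho * (diag(1 / q, m - 1L) + 1 / pm)
    step <- solve(H, grad)
    lam <- 1
    repeat {
      qn <- q - lam * step
      if (all(qn > 0) && sum(qn) < 1) break
      lam <- lam / 2
    }
    q <- qn
  }
  c(q, 1 - sum(q))
}

# independent deterministic kNN written against dist(); same tie rules,
# different code path
oracle_knn <- function(train_x, train_y, test_x, k) {
  apply(test_x, 1L, function(x) {
    d <- sqrt(colSums((t(train_x) - x)^2))
    ord <- order(d, seq_along(d))
    nb <- train_y[ord[seq_len(k)]]
    tab <- table(nb)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) == 1L) winners else nb[nb %in% winners][1L]
  })
}

# Welch / pooled two-sample t statistic from the textbook formulas
oracle_t_stat <- function(x, y, var_equal = FALSE) {
  nx <- length(x); ny <- length(y)
  if (var_equal) {
    sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
    (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  } else {
    (mean(x) - mean(y)) / sqrt(var(x) / nx + var(y) / ny)
  }
}

# small labeled dataset used by several files
toy_dataset <- function() {
  expr_set(matrix(c(1, 2, 3, 4,
                    1.1, 2.1, 3.1, 4.1,
                    5, 6, 7, 8,
                    5.2, 6.2, 7.2, 8.2), nrow = 4, byrow = TRUE,
                  dimnames = list(paste0("s", 1:4), paste0("g", 1:4))),
           labels = c("a", "a", "b", "b"))
}
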