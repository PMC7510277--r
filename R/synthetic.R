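#' Simulate a labeled expression dataset with planted informative genes
#'
#' Generates a microarray-style continuous expression matrix: every gene
#' is Gaussian noise, and a planted subset of informative genes
#' additionally receives class-specific mean offsets, equally spaced so
#' that adjacent classes differ by `effect_size * noise_sd`. The default
#' scenario (60 samples, 500 genes, 20 informative, 2 balanced classes,
#' effect size 2) is the package's reference condition for recovery
#' experiments. Generation is a pure function of the scenario and seed.
#'
#' @param n_samples,n_genes,n_informative,n_classes Scenario dimensions.
#' @param effect_size Class-mean shift between adjacent classes in units
#'   of `noise_sd` (default 2).
#' @param noise_sd Within-class standard deviation (default 1).
#' @param class_proportions Optional simplex vector of length
#'   `n_classes` (default balanced). Sample counts are rounded; every
#'   class keeps at least one sample.
#' @param distribution `"gaussian"` (default) or `"lognormal"`, which
#'   exponentiates the Gaussian field for RNA-seq-like heavy tails (the
#'   planted structure then lives on the log scale).
#' @param informative_genes Optional integer positions or gene ids of the
#'   planted genes; default is a seeded random draw. Supplying them lets
#'   two simulated cohorts share one ground truth.
#' @param seed Integer seed (default 1).
#' @return A list with `data` (an [expr_set]), `informative` (character
#'   vector of planted gene ids) and `scenario` (the parameters).
#' @examples
#' sim <- simulate_expression(n_samples = 20, n_genes = 30, n_informative = 3,
#'                            seed = 7)
#' sim$informative
#' @export
simulate_expression <- function(n_samples = 60L, n_genes = 500L,
                                n_informative = 20L, n_classes = 2L,
                                effect_size = 2, noise_sd = 1,
                                class_proportions = NULL,
                                distribution = c("gaussian", "lognormal"),
                                informative_genes = NULL, seed = 1L) {
  distribution <- arg_match(distribution)
  n_samples <- stopifnot_scalar_int(n_samples, "n_samples", min = 2L)
  n_genes <- stopifnot_scalar_int(n_genes, "n_genes", min = 1L)
  n_informative <- stopifnot_scalar_int(n_informative, "n_informative", min = 0L)
  n_classes <- stopifnot_scalar_int(n_classes, "n_classes", min = 2L)
  if (n_informative > n_genes) abort("`n_informative` cannot exceed `n_genes`.")
  if (noise_sd <= 0) abort("`noise_sd` must be positive.")
  if (is.null(class_proportions)) {
    class_proportions <- rep(1 / n_classes, n_classes)
  }
  if (length(class_proportions) != n_classes || any(class_proportions <= 0) ||
      abs(sum(class_proportions) - 1) > 1e-8) {
    abort("`class_proportions` must be positive and sum to 1, one per class.")
  }
  counts <- pmax(1L, round(class_proportions * n_samples))
  while (sum(counts) != n_samples) { # fix rounding drift on the largest class
    i <- which.max(counts)
    counts[i] <- counts[i] + sign(n_samples - sum(counts))
  }
  gene_ids <- sprintf("g%04d", seq_len(n_genes))

  with_seed(seed, {
    labels <- rep(paste0("class_", seq_len(n_classes)), counts)
    X <- matrix(rnorm(n_samples * n_genes, sd = noise_sd), n_samples, n_genes)
    if (is.null(informative_genes)) {
      informative <- sort(sample.int(n_genes, n_informative))
    } else if (is.character(informative_genes)) {
      informative <- match(informative_genes, gene_ids)
      if (anyNA(informative)) abort("unknown gene id in `informative_genes`.")
    } else {
      informative <- as.integer(informative_genes)
      if (any(informative < 1L | informative > n_genes)) {
        abort("`informative_genes` positions out of range.")
      }
    }
    if (length(informative)) {
      class_idx <- rep(seq_len(n_classes), counts)
      offsets <- effect_size * noise_sd * (seq_len(n_classes) - (n_classes + 1) / 2)
      X[, informative] <- X[, informative] + offsets[class_idx]
    }
    if (distribution == "lognormal") X <- exp(X)
    data <- expr_set(X, labels,
                     sample_ids = sprintf("s%03d", seq_len(n_samples)),
                     gene_ids = gene_ids)
    list(data = data,
         informative = gene_ids[informative],
         scenario = list(n_samples = n_samples, n_genes = n_genes,
                         n_informative = n_informative, n_classes = n_classes,
                         effect_size = effect_size, noise_sd = noise_sd,
                         class_proportions = class_proportions,
                         distribution = distribution, seed = seed))
  })
}

#' Simulate an interaction network with a planted hub
#'
#' `"planted_hub"` (default) draws a sparse Erdos-Renyi background with
#' edge probability `base_prob` and wires one designated hub node to
#' `hub_degree` other nodes; `"erdos_renyi"` is the plain background;
#' `"preferential_attachment"` grows a Barabasi-Albert graph (its ground
#' truth is the highest-degree node). Generation is a pure function of
#' the scenario and seed.
#'
#' @param n_nodes Number of nodes (default 100).
#' @param model Graph model.
#' @param hub_degree Number of neighbours wired to the planted hub
#'   (default 20; must be below `n_nodes`).
#' @param base_prob Background edge probability (default 0.02).
#' @param seed Integer seed (default 1).
#' @return A list with `network` (an undirected simple igraph graph with
#'   node names `n001`, ...), `hub` (the ground-truth hub id) and
#'   `scenario`.
#' @export
simulate_graph <- function(n_nodes = 100L,
                           model = c("planted_hub", "preferential_attachment",
                                     "erdos_renyi"),
                           hub_degree = 20L, base_prob = 0.02, seed = 1L) {
  model <- arg_match(model)
  n_nodes <- stopifnot_scalar_int(n_nodes, "n_nodes", min = 2L)
  hub_degree <- stopifnot_scalar_int(hub_degree, "hub_degree", min = 1L)
  if (hub_degree >= n_nodes) abort("`hub_degree` must be below `n_nodes`.")
  if (base_prob < 0 || base_prob > 1) abort("`base_prob` must be in [0, 1].")
  ids <- sprintf("n%03d", seq_len(n_nodes))
  with_seed(seed, {
    if (model == "preferential_attachment") {
      g <- igraph::sample_pa(n_nodes, directed = FALSE)
      g <- igraph::set_vertex_attr(g, "name", value = ids)
      hub <- ids[which.max(igraph::degree(g))]
    } else {
      g <- igraph::sample_gnp(n_nodes, base_prob, directed = FALSE)
      g <- igraph::set_vertex_attr(g, "name", value = ids)
      hub <- NA_character_
      if (model == "planted_hub") {
        hub_idx <- 1L
        targets <- sample(setdiff(seq_len(n_nodes), hub_idx), hub_degree)
        g <- igraph::add_edges(g, rbind(hub_idx, targets))
        g <- igraph::simplify(g)
        hub <- ids[hub_idx]
      }
    }
    list(network = g, hub = hub,
         scenario = list(n_nodes = n_nodes, model = model,
                         hub_degree = hub_degree, base_prob = base_prob,
                         seed = seed))
  })
}
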