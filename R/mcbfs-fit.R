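#' Multi-scale clustering-based feature selection (MCBFS)
#'
#' Supervised gene weighting for a labeled expression matrix. A bank of
#' `m` bounded Gaussian-style dissimilarities at different bandwidths
#' measures each gene's within-class scatter; alternating closed-form
#' updates of a gene-weight simplex `W` and a kernel-weight simplex `P`
#' minimize the entropy- and ridge-regularized objective, with both
#' regularization strengths re-estimated adaptively each iteration. Genes
#' are ranked by their final weight, largest first.
#'
#' @param data An [expr_set], or a samples-x-genes data frame / matrix
#'   (with `labels` a vector or, for data frames, a label column name).
#' @param labels Class labels when `data` is not an `expr_set`.
#' @param m Number of distance functions (default 50).
#' @param alpha,beta Positive tuning constants for the adaptive ridge
#'   strength and entropy temperature (defaults 0.5 each).
#' @param max_iter Maximum number of alternating iterations (default 100).
#' @param tol Convergence threshold: stop once `max|dW|` and `max|dP|`
#'   both fall below it (default 1e-6).
#' @param sigma_grid Optional bandwidth multipliers of length `m`
#'   (default [default_sigma_grid]).
#' @param scale_genes Standardize every gene to zero mean and unit
#'   variance before fitting (default `TRUE`). The objective scores
#'   absolute within-class compactness, so on raw data it rewards genes
#'   that are merely flat; standardization makes the score a relative
#'   compactness (small exactly when the between-class component is
#'   large), which is what makes the ranking discriminative. Set to
#'   `FALSE` to fit raw values.
#' @param rho_fallback Entropy temperature used in the degenerate `m = 1`
#'   case (default 1).
#' @param keep_weights Also record the full `W` and `P` vectors at every
#'   iteration (memory grows with `max_iter * (p + m)`; meant for
#'   diagnostics on small problems).
#'
#' @return An object of class `mcbfs_fit` with elements
#'   `ranking` (tibble: `gene`, `weight`, `rank`), `W`, `P`,
#'   `trajectory` (tibble: `iteration`, `J`, `delta`, `rho`, `dW`, `dP`),
#'   `converged`, `dropped_genes` (zero-range genes removed before the
#'   fit), and the call parameters. Use [tidy()] for the ranking,
#'   [glance()] for a one-row fit summary, [autoplot()] for the
#'   optimization trajectory and [top_genes()] for the head of the
#'   ranking.
#'
#' @details Constant (zero-range) genes would otherwise be ranked best —
#'   zero scatter is maximal compactness — so they are dropped with a
#'   warning before fitting. Ties in the final weights are broken by input
#'   gene order, making the ranking deterministic. The whole procedure is
#'   deterministic; no random numbers are drawn.
#'
#' @examples
#' sim <- simulate_expression(n_samples = 30, n_genes = 50, n_informative = 5,
#'                            seed = 1)
#' fit <- mcbfs(sim$data, m = 10)
#' top_genes(fit, 5)
#' @export
mcbfs <- function(data, labels = NULL, m = 50L, alpha = 0.5, beta = 0.5,
                  max_iter = 100L, tol = 1e-6, sigma_grid = NULL,
                  scale_genes = TRUE, rho_fallback = 1,
                  keep_weights = FALSE) {
  data <- as_expr_set(data, labels)
  m <- stopifnot_scalar_int(m, "m", min = 1L)
  max_iter <- stopifnot_scalar_int(max_iter, "max_iter", min = 1L)
  if (alpha <= 0 || beta <= 0) abort("`alpha` and `beta` must be positive.")
  if (tol <= 0) abort("`tol` must be positive.")
  if (!is.null(sigma_grid) && length(sigma_grid) != m) {
    abort(sprintf("`sigma_grid` must have length m = %d.", m))
  }

  rng <- apply(data$values, 2L, function(v) max(v) - min(v))
  dropped <- colnames(data$values)[rng == 0]
  if (length(dropped)) {
    warn(sprintf("dropped %d constant gene(s) before fitting (e.g. '%s').",
                 length(dropped), dropped[1L]))
    if (length(dropped) == ncol(data$values)) {
      abort("degenerate data: every gene constant.")
    }
    data <- expr_set(data$values[, rng > 0, drop = FALSE], data$labels)
  }
  if (scale_genes) data <- transform_zscore(data)

  bank <- dissimilarity_bank(data, sigmas = sigma_grid, m = m)
  A <- bank$A
  p <- ncol(A)
  W <- rep(1 / p, p)
  P <- rep(1 / m, m)

  traj <- vector("list", max_iter)
  weights_hist <- if (keep_weights) vector("list", max_iter) else NULL
  converged <- FALSE
  iter <- 0L
  for (t in seq_len(max_iter)) {
    delta <- update_delta(A, W, P, alpha)
    rho <- update_rho(A, W, P, beta, fallback = rho_fallback)
    W_new <- update_gene_weights(A, P, delta, quiet = TRUE)
    P_new <- update_function_weights(A, W_new, rho)
    dW <- max(abs(W_new - W))
    dP <- max(abs(P_new - P))
    W <- W_new
    P <- P_new
    iter <- t
    traj[[t]] <- c(J = mcbfs_objective(A, W, P, delta, rho),
                   delta = delta, rho = rho, dW = dW, dP = dP)
    if (keep_weights) weights_hist[[t]] <- list(W = W, P = P)
    if (dW < tol && dP < tol) {
      converged <- TRUE
      break
    }
  }
  traj <- dplyr::bind_rows(lapply(traj[seq_len(iter)], function(x) as.list(x)))
  traj <- dplyr::mutate(traj, iteration = dplyr::row_number(), .before = 1L)

  ord <- order(-W, seq_along(W)) # ties keep input gene order
  ranking <- tibble(gene = colnames(A)[ord], weight = W[ord],
                    rank = seq_len(p))
  structure(list(
    ranking = ranking,
    W = setNames(W, colnames(A)),
    P = P,
    sigmas = bank$sigmas,
    gammas = bank$gammas,
    trajectory = traj,
    weights_history = if (keep_weights) weights_hist[seq_len(iter)] else NULL,
    converged = converged,
    iterations = iter,
    dropped_genes = dropped,
    params = list(m = m, alpha = alpha, beta = beta, max_iter = max_iter,
                  tol = tol, scale_genes = scale_genes)
  ), class = "mcbfs_fit")
}

#' Head of an MCBFS ranking
#'
#' @param fit An `mcbfs_fit`, or a ranking tibble (`gene`, `weight`).
#' @param k How many genes (1 to the number of ranked genes).
#' @return A tibble with the first `k` rows of the ranking.
#' @export
top_genes <- function(fit, k) {
  ranking <- if (inherits(fit, "mcbfs_fit")) fit$ranking else validate_ranking(fit)
  k <- stopifnot_scalar_int(k, "k", min = 1L)
  if (k > nrow(ranking)) {
    abort(sprintf("`k` = %d exceeds the %d ranked genes.", k, nrow(ranking)))
  }
  ranking[seq_len(k), , drop = FALSE]
}

#' @export
print.mcbfs_fit <- function(x, ...) {
  cat(sprintf("<mcbfs_fit> %d genes, m = %d kernels; %s after %d iteration(s)\n",
              nrow(x$ranking), x$params$m,
              if (x$converged) "converged" else "stopped at max_iter",
              x$iterations))
  cat("Top genes:\n")
  print(utils::head(x$ranking, 5L))
  invisible(x)
}

#' @describeIn mcbfs Ranking as a tibble (`gene`, `weight`, `rank`).
#' @param x An `mcbfs_fit`.
#' @param ... Unused.
#' @export
tidy.mcbfs_fit <- function(x, ...) x$ranking

#' @describeIn mcbfs One-row fit summary: iterations, convergence flag,
#'   final objective, final `delta`/`rho`, number of genes kept and
#'   dropped, and the effective number of kernels `exp(entropy(P))`.
#' @export
glance.mcbfs_fit <- function(x, ...) {
  last <- x$trajectory[nrow(x$trajectory), ]
  tibble(
    iterations = x$iterations,
    converged = x$converged,
    objective = last$J,
    delta = last$delta,
    rho = last$rho,
    n_genes = nrow(x$ranking),
    n_dropped = length(x$dropped_genes),
    effective_kernels = exp(-sum(xlogx(x$P)))
  )
}

#' @describeIn mcbfs Optimization trajectory: objective, `delta` and
#'   `rho` against iteration, on free y scales.
#' @param object An `mcbfs_fit`.
#' @export
autoplot.mcbfs_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trajectory[, c("iteration", "J", "delta", "rho")],
                            -"iteration", names_to = "quantity")
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$quantity), scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL,
                  title = "MCBFS optimization trajectory")
}

#' Gene-weight profile plot
#'
#' Weights in rank order, with an optional highlight set (e.g. planted
#' informative genes in a simulation).
#'
#' @param fit An `mcbfs_fit`.
#' @param highlight Character vector of gene ids drawn in a second colour.
#' @param top Show only the first `top` ranks (default all).
#' @return A ggplot object.
#' @export
plot_gene_weights <- function(fit, highlight = NULL, top = NULL) {
  stopifnot(inherits(fit, "mcbfs_fit"))
  df <- fit$ranking
  if (!is.null(top)) df <- utils::head(df, top)
  df$highlighted <- df$gene %in% (highlight %||% character(0))
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$weight,
                                   colour = .data$highlighted)) +
    ggplot2::geom_point(size = 0.9, show.legend = !is.null(highlight)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
                                 name = "highlighted") +
    ggplot2::labs(x = "rank", y = "weight", title = "MCBFS gene weights")
}
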