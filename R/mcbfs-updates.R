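#' Per-class mean expression (cluster centers)
#'
#' Classes are treated as known clusters; the center of class *i* is the
#' arithmetic mean of its samples, gene by gene.
#'
#' @param data An [expr_set], or a samples-x-genes matrix / data frame.
#' @param labels Class labels when `data` is not an `expr_set`.
#' @return A list with `centers` (classes x genes matrix, rows named by
#'   class) and `class_sizes` (named integer vector).
#' @export
class_centers <- function(data, labels = NULL) {
  data <- as_expr_set(data, labels)
  X <- data$values
  lv <- levels(data$labels)
  centers <- do.call(rbind, lapply(lv, function(cl) {
    colMeans(X[data$labels == cl, , drop = FALSE])
  }))
  dimnames(centers) <- list(lv, colnames(X))
  list(centers = centers, class_sizes = setNames(tabulate(data$labels), lv))
}

#' Default bandwidth-multiplier grid
#'
#' The multi-scale dissimilarity bank uses `m` Gaussian-style kernels whose
#' bandwidths are a common data-derived scale times a multiplier
#' `sigma_n`. The default grid is geometric from `1e-2` to `1e2`,
#' spanning sub-range to super-range length scales as is common in
#' multi-kernel learning; `m = 1` anchors the single kernel at 1.
#'
#' @param m Number of distance functions (kernels), a positive integer.
#' @return Strictly increasing vector of `m` positive multipliers.
#' @export
default_sigma_grid <- function(m, lower = 1e-2, upper = 1e2) {
  m <- stopifnot_scalar_int(m, "m", min = 1L)
  if (m == 1L) return(1)
  10^seq(log10(lower), log10(upper), length.out = m)
}

#' Kernel bandwidths from gene ranges
#'
#' Each gene's range (max minus min over all samples) is computed; the
#' bandwidth of kernel *n* is
#' `gamma_n = sigma_n * (max(ranges) + min(ranges)) / 2`, one global scale
#' per kernel shared by every gene.
#'
#' @param sigmas Positive multipliers, one per kernel.
#' @param data An [expr_set] or matrix (with `labels` then ignored for the
#'   ranges, which use all samples).
#' @inheritParams class_centers
#' @return A list with `gammas` (length `m`) and `gene_ranges` (length `p`,
#'   named by gene).
#' @export
compute_gammas <- function(sigmas, data, labels = NULL) {
  if (!is.numeric(sigmas) || any(sigmas <= 0)) abort("`sigmas` must be positive.")
  X <- if (inherits(data, "expr_set")) data$values else as.matrix(data)
  rng <- apply(X, 2L, function(v) max(v) - min(v))
  if (all(rng == 0)) abort("degenerate data: every gene constant.")
  gammas <- sigmas * (max(rng) + min(rng)) / 2
  list(gammas = gammas, gene_ranges = rng)
}

#' Multi-scale dissimilarity bank
#'
#' For kernel *n* and gene *k*, sums the bounded dissimilarity
#' `d_n(x, v) = 1 - exp(-gamma_n * (x - v)^2)` between every sample's
#' expression and its own class center:
#' `A[n, k] = sum_j (1 - exp(-gamma_n * (x_jk - v_{class(j),k})^2))`.
#' The bank depends only on the data and labels, so it is computed once
#' per fit and never changes across iterations.
#'
#' @inheritParams class_centers
#' @param sigmas Bandwidth multipliers (default [default_sigma_grid] of
#'   length `m`).
#' @param m Number of kernels, used when `sigmas` is `NULL`.
#' @return A list of class `dissimilarity_bank`: `A` (m x p matrix, genes
#'   named), `gammas`, `sigmas`, `gene_ranges`.
#' @export
dissimilarity_bank <- function(data, labels = NULL, sigmas = NULL, m = 50L) {
  data <- as_expr_set(data, labels)
  sigmas <- sigmas %||% default_sigma_grid(m)
  cc <- class_centers(data)
  gm <- compute_gammas(sigmas, data)
  X <- data$values
  D2 <- (X - cc$centers[as.integer(data$labels), , drop = FALSE])^2
  A <- do.call(rbind, lapply(gm$gammas, function(g) colSums(1 - exp(-g * D2))))
  dimnames(A) <- list(NULL, colnames(X))
  structure(list(A = A, gammas = gm$gammas, sigmas = sigmas,
                 gene_ranges = gm$gene_ranges),
            class = "dissimilarity_bank")
}

#' Closed-form update of the gene-weight simplex
#'
#' Minimizes the kernel-weighted within-class scatter plus the ridge
#' penalty `delta * sum(W^2)` subject to `sum(W) = 1`, via the Lagrangian
#' closed form
#' `W_k = 1/p + (1/(2 delta)) * (mean_k(b) - b_k)` with
#' `b_k = sum_n P_n A[n, k]`. The equality-constrained solution can leave
#' the box, so negative entries are clipped to zero and the vector is
#' renormalized (with a message when that projection triggers).
#'
#' @param A m x p dissimilarity bank matrix (or a `dissimilarity_bank`).
#' @param P Kernel weights on the simplex, length m.
#' @param delta Positive ridge strength.
#' @param quiet Suppress the clipping message.
#' @param clip Project back onto the box after the equality-constrained
#'   solve (default `TRUE`); `clip = FALSE` returns the raw closed form,
#'   which may contain negative entries.
#' @return Gene weights on the simplex, length p.
#' @export
update_gene_weights <- function(A, P, delta, quiet = FALSE, clip = TRUE) {
  A <- bank_matrix(A)
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0) {
    abort("`delta` must be a single positive number.")
  }
  check_simplex(P, "P")
  p <- ncol(A)
  b <- as.vector(P %*% A)
  W <- 1 / p + (1 / (2 * delta)) * (sum(b) / p - b)
  if (clip && any(W < 0)) {
    if (!quiet) inform(sprintf("clipped %d negative gene weight(s) to zero.", sum(W < 0)))
    W[W < 0] <- 0
    W <- W / sum(W)
  }
  W
}

#' Entropy-regularized update of the kernel-weight simplex
#'
#' With `B_n = sum_k W_k A[n, k]`, the minimizer of
#' `sum(P * B) + rho * sum(P * log(P))` over the simplex is the softmax
#' `P_n = exp(-B_n / rho) / sum(exp(-B / rho))`, computed with a max-shift
#' for numerical stability.
#'
#' @inheritParams update_gene_weights
#' @param W Gene weights on the simplex, length p.
#' @param rho Positive entropy temperature.
#' @return Kernel weights on the simplex, length m.
#' @export
update_function_weights <- function(A, W, rho) {
  A <- bank_matrix(A)
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0) {
    abort("`rho` must be a single positive number.")
  }
  check_simplex(W, "W")
  B <- as.vector(A %*% W)
  z <- -B / rho
  z <- z - max(z)
  exp(z) / sum(exp(z))
}

#' Adaptive ridge strength
#'
#' `delta = alpha * sum_n P_n B_n / sum_k W_k^2`, keeping the ridge on the
#' same order of magnitude as the scatter term at the current iterate.
#'
#' @inheritParams update_function_weights
#' @param P Kernel weights from the previous iterate.
#' @param alpha Positive tuning constant (default 0.5).
#' @return A single positive number.
#' @export
update_delta <- function(A, W, P, alpha = 0.5) {
  A <- bank_matrix(A)
  check_simplex(W, "W")
  check_simplex(P, "P")
  spb <- sum(P * as.vector(A %*% W))
  if (spb <= 0) abort("degenerate: zero within-class scatter.")
  alpha * spb / sum(W^2)
}

#' Adaptive entropy temperature
#'
#' `rho = beta * sum_n P_n B_n / |sum_n P_n log(P_n)|`. The entropy in the
#' denominator is non-positive, so its absolute value is taken to keep the
#' temperature positive while preserving the magnitude. A one-hot `P` has
#' zero entropy: with a single kernel (`m = 1`) the configured fallback is
#' returned and `P` stays `(1)`; otherwise it is an error.
#'
#' @inheritParams update_delta
#' @param beta Positive tuning constant (default 0.5).
#' @param fallback Temperature returned in the degenerate `m = 1` case.
#' @return A single positive number.
#' @export
update_rho <- function(A, W, P, beta = 0.5, fallback = 1) {
  A <- bank_matrix(A)
  check_simplex(W, "W")
  check_simplex(P, "P")
  ent <- sum(xlogx(P))
  if (ent == 0) {
    if (length(P) == 1L) return(fallback)
    abort("kernel weights collapsed to one-hot: entropy is zero.")
  }
  spb <- sum(P * as.vector(A %*% W))
  if (spb <= 0) abort("degenerate: zero within-class scatter.")
  beta * spb / abs(ent)
}

#' Objective value
#'
#' `J = sum_n P_n sum_k W_k A[n,k] + delta * sum(W^2) + rho * sum(P log P)`
#' with natural logs and the `0 log 0 := 0` convention.
#'
#' @inheritParams update_delta
#' @param delta,rho Positive regularization strengths.
#' @return A single number.
#' @export
mcbfs_objective <- function(A, W, P, delta, rho) {
  A <- bank_matrix(A)
  sum(P * as.vector(A %*% W)) + delta * sum(W^2) + rho * sum(xlogx(P))
}

bank_matrix <- function(A) {
  if (inherits(A, "dissimilarity_bank")) A <- A$A
  if (!is.matrix(A) || !is.numeric(A)) abort("`A` must be an m x p numeric matrix.")
  A
}
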