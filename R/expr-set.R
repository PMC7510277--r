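#' Labeled expression dataset
#'
#' A light container for a labeled expression matrix: a numeric matrix of
#' `s` samples by `p` genes plus one class label per sample. All analysis
#' functions in the package accept either an `expr_set` or a plain data
#' frame / matrix together with a label vector.
#'
#' @param values Numeric matrix or data frame, samples in rows, genes in
#'   columns. Row names (or `sample_ids`) identify samples; column names
#'   (or `gene_ids`) identify genes.
#' @param labels Vector of class labels, one per sample; at least two
#'   distinct values.
#' @param sample_ids,gene_ids Optional identifier vectors overriding the
#'   dimnames of `values`.
#'
#' @return An object of class `expr_set`: a list with elements `values`
#'   (matrix with dimnames), and `labels` (factor with levels in order of
#'   first appearance).
#'
#' @details Internal class indices follow the order of first appearance of
#'   each label, so results are invariant to how labels happen to sort.
#'   Missing values are rejected: upstream imputation is deliberately out
#'   of scope.
#'
#' @examples
#' es <- expr_set(matrix(rnorm(12), 4, 3), labels = c("a", "a", "b", "b"))
#' es
#' @export
expr_set <- function(values, labels, sample_ids = NULL, gene_ids = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix or data frame (samples x genes).")
  }
  s <- nrow(values)
  p <- ncol(values)
  if (s < 2L || p < 1L) abort("need at least 2 samples and 1 gene.")
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    abort(sprintf("missing value at sample %d, gene %d; impute or drop upstream.",
                  bad[[1L]], bad[[2L]]))
  }
  sample_ids <- as.character(sample_ids %||% rownames(values) %||% paste0("sample_", seq_len(s)))
  gene_ids <- as.character(gene_ids %||% colnames(values) %||% paste0("gene_", seq_len(p)))
  if (length(sample_ids) != s) abort("`sample_ids` length must match the number of rows.")
  if (length(gene_ids) != p) abort("`gene_ids` length must match the number of columns.")
  if (anyDuplicated(sample_ids)) {
    abort(sprintf("duplicate sample id: '%s'.", sample_ids[duplicated(sample_ids)][1L]))
  }
  if (anyDuplicated(gene_ids)) {
    abort(sprintf("duplicate gene id: '%s'.", gene_ids[duplicated(gene_ids)][1L]))
  }
  if (length(labels) != s) {
    abort(sprintf("%d labels supplied for %d samples.", length(labels), s))
  }
  if (anyNA(labels)) abort("labels contain missing values.")
  labels <- factor(as.character(labels), levels = unique(as.character(labels)))
  if (nlevels(labels) < 2L) abort("need at least 2 distinct class labels.")
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(list(values = values, labels = labels), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("<expr_set> %d samples x %d genes, %d classes (%s)\n",
              nrow(x$values), ncol(x$values), nlevels(x$labels),
              paste(sprintf("%s: %d", levels(x$labels), tabulate(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)

#' @describeIn expr_set Convert to a tibble: one row per sample with a
#'   `sample_id` column, a `label` column, and one column per gene.
#' @param x An `expr_set`.
#' @param ... Unused.
#' @export
as_tibble.expr_set <- function(x, ...) {
  out <- tibble::as_tibble(x$values)
  dplyr::bind_cols(
    tibble(sample_id = rownames(x$values), label = as.character(x$labels)),
    out
  )
}

# Coerce the (data, labels) pair every analysis entry point accepts into an
# expr_set. `data` may already be one (labels then ignored), or a matrix /
# data frame with `labels` either a vector or the name of one of its columns.
as_expr_set <- function(data, labels = NULL) {
  if (inherits(data, "expr_set")) return(data)
  if (is.data.frame(data)) {
    if (is.character(labels) && length(labels) == 1L && labels %in% names(data)) {
      lab <- data[[labels]]
      keep <- setdiff(names(data), c(labels, "sample_id"))
      ids <- if ("sample_id" %in% names(data)) data[["sample_id"]] else rownames(data)
      return(expr_set(as.matrix(data[keep]), lab, sample_ids = ids))
    }
  }
  if (is.null(labels)) abort("supply `labels` (a vector, or a column name of `data`).")
  expr_set(data, labels)
}

#' Restrict an expression dataset to a gene subset
#'
#' @param data An `expr_set`.
#' @param genes Character vector of gene ids (order preserved).
#' @return An `expr_set` with only the requested genes.
#' @export
select_genes <- function(data, genes) {
  stopifnot(inherits(data, "expr_set"))
  genes <- as.character(genes)
  if (length(genes) == 0L) abort("`genes` must name at least one gene.")
  missing <- setdiff(genes, colnames(data$values))
  if (length(missing)) {
    abort(sprintf("genes not in dataset: %s.", paste(missing, collapse = ", ")))
  }
  expr_set(data$values[, genes, drop = FALSE], data$labels)
}

#' Per-gene transforms for expression values
#'
#' Loading applies no normalization; these explicit transforms cover the
#' common preprocessing choices. `transform_zscore()` centers and scales
#' each gene to unit variance (constant genes are left centered at zero);
#' `transform_log()` applies `log2(x + offset)`.
#'
#' @param data An `expr_set`.
#' @param offset Pseudocount added before the log (default 1).
#' @return A transformed `expr_set`.
#' @export
transform_zscore <- function(data) {
  stopifnot(inherits(data, "expr_set"))
  v <- scale(data$values)
  v[, attr(v, "scaled:scale") == 0] <- 0
  expr_set(v[, , drop = FALSE], data$labels)
}

#' @rdname transform_zscore
#' @export
transform_log <- function(data, offset = 1) {
  stopifnot(inherits(data, "expr_set"))
  if (any(data$values + offset <= 0)) {
    abort("log transform undefined: values + offset must be positive.")
  }
  expr_set(log2(data$values + offset), data$labels)
}
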