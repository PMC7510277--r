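#' Read a labeled expression matrix from delimited text
#'
#' Reads a TSV/CSV expression dump with ids in the first row and column and
#' resolves a class label for every sample. The dominant convention for
#' expression text dumps puts genes in rows, so that is the default
#' orientation; internally everything is normalized to samples x genes.
#'
#' @param path Path to the expression table. The delimiter is sniffed from
#'   the extension (`.csv` is comma, anything else tab) and can be
#'   overridden with `delim`.
#' @param orientation `"genes_as_rows"` (default) or `"samples_as_rows"`.
#' @param label_source Where the class labels come from: a path to a label
#'   file (either one label per line in sample order, or two columns
#'   `sample_id<TAB>label`), a character vector of labels (one per
#'   sample), or the id of a row (for `genes_as_rows`) / column (for
#'   `samples_as_rows`) of the matrix itself that carries the labels and is
#'   removed from the numeric body.
#' @param delim Field delimiter; `NULL` (default) sniffs from the extension.
#'
#' @return An [expr_set].
#'
#' @details Non-numeric or empty body cells are a load-time error naming
#'   the offending row and column: silent coercion to `NA` would defeat the
#'   no-missing-values invariant downstream code relies on.
#'
#' @export
read_expression <- function(path,
                            orientation = c("genes_as_rows", "samples_as_rows"),
                            label_source,
                            delim = NULL) {
  orientation <- arg_match(orientation)
  delim <- delim %||% sniff_delim(path)
  raw <- utils::read.delim(path, sep = delim, header = TRUE, row.names = NULL,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(raw) < 2L) abort(sprintf("'%s': expected an id column plus data columns.", path))
  row_ids <- raw[[1L]]
  body <- raw[, -1L, drop = FALSE]
  col_ids <- colnames(body)

  label_vec <- NULL
  if (is.character(label_source) && length(label_source) == 1L && file.exists(label_source)) {
    label_vec <- NA # resolved after orientation, needs sample ids
  } else if (is.character(label_source) && length(label_source) == 1L) {
    # a row/column of the matrix carrying labels
    if (orientation == "genes_as_rows") {
      hit <- which(row_ids == label_source)
      if (length(hit) != 1L) {
        abort(sprintf("label row '%s' not found in '%s'.", label_source, path))
      }
      label_vec <- as.character(unlist(body[hit, ], use.names = FALSE))
      body <- body[-hit, , drop = FALSE]
      row_ids <- row_ids[-hit]
    } else {
      hit <- which(col_ids == label_source)
      if (length(hit) != 1L) {
        abort(sprintf("label column '%s' not found in '%s'.", label_source, path))
      }
      label_vec <- as.character(body[[hit]])
      body <- body[, -hit, drop = FALSE]
      col_ids <- col_ids[-hit]
    }
  } else if (length(label_source) > 1L) {
    label_vec <- as.character(label_source)
  } else {
    abort("`label_source` must be a label file path, a label vector, or a row/column id.")
  }

  mat <- parse_numeric_body(body, row_ids, col_ids, path)
  if (orientation == "genes_as_rows") {
    values <- t(mat)
    sample_ids <- col_ids
    gene_ids <- row_ids
  } else {
    values <- mat
    sample_ids <- row_ids
    gene_ids <- col_ids
  }
  if (anyDuplicated(gene_ids)) {
    abort(sprintf("'%s': duplicate gene id '%s'.", path,
                  gene_ids[duplicated(gene_ids)][1L]))
  }

  if (length(label_vec) == 1L && is.na(label_vec[1L])) {
    label_vec <- read_label_file(label_source, sample_ids)
  }
  if (length(label_vec) != length(sample_ids)) {
    abort(sprintf("'%s': %d labels for %d samples.", path,
                  length(label_vec), length(sample_ids)))
  }
  expr_set(values, label_vec, sample_ids = sample_ids, gene_ids = gene_ids)
}

sniff_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

parse_numeric_body <- function(body, row_ids, col_ids, path) {
  mat <- matrix(NA_real_, nrow(body), ncol(body))
  for (j in seq_len(ncol(body))) {
    cell <- trimws(body[[j]])
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) | cell == "")
    if (length(bad)) {
      abort(sprintf("'%s': non-numeric or empty cell at row '%s', column '%s' (value '%s').",
                    path, row_ids[bad[1L]], col_ids[j], cell[bad[1L]]))
    }
    mat[, j] <- num
  }
  dimnames(mat) <- list(row_ids, col_ids)
  mat
}

read_label_file <- function(path, sample_ids) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "[\t,]")
  ncols <- lengths(parts)
  if (all(ncols == 1L)) {
    labs <- trimws(vapply(parts, `[[`, "", 1L))
    if (length(labs) == length(sample_ids) + 1L &&
        !labs[1L] %in% labs[-1L] && tolower(labs[1L]) %in% c("label", "labels", "class")) {
      labs <- labs[-1L] # tolerate a header line
    }
    return(labs)
  }
  ids <- trimws(vapply(parts, `[[`, "", 1L))
  labs <- trimws(vapply(parts, `[[`, "", 2L))
  if (identical(tolower(ids[1L]), "sample_id") || identical(tolower(labs[1L]), "label")) {
    ids <- ids[-1L]
    labs <- labs[-1L]
  }
  missing <- setdiff(sample_ids, ids)
  if (length(missing)) {
    abort(sprintf("label file '%s' has no label for sample(s): %s.",
                  path, paste(head(missing, 5L), collapse = ", ")))
  }
  labs[match(sample_ids, ids)]
}

#' Read an undirected interaction network from an edge list
#'
#' Supports plain two-column pair lists and the Cytoscape SIF dialect
#' (`node relation node [node ...]`, fanning one line out to several
#' edges). Repeated and reversed pairs collapse to a single undirected
#' edge; self-loops are dropped with a warning.
#'
#' @param path Path to the edge file.
#' @param dialect `"tsv_pairs"` (default) or `"sif"`.
#' @return An undirected simple [igraph::igraph] graph.
#' @export
read_edge_list <- function(path, dialect = c("tsv_pairs", "sif")) {
  dialect <- arg_match(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  from <- character(0)
  to <- character(0)
  singletons <- character(0)
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "[ \t]+")[[1L]]
    if (dialect == "tsv_pairs") {
      if (length(tok) < 2L) {
        abort(sprintf("'%s': line '%s' needs two node columns.", path, ln))
      }
      tok <- c(tok[1L], "-", tok[2L])
    }
    if (length(tok) == 1L) {
      singletons <- c(singletons, tok)
      next
    }
    if (length(tok) == 2L) {
      abort(sprintf("'%s': SIF line '%s' has a relation but no target node.", path, ln))
    }
    src <- tok[1L]
    dst <- tok[-(1:2)]
    if (!nzchar(src) || any(!nzchar(dst))) {
      abort(sprintf("'%s': blank node name in line '%s'.", path, ln))
    }
    from <- c(from, rep(src, length(dst)))
    to <- c(to, dst)
  }
  self <- from == to
  if (any(self)) {
    warn(sprintf("dropped %d self-loop(s) (e.g. '%s').", sum(self), from[self][1L]))
    from <- from[!self]
    to <- to[!self]
  }
  nodes <- unique(c(from, to, singletons))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from, to))
  }
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Read and write gene rankings
#'
#' A gene ranking is a two-column table, best gene first, with
#' non-increasing weights. On disk it is a TSV with header
#' `gene<TAB>weight`; comment lines starting with `#` are ignored so CLI
#' provenance headers round-trip.
#'
#' @param ranking A data frame / tibble with columns `gene` and `weight`,
#'   ordered best first.
#' @param path File path.
#' @return `write_ranking()` returns `path` invisibly; `read_ranking()`
#'   returns a tibble with columns `gene` (character) and `weight`
#'   (double).
#' @export
write_ranking <- function(ranking, path) {
  ranking <- validate_ranking(ranking)
  readr::write_tsv(ranking[, c("gene", "weight")], path)
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(gene = readr::col_character(),
                                                 weight = readr::col_double()))
  validate_ranking(out)
}

validate_ranking <- function(ranking) {
  if (!is.data.frame(ranking) || !all(c("gene", "weight") %in% names(ranking))) {
    abort("a ranking needs columns `gene` and `weight`.")
  }
  ranking <- tibble::as_tibble(ranking)
  ranking$gene <- as.character(ranking$gene)
  ranking$weight <- as.numeric(ranking$weight)
  if (anyDuplicated(ranking$gene)) abort("ranking gene ids must be unique.")
  if (nrow(ranking) > 1L && any(diff(ranking$weight) > 1e-12)) {
    abort("ranking weights must be non-increasing (best gene first).")
  }
  ranking
}
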