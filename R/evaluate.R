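#' Deterministic k-nearest-neighbour prediction
#'
#' Euclidean kNN with fully deterministic tie handling: equal distances
#' are broken by the lower training-sample index, and vote ties among
#' classes are broken in favour of the tied class seen earliest in the
#' neighbour order (i.e. the class of the nearest neighbour belonging to a
#' tied class).
#'
#' @param train An [expr_set] used as the reference set.
#' @param test An [expr_set] or numeric matrix / data frame of query
#'   samples over the same genes (columns are matched by name when
#'   present).
#' @param k Number of neighbours (default 5; at most the training size).
#' @param genes Optional gene subset used for the distance.
#' @return Character vector of predicted labels, one per query sample.
#' @export
knn_predict <- function(train, test, k = 5L, genes = NULL) {
  stopifnot(inherits(train, "expr_set"))
  if (!is.null(genes)) train <- select_genes(train, genes)
  k <- stopifnot_scalar_int(k, "k", min = 1L)
  if (k > nrow(train$values)) {
    abort(sprintf("`k` = %d exceeds the %d training samples.", k, nrow(train$values)))
  }
  test_x <- if (inherits(test, "expr_set")) test$values else as.matrix(test)
  gene_ids <- colnames(train$values)
  if (!is.null(colnames(test_x))) {
    missing <- setdiff(gene_ids, colnames(test_x))
    if (length(missing)) {
      abort(sprintf("test samples lack gene(s): %s.", paste(head(missing, 5L), collapse = ", ")))
    }
    test_x <- test_x[, gene_ids, drop = FALSE]
  } else if (ncol(test_x) != length(gene_ids)) {
    abort("unnamed test matrix must have the same number of genes as the training set.")
  }
  train_x <- train$values
  labels <- as.character(train$labels)
  vapply(seq_len(nrow(test_x)), function(i) {
    d2 <- rowSums((train_x - matrix(test_x[i, ], nrow(train_x), ncol(train_x),
                                    byrow = TRUE))^2)
    ord <- order(d2, seq_along(d2)) # distance ties -> lower training index
    nb <- labels[ord[seq_len(k)]]
    votes <- table(nb)
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) top else nb[nb %in% top][1L]
  }, character(1))
}

#' Classification metrics from true and predicted labels
#'
#' Builds the confusion matrix and computes accuracy and Cohen's kappa
#' for any number of classes; for binary problems additionally
#' sensitivity, specificity, F-score and the Matthews correlation
#' coefficient with respect to a positive class. Any metric whose
#' denominator is zero is reported as 0 (with a warning unless `quiet`).
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param positive Positive class for the binary metrics; defaults to the
#'   lexicographically larger of the two labels.
#' @param quiet Suppress zero-denominator warnings.
#' @return A list of class `metric_set`: `acc`, `kappa`, `confusion`
#'   (true classes in rows), and for binary data `sn`, `sp`, `f_score`,
#'   `mcc` and `positive`. `tidy()` turns it into a one-row tibble.
#' @export
compute_metrics <- function(y_true, y_pred, positive = NULL, quiet = FALSE) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred) || length(y_true) < 1L) {
    abort("`y_true` and `y_pred` must have equal, positive length.")
  }
  classes <- sort(unique(c(y_true, y_pred)))
  conf <- table(factor(y_true, classes), factor(y_pred, classes))
  total <- sum(conf)
  acc <- sum(diag(conf)) / total

  safe_div <- function(num, den, what) {
    if (den == 0) {
      if (!quiet) warn(sprintf("%s undefined (zero denominator); reported as 0.", what))
      return(0)
    }
    num / den
  }
  p_e <- sum(rowSums(conf) * colSums(conf)) / total^2
  kappa <- safe_div(acc - p_e, 1 - p_e, "kappa")

  out <- list(acc = acc, kappa = kappa, confusion = unclass(conf))
  truth_classes <- sort(unique(y_true))
  if (length(classes) == 2L) {
    positive <- positive %||% max(classes)
    if (!positive %in% classes) {
      abort(sprintf("positive label '%s' not among the observed classes.", positive))
    }
    negative <- setdiff(classes, positive)
    tp <- conf[positive, positive]
    tn <- conf[negative, negative]
    fp <- conf[negative, positive]
    fn <- conf[positive, negative]
    sn <- safe_div(tp, tp + fn, "sensitivity")
    sp <- safe_div(tn, tn + fp, "specificity")
    prec <- safe_div(tp, tp + fp, "precision")
    f <- safe_div(2 * prec * sn, prec + sn, "F-score")
    mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    mcc <- safe_div(tp * tn - fp * fn, mcc_den, "MCC")
    out <- c(out, list(sn = sn, sp = sp, f_score = f, mcc = mcc,
                       positive = positive))
  }
  structure(out, class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat("<metric_set>\n")
  print(tidy(x))
  invisible(x)
}

#' @describeIn compute_metrics Metrics as a one-row tibble (binary-only
#'   columns absent for multiclass input).
#' @param x A `metric_set`.
#' @param ... Unused.
#' @export
tidy.metric_set <- function(x, ...) {
  base <- tibble(acc = x$acc, kappa = x$kappa)
  if (!is.null(x$mcc)) {
    base <- dplyr::bind_cols(
      tibble(acc = x$acc, sn = x$sn, sp = x$sp, f_score = x$f_score,
             mcc = x$mcc, kappa = x$kappa))
  }
  base
}

# resolve a classifier descriptor into a fit/predict pair
resolve_classifier <- function(classifier, k = 5L) {
  if (is.list(classifier) && all(c("fit", "predict") %in% names(classifier))) {
    return(c(classifier, list(label = classifier$label %||% "custom")))
  }
  if (identical(classifier, "knn")) {
    return(list(
      fit = function(train) train,
      predict = function(model, test) knn_predict(model, test, k = min(k, nrow(model$values))),
      label = sprintf("knn (k = %d)", k)
    ))
  }
  if (identical(classifier, "svm_rbf")) {
    if (!requireNamespace("e1071", quietly = TRUE)) {
      abort("the 'svm_rbf' classifier needs the e1071 package.")
    }
    return(list(
      fit = function(train) e1071::svm(train$values, train$labels, kernel = "radial"),
      predict = function(model, test) {
        test_x <- if (inherits(test, "expr_set")) test$values else as.matrix(test)
        as.character(stats::predict(model, test_x))
      },
      label = "svm (RBF kernel)"
    ))
  }
  abort("`classifier` must be \"knn\", \"svm_rbf\", or a list(fit=, predict=).")
}

# stratified fold assignment: within each class, shuffled indices are dealt
# to folds round-robin; returns an integer fold id per sample
stratified_folds <- function(labels, folds) {
  assign <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Repeated stratified k-fold cross-validation of a gene subset
#'
#' Evaluates a fixed gene subset with a classifier under stratified
#' k-fold cross-validation repeated several times, reshuffling the folds
#' each repeat from a seeded generator. The gene subset and any ranking
#' that produced it are taken as given (never re-fit inside folds), which
#' matches evaluating a pre-computed ranking.
#'
#' @inheritParams mcbfs
#' @param genes Optional character vector restricting the dataset to a
#'   gene subset.
#' @param classifier `"knn"` (default), `"svm_rbf"`, or a
#'   `list(fit = function(train_expr_set), predict = function(model, test))`
#'   pair.
#' @param k Neighbour count for the kNN classifier (default 5).
#' @param folds Folds per repeat (default 10; reduced with a warning when
#'   the smallest class has fewer samples).
#' @param repeats Number of repeats (default 10).
#' @param seed Integer seed driving the fold shuffles (required for a
#'   reproducible report).
#' @param positive Positive class for the binary metrics.
#' @return An object of class `cv_report`: `per_fold` (tibble with one
#'   row per fold x repeat), `summary` (mean and SD per metric),
#'   `gene_subset`, `classifier`, `folds`, `repeats`, `seed`. `tidy()`
#'   returns the per-fold table, `glance()` the one-row summary,
#'   `autoplot()` boxplots of the per-fold metrics.
#' @export
repeated_cv <- function(data, labels = NULL, genes = NULL,
                        classifier = "knn", k = 5L, folds = 10L,
                        repeats = 10L, seed = 1L, positive = NULL) {
  data <- as_expr_set(data, labels)
  if (!is.null(genes)) data <- select_genes(data, genes)
  folds <- stopifnot_scalar_int(folds, "folds", min = 2L)
  repeats <- stopifnot_scalar_int(repeats, "repeats", min = 1L)
  if (nlevels(data$labels) < 2L) abort("cross-validation needs at least 2 classes.")
  min_class <- min(tabulate(data$labels))
  if (min_class < folds) {
    warn(sprintf("smallest class has %d samples; reducing folds from %d to %d.",
                 min_class, folds, min_class))
    folds <- max(2L, min_class)
  }
  clf <- resolve_classifier(classifier, k = k)

  rows <- with_seed(seed, {
    purrr::map(seq_len(repeats), function(rep_i) {
      fold_id <- stratified_folds(data$labels, folds)
      purrr::map(seq_len(folds), function(f) {
        tr <- expr_set(data$values[fold_id != f, , drop = FALSE],
                       data$labels[fold_id != f])
        te_x <- data$values[fold_id == f, , drop = FALSE]
        te_y <- as.character(data$labels[fold_id == f])
        model <- clf$fit(tr)
        pred <- clf$predict(model, te_x)
        ms <- compute_metrics(te_y, pred, positive = positive, quiet = TRUE)
        dplyr::bind_cols(tibble(repeat_ = rep_i, fold = f), tidy(ms))
      })
    })
  })
  per_fold <- dplyr::bind_rows(purrr::flatten(rows))
  metric_cols <- setdiff(names(per_fold), c("repeat_", "fold"))
  summary <- dplyr::summarise(
    tidyr::pivot_longer(per_fold, dplyr::all_of(metric_cols),
                        names_to = "metric"),
    mean = mean(.data$value), sd = stats::sd(.data$value),
    .by = "metric")
  structure(list(per_fold = per_fold, summary = summary,
                 gene_subset = genes %||% colnames(data$values),
                 classifier = clf$label, folds = folds, repeats = repeats,
                 seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s, %d-fold CV x %d repeat(s), %d gene(s), seed %s\n",
              x$classifier, x$folds, x$repeats, length(x$gene_subset),
              format(x$seed)))
  print(x$summary)
  invisible(x)
}

#' @describeIn repeated_cv Per-fold metrics, one row per fold x repeat.
#' @param x A `cv_report`.
#' @param ... Unused.
#' @export
tidy.cv_report <- function(x, ...) x$per_fold

#' @describeIn repeated_cv One-row summary: `mean_<metric>` and
#'   `sd_<metric>` columns plus the evaluation parameters.
#' @export
glance.cv_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "sd"))
  dplyr::bind_cols(wide, tibble(folds = x$folds, repeats = x$repeats,
                                n_genes = length(x$gene_subset),
                                classifier = x$classifier))
}

#' @describeIn repeated_cv Boxplots of the per-fold metric distributions.
#' @param object A `cv_report`.
#' @export
autoplot.cv_report <- function(object, ...) {
  metric_cols <- setdiff(names(object$per_fold), c("repeat_", "fold"))
  df <- tidyr::pivot_longer(object$per_fold, dplyr::all_of(metric_cols),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%d-fold CV x %d repeats (%s)",
                                  object$folds, object$repeats,
                                  object$classifier))
}

#' Best nested prefix of a ranking
#'
#' Evaluates the nested prefixes top-1, top-2, ..., top-`max_k` of a gene
#' ranking by [repeated_cv] and returns the prefix with the highest mean
#' accuracy (ties resolved toward the smaller prefix). Starting subsets
#' from the first-ranked gene keeps the number of candidate subsets
#' linear in `max_k`.
#'
#' @inheritParams repeated_cv
#' @param ranking A ranking tibble (`gene`, `weight`), best first.
#' @param max_k Largest prefix evaluated (default 100, capped at the
#'   ranking length).
#' @return A list of class `prefix_search`: `best_k`, `best_report` (the
#'   [repeated_cv] report of the winning prefix), and `table`
#'   (tibble: `k`, `mean_acc`, `sd_acc`).
#' @export
best_prefix <- function(data, ranking, labels = NULL, max_k = 100L,
                        classifier = "knn", k = 5L, folds = 10L,
                        repeats = 10L, seed = 1L, positive = NULL) {
  data <- as_expr_set(data, labels)
  ranking <- validate_ranking(ranking)
  max_k <- stopifnot_scalar_int(max_k, "max_k", min = 1L)
  if (max_k > nrow(ranking)) {
    abort(sprintf("`max_k` = %d exceeds the ranking length %d.", max_k, nrow(ranking)))
  }
  reports <- purrr::map(seq_len(max_k), function(kk) {
    repeated_cv(data, genes = ranking$gene[seq_len(kk)],
                classifier = classifier, k = k, folds = folds,
                repeats = repeats, seed = seed, positive = positive)
  })
  mean_acc <- purrr::map_dbl(reports, function(r) {
    r$summary$mean[r$summary$metric == "acc"]
  })
  sd_acc <- purrr::map_dbl(reports, function(r) {
    r$summary$sd[r$summary$metric == "acc"]
  })
  best_k <- which.max(mean_acc) # which.max takes the first (smallest k) on ties
  structure(list(best_k = best_k, best_report = reports[[best_k]],
                 table = tibble(k = seq_len(max_k), mean_acc = mean_acc,
                                sd_acc = sd_acc)),
            class = "prefix_search")
}

#' @export
print.prefix_search <- function(x, ...) {
  cat(sprintf("<prefix_search> best prefix k = %d (mean accuracy %.4f)\n",
              x$best_k, x$table$mean_acc[x$best_k]))
  invisible(x)
}

#' Exhaustive best-subset search over candidate genes
#'
#' Trains on `train` and scores on the independent `test` set for every
#' non-empty subset of the candidate genes (`2^g - 1` evaluations), and
#' returns the subset maximizing the selection criterion. Ties are broken
#' toward the smaller subset, then the lexicographically first gene
#' combination.
#'
#' @param train,test [expr_set]s sharing the candidate genes.
#' @param candidates Character vector of at most 15 candidate gene ids
#'   (beyond that the search space explodes; use [best_prefix] instead).
#' @param classifier,k,positive As in [repeated_cv].
#' @param criterion `"acc"` (default) or `"mcc"` (binary data only).
#' @return A list of class `subset_search`: `evaluated` (count,
#'   `2^g - 1`), `best_subset`, `best_metrics` (a `metric_set`), and
#'   `table` (one row per subset: `genes` list-column, `size`, metric
#'   columns).
#' @export
exhaustive_search <- function(train, test, candidates, classifier = "knn",
                              k = 5L, positive = NULL,
                              criterion = c("acc", "mcc")) {
  criterion <- arg_match(criterion)
  stopifnot(inherits(train, "expr_set"), inherits(test, "expr_set"))
  candidates <- as.character(candidates)
  if (length(candidates) < 1L) abort("`candidates` must name at least one gene.")
  if (length(candidates) > 15L) {
    abort(sprintf("%d candidates give %.3g subsets; use best_prefix() for large candidate sets.",
                  length(candidates), 2^length(candidates) - 1))
  }
  clf <- resolve_classifier(classifier, k = k)
  g <- length(candidates)
  subsets <- purrr::flatten(purrr::map(seq_len(g), function(sz) {
    utils::combn(candidates, sz, simplify = FALSE)
  }))
  eval_one <- function(genes) {
    tr <- select_genes(train, genes)
    te <- select_genes(test, genes)
    model <- clf$fit(tr)
    pred <- clf$predict(model, te$values)
    compute_metrics(as.character(test$labels), pred, positive = positive,
                    quiet = TRUE)
  }
  metrics <- purrr::map(subsets, eval_one)
  tab <- dplyr::bind_cols(
    tibble(genes = subsets, size = lengths(subsets)),
    dplyr::bind_rows(purrr::map(metrics, tidy))
  )
  score <- tab[[criterion]]
  lex_key <- vapply(subsets, function(gs) paste(sort(gs), collapse = "\r"), character(1))
  best <- order(-score, tab$size, lex_key)[1L]
  structure(list(evaluated = length(subsets),
                 best_subset = subsets[[best]],
                 best_metrics = metrics[[best]],
                 criterion = criterion,
                 table = tab),
            class = "subset_search")
}

#' @export
print.subset_search <- function(x, ...) {
  cat(sprintf("<subset_search> %d subsets evaluated; best (%s = %.4f): %s\n",
              x$evaluated, x$criterion,
              tidy(x$best_metrics)[[x$criterion]],
              paste(x$best_subset, collapse = ", ")))
  invisible(x)
}

#' Per-gene two-sample t-tests
#'
#' Tests each gene for a mean difference between the two classes
#' (Welch's unequal-variance t by default; set `var_equal = TRUE` for the
#' pooled form) and flags significance at `p <= alpha` with no
#' multiplicity correction by default (Benjamini-Hochberg available
#' behind `adjust = "BH"`).
#'
#' @inheritParams repeated_cv
#' @param var_equal Use the pooled-variance t-test (default `FALSE`,
#'   i.e. Welch).
#' @param alpha Significance threshold (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A tibble with columns `gene`, `statistic`, `p_value`,
#'   `significant`, ordered as the input genes. Genes constant in both
#'   classes have an undefined statistic and are excluded with a warning.
#' @export
ttest_genes <- function(data, labels = NULL, genes = NULL,
                        var_equal = FALSE, alpha = 0.05,
                        adjust = c("none", "BH")) {
  adjust <- arg_match(adjust)
  data <- as_expr_set(data, labels)
  if (!is.null(genes)) data <- select_genes(data, genes)
  if (nlevels(data$labels) != 2L) {
    abort("two-sample t-tests need exactly 2 classes.")
  }
  if (min(tabulate(data$labels)) < 2L) {
    abort("both classes need at least 2 samples.")
  }
  grp <- data$labels == levels(data$labels)[1L]
  res <- purrr::map(colnames(data$values), function(g) {
    x <- data$values[grp, g]
    y <- data$values[!grp, g]
    ht <- tryCatch(t.test(x, y, var.equal = var_equal),
                   error = function(e) NULL)
    if (is.null(ht)) {
      return(tibble(gene = g, statistic = NA_real_, p_value = NA_real_))
    }
    tibble(gene = g, statistic = unname(ht$statistic), p_value = ht$p.value)
  })
  out <- dplyr::bind_rows(res)
  undefined <- out$gene[is.na(out$statistic)]
  if (length(undefined)) {
    warn(sprintf("excluded %d gene(s) with zero variance in both classes: %s.",
                 length(undefined), paste(head(undefined, 5L), collapse = ", ")))
    out <- out[!is.na(out$statistic), , drop = FALSE]
  }
  if (adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value <= alpha
  out
}

#' Filter hub genes by survival p-values
#'
#' Keeps the hub genes whose externally supplied survival (log-rank)
#' p-value falls below 0.05 and orders them by ascending p-value — the
#' screen that turns hub genes into key informative genes. Survival
#' analysis itself is out of scope; the p-values come from an external
#' tool.
#'
#' @param hubs Character vector of hub gene ids.
#' @param pvalues Named numeric vector of per-gene p-values, or a data
#'   frame with columns `gene` and `p_value` (or `p`).
#' @param threshold Exclusive significance cutoff (default 0.05).
#' @return A tibble with columns `gene` and `p_value`, ascending by
#'   `p_value` (ties keep the input hub order).
#' @export
filter_key_genes <- function(hubs, pvalues, threshold = 0.05) {
  hubs <- as.character(hubs)
  if (is.data.frame(pvalues)) {
    pcol <- intersect(c("p_value", "p", "pvalue"), names(pvalues))[1L]
    if (is.na(pcol) || !"gene" %in% names(pvalues)) {
      abort("`pvalues` data frame needs columns `gene` and `p_value` (or `p`).")
    }
    pvalues <- setNames(as.numeric(pvalues[[pcol]]), as.character(pvalues$gene))
  }
  missing <- hubs[!hubs %in% names(pvalues)]
  if (length(missing)) {
    abort(sprintf("no p-value supplied for hub gene(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  p <- unname(pvalues[hubs])
  keep <- p < threshold
  out <- tibble(gene = hubs[keep], p_value = p[keep])
  out[order(out$p_value), , drop = FALSE]
}
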