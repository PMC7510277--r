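test_that("kNN follows its deterministic distance and vote tie rules", {
  train <- expr_set(rbind(c(0, 0), c(1, 0), c(0, 1), c(2, 2), c(3, 2), c(2, 3)),
                    labels = c("a", "a", "a", "b", "b", "b"),
                    gene_ids = c("g1", "g2"))
  # a test point equal to a training point at k = 1 takes that label
  expect_equal(knn_predict(train, rbind(c(2, 2)), k = 1), "b")
  # k = n: the global majority (here tied 3-3 -> class of nearest neighbour)
  expect_equal(knn_predict(train, rbind(c(0.1, 0)), k = 6), "a")
  # hand-sorted toy: matches the independent oracle on random queries
  set.seed(77)
  queries <- matrix(runif(20, -1, 4), 10, 2)
  expect_equal(knn_predict(train, queries, k = 3),
               unname(oracle_knn(train$values, as.character(train$labels),
                                 queries, k = 3)))
  # exact distance tie -> lower training index wins
  tie_train <- expr_set(rbind(c(-1, 0), c(1, 0), c(5, 5), c(6, 6)),
                        labels = c("a", "b", "c", "c"))
  expect_equal(knn_predict(tie_train, rbind(c(0, 0)), k = 1), "a")
  expect_error(knn_predict(train, rbind(c(0, 0)), k = 7), "exceeds")
})

test_that("metric formulas reproduce the hand-computed confusion example", {
  y_true <- c(rep("pos", 5), rep("neg", 5))
  y_pred <- c("pos", "pos", "pos", "neg", "neg", # TP = 3, FN = 2
              "neg", "neg", "neg", "neg", "pos") # TN = 4, FP = 1
  ms <- compute_metrics(y_true, y_pred, positive = "pos")
  expect_equal(ms$acc, 0.7)
  expect_equal(ms$sn, 0.6)
  expect_equal(ms$sp, 0.8)
  expect_equal(ms$f_score, 2 / 3, tolerance = 1e-5)
  expect_equal(ms$mcc, 10 / sqrt(600), tolerance = 1e-5)
  expect_equal(sum(ms$confusion), 10)

  perfect <- compute_metrics(y_true, y_true, positive = "pos")
  expect_equal(tidy(perfect),
               tibble::tibble(acc = 1, sn = 1, sp = 1, f_score = 1,
                              mcc = 1, kappa = 1))

  # balanced truth, constant prediction: kappa 0, several zero denominators
  w <- testthat::capture_warnings(
    const <- compute_metrics(c("a", "a", "b", "b"), rep("a", 4),
                             positive = "b"))
  expect_true(any(grepl("zero denominator", w)))
  expect_equal(const$kappa, 0)
  expect_equal(const$acc, 0.5)
  expect_error(compute_metrics(y_true, y_pred, positive = "zzz"), "positive label")
})

test_that("metric bounds and label-swap symmetry hold on random confusions", {
  set.seed(55)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    y_true <- sample(c("x", "y"), n, replace = TRUE)
    if (length(unique(y_true)) < 2) y_true[1:2] <- c("x", "y")
    y_pred <- sample(c("x", "y"), n, replace = TRUE)
    a <- compute_metrics(y_true, y_pred, positive = "y", quiet = TRUE)
    expect_true(all(c(a$acc, a$sn, a$sp, a$f_score) >= 0 &
                    c(a$acc, a$sn, a$sp, a$f_score) <= 1))
    expect_true(a$mcc >= -1 && a$mcc <= 1 && a$kappa >= -1 && a$kappa <= 1)
    b <- compute_metrics(y_true, y_pred, positive = "x", quiet = TRUE)
    expect_equal(a$acc, b$acc)
    expect_equal(a$sn, b$sp)
    expect_equal(a$sp, b$sn)
    expect_equal(abs(a$mcc), abs(b$mcc))
  }
  # multiclass: binary-only fields are absent
  m <- compute_metrics(c("a", "b", "c"), c("a", "b", "b"), quiet = TRUE)
  expect_null(m$sn)
  expect_named(tidy(m), c("acc", "kappa"))
})

test_that("repeated CV partitions samples, stratifies, and is seed-deterministic", {
  sim <- simulate_expression(n_samples = 40, n_genes = 30, n_informative = 5,
                             seed = 21)
  rep1 <- repeated_cv(sim$data, genes = sim$informative, folds = 5, repeats = 3,
                      seed = 42)
  rep2 <- repeated_cv(sim$data, genes = sim$informative, folds = 5, repeats = 3,
                      seed = 42)
  expect_identical(rep1$per_fold, rep2$per_fold)
  expect_equal(nrow(rep1$per_fold), 15L)
  gl <- glance(rep1)
  expect_true(gl$mean_acc >= min(rep1$per_fold$acc) &&
              gl$mean_acc <= max(rep1$per_fold$acc))
  expect_s3_class(autoplot(rep1), "ggplot")

  # fold membership is a partition every repeat (checked via the internals)
  set.seed(1)
  labels <- factor(rep(c("a", "b"), c(12, 8)))
  fid <- mcbfs:::stratified_folds(labels, 4)
  expect_equal(sort(unique(fid)), 1:4)
  expect_equal(as.vector(table(fid)), rep(5L, 4)) # stratified: 3a + 2b per fold
  expect_equal(as.vector(table(fid, labels)[, "a"]), rep(3L, 4))

  # folds shrink with a warning when the smallest class is tiny
  small <- simulate_expression(n_samples = 12, n_genes = 10, n_informative = 2,
                               class_proportions = c(0.75, 0.25), seed = 3)
  expect_warning(repeated_cv(small$data, folds = 10, repeats = 1, seed = 1),
                 "reducing folds")
})

test_that("a majority-vote classifier scores the base rate under CV", {
  sim <- simulate_expression(n_samples = 60, n_genes = 5, n_informative = 0,
                             class_proportions = c(0.7, 0.3), seed = 13)
  majority <- list(
    fit = function(train) names(which.max(table(train$labels))),
    predict = function(model, test) rep(model, nrow(test)),
    label = "majority"
  )
  rep <- repeated_cv(sim$data, classifier = majority, folds = 10, repeats = 2,
                     seed = 5)
  expect_equal(glance(rep)$mean_acc, 0.7, tolerance = 0.02)
})

test_that("trained predictions never depend on test-fold labels", {
  sim <- simulate_expression(n_samples = 20, n_genes = 10, n_informative = 3,
                             seed = 17)
  train <- expr_set(sim$data$values[1:14, ], sim$data$labels[1:14])
  test_x <- sim$data$values[15:20, ]
  p1 <- knn_predict(train, test_x, k = 3)
  p2 <- knn_predict(train, test_x[sample(6), ][order(sample(6)), ], k = 3)
  expect_equal(p1, knn_predict(train, test_x, k = 3))
  expect_length(p1, 6L)
})

test_that("best_prefix prefers the smallest prefix among ties", {
  sim <- simulate_expression(n_samples = 40, n_genes = 20, n_informative = 1,
                             effect_size = 8, seed = 23)
  fit <- mcbfs(sim$data, m = 5)
  res <- best_prefix(sim$data, fit$ranking, max_k = 5, folds = 5, repeats = 2,
                     seed = 11)
  expect_equal(nrow(res$table), 5L)
  # one hugely informative gene: accuracy 1 from k = 1 on, ties resolve to 1
  expect_equal(res$best_k, 1L)
  expect_equal(res$table$mean_acc[1], 1)
  r1 <- best_prefix(sim$data, fit$ranking, max_k = 1, folds = 5, repeats = 1,
                    seed = 2)
  expect_equal(r1$best_k, 1L)
  expect_error(best_prefix(sim$data, fit$ranking, max_k = 21), "exceeds")
})

test_that("exhaustive search enumerates every subset and matches a re-evaluation loop", {
  sim_tr <- simulate_expression(n_samples = 30, n_genes = 8, n_informative = 2,
                                informative_genes = c(1, 2), seed = 31)
  sim_te <- simulate_expression(n_samples = 20, n_genes = 8, n_informative = 2,
                                informative_genes = c(1, 2), seed = 32)
  res <- exhaustive_search(sim_tr$data, sim_te$data,
                           candidates = paste0("g000", 1:6), k = 3)
  expect_equal(res$evaluated, 63L) # 2^6 - 1
  expect_true(all(res$best_subset %in% paste0("g000", 1:6)))

  # independent loop over bitmasks with the oracle kNN
  accs <- numeric(0)
  keys <- character(0)
  cand <- paste0("g000", 1:6)
  for (mask in 1:63) {
    genes <- cand[bitwAnd(mask, 2^(0:5)) > 0]
    pred <- oracle_knn(sim_tr$data$values[, genes, drop = FALSE],
                       as.character(sim_tr$data$labels),
                       sim_te$data$values[, genes, drop = FALSE], k = 3)
    accs <- c(accs, mean(pred == as.character(sim_te$data$labels)))
    keys <- c(keys, paste(sort(genes), collapse = "|"))
  }
  got <- setNames(res$table$acc,
                  vapply(res$table$genes, function(g) paste(sort(g), collapse = "|"),
                         character(1)))
  expect_equal(unname(got[keys]), accs)
  expect_equal(max(accs), tidy(res$best_metrics)$acc)

  # single candidate and the size guard
  r1 <- exhaustive_search(sim_tr$data, sim_te$data, candidates = "g0001")
  expect_equal(r1$evaluated, 1L)
  expect_equal(r1$best_subset, "g0001")
  expect_error(exhaustive_search(sim_tr$data, sim_te$data,
                                 candidates = sprintf("g%04d", 1:16)),
               "best_prefix")
})

test_that("jointly informative gene pairs are found by the exhaustive search", {
  hits <- 0L
  for (s in 1:10) {
    tr <- simulate_expression(n_samples = 40, n_genes = 10, n_informative = 2,
                              informative_genes = c(3, 7), effect_size = 1.6,
                              seed = 100 + s)
    te <- simulate_expression(n_samples = 30, n_genes = 10, n_informative = 2,
                              informative_genes = c(3, 7), effect_size = 1.6,
                              seed = 200 + s)
    res <- exhaustive_search(tr$data, te$data, candidates = sprintf("g%04d", 1:10))
    if (all(c("g0003", "g0007") %in% res$best_subset)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("per-gene t-tests match the textbook statistic and flag significance", {
  # identical groups with internal variance: t = 0, p = 1
  es <- expr_set(matrix(c(1, 2, 3, 1, 2, 3), 6, 1), rep(c("a", "b"), each = 3),
                 gene_ids = "g1")
  tt <- ttest_genes(es)
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)
  expect_false(tt$significant)

  # clearly shifted toy groups are significant
  es2 <- expr_set(matrix(c(0, 0, 1, 1, 10, 10, 11, 11), 8, 1),
                  rep(c("a", "b"), each = 4), gene_ids = "g1")
  tt2 <- ttest_genes(es2)
  expect_gt(abs(tt2$statistic), 10)
  expect_true(tt2$significant)
  expect_equal(tt2$statistic,
               oracle_t_stat(c(0, 0, 1, 1), c(10, 10, 11, 11)), tolerance = 1e-10)

  # reference equivalence on random pairs, both variants
  set.seed(61)
  for (i in 1:100) {
    x <- rnorm(sample(3:10, 1))
    y <- rnorm(sample(3:10, 1), mean = runif(1, -1, 1))
    es_i <- expr_set(matrix(c(x, y), ncol = 1), rep(c("a", "b"), c(length(x), length(y))),
                     gene_ids = "g1")
    expect_equal(ttest_genes(es_i)$statistic, oracle_t_stat(x, y), tolerance = 1e-10)
    expect_equal(ttest_genes(es_i, var_equal = TRUE)$statistic,
                 oracle_t_stat(x, y, var_equal = TRUE), tolerance = 1e-10)
  }

  # zero-variance genes are excluded with a warning
  es3 <- expr_set(cbind(g1 = c(1, 2, 4, 6), g2 = c(5, 5, 5, 5)),
                  rep(c("a", "b"), each = 2))
  expect_warning(tt3 <- ttest_genes(es3), "zero variance")
  expect_equal(tt3$gene, "g1")
})

test_that("the key-gene filter keeps sub-threshold p-values in ascending order", {
  pv <- readr::read_tsv(system.file("extdata", "luad_hub_pvalues.tsv",
                                    package = "mcbfs"),
                        show_col_types = FALSE)
  key <- filter_key_genes(pv$gene, pv)
  expect_equal(nrow(key), 7L)
  expect_equal(key$gene, c("TEK", "ANGPT1", "CAV1", "SPP1", "CDH5",
                           "PECAM1", "CLDN5"))
  expect_true(all(diff(key$p_value) >= 0))

  expect_equal(nrow(filter_key_genes(c("a", "b"), c(a = 1, b = 1))), 0L)
  all_zero <- filter_key_genes(c("b", "a"), c(a = 0, b = 0))
  expect_equal(all_zero$gene, c("b", "a")) # equal keys keep input order
  expect_error(filter_key_genes(c("a", "zz"), c(a = 0.01)), "zz")
})

test_that("the svm classifier plugs into the same CV interface", {
  skip_if_not_installed("e1071")
  sim <- simulate_expression(n_samples = 30, n_genes = 10, n_informative = 3,
                             seed = 41)
  rep <- repeated_cv(sim$data, genes = sim$informative, classifier = "svm_rbf",
                     folds = 5, repeats = 1, seed = 9)
  expect_equal(nrow(rep$per_fold), 5L)
  expect_gt(glance(rep)$mean_acc, 0.7)
})
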