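emb_of <- function(values) matrix(rep(values, each = 20), 20)

test_that("database/query split halves classes then balances the database", {
  emb <- matrix(rnorm(20 * 10), 20)
  labs <- rep(c("A", "B"), c(6, 4))
  sq <- split_database_query(emb, labs, seed = 2)
  expect_equal(as.vector(table(sq$database$labels)), c(2L, 2L))
  expect_equal(as.vector(table(sq$query$labels)), c(4L, 2L))
  # even 4 + 4 case halves cleanly
  sq2 <- split_database_query(emb[, 1:8], rep(c("A", "B"), each = 4),
                              seed = 2)
  expect_equal(as.vector(table(sq2$database$labels)), c(2L, 2L))
  expect_equal(as.vector(table(sq2$query$labels)), c(2L, 2L))
  expect_error(split_database_query(emb, rep(c("A", "B", "C"), c(5, 4, 1)),
                                    seed = 1), ">= 2 members")
  expect_identical(split_database_query(emb, labs, seed = 2)$query$labels,
                   sq$query$labels)
})

test_that("class centers are per-class means in catalog order", {
  emb <- cbind(emb_of(0), emb_of(2), emb_of(10))
  cc <- class_centers(emb, c("A", "A", "B"))
  expect_equal(cc$centers[, "A"], rep(1, 20))
  expect_equal(cc$centers[, "B"], rep(10, 20))
  perm <- class_centers(emb[, c(3, 1, 2)], c("B", "A", "A"))
  expect_equal(perm$centers, cc$centers)
  expect_error(class_centers(emb, c("A", "A", "B"), classes = c("A", "C")),
               "absent")
})

test_that("nearest-center classification breaks ties by catalog order", {
  cc <- class_centers(cbind(emb_of(0), emb_of(10)), c("lo", "hi"),
                      classes = c("hi", "lo"))
  expect_identical(nearest_center_classify(rep(4, 20), cc)$label, "lo")
  expect_identical(nearest_center_classify(rep(0, 20), cc)$label, "lo")
  # exact midpoint: tie goes to the earlier catalog class
  expect_identical(nearest_center_classify(rep(5, 20), cc)$label, "hi")
  sc <- nearest_center_classify(rep(4, 20), cc)$scores
  expect_identical(names(which.max(sc)), "lo")
})

test_that("the metric panel reproduces the confusion-count formulas", {
  truth <- rep(c("pos", "neg"), c(5, 5))
  pred <- c(rep("pos", 3), rep("neg", 2), "pos", rep("neg", 4))
  rep <- compute_metrics(truth, pred, classes = c("neg", "pos"),
                         positive = "pos")
  expect_equal(rep$metrics[["accuracy"]], 0.7)
  expect_equal(rep$metrics[["precision"]], 0.75)
  expect_equal(rep$metrics[["recall"]], 0.6)
  expect_equal(rep$metrics[["f1"]], 2 / 3, tolerance = 1e-10)
  expect_equal(rep$metrics[["specificity"]], 0.8)
  expect_equal(sum(rep$confusion), 10)
})

test_that("perfect separable predictions score 1 everywhere", {
  truth <- rep(c("a", "b"), each = 5)
  scores <- cbind(a = c(rep(1, 5), rep(0, 5)),
                  b = c(rep(0, 5), rep(1, 5)))
  rep <- compute_metrics(truth, truth, scores, classes = c("a", "b"))
  expect_true(all(abs(rep$metrics - 1) < 1e-12))
})

test_that("metrics agree with the nested-loop counting oracle", {
  set.seed(99)
  for (trial in 1:200) {
    n <- sample(6:30, 1)
    truth <- sample(c("x", "y"), n, replace = TRUE)
    pred <- sample(c("x", "y"), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    got <- compute_metrics(truth, pred, classes = c("x", "y"),
                           positive = "y")$metrics
    want <- oracle_binary_metrics(truth, pred, positive = "y")
    for (nm in names(want))
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-12, label = nm)
  }
})

test_that("AUC is trapezoidal, monotone-invariant and matches pROC", {
  set.seed(7)
  truth <- sample(c("a", "b"), 40, replace = TRUE)
  s <- rnorm(40) + (truth == "b")
  scores <- cbind(a = -s, b = s)
  rep1 <- compute_metrics(truth, ifelse(s > 0.5, "b", "a"), scores,
                          classes = c("a", "b"))
  # strictly monotone transform of scores leaves AUC unchanged
  scores2 <- cbind(a = -exp(s), b = exp(s))
  rep2 <- compute_metrics(truth, ifelse(s > 0.5, "b", "a"), scores2,
                          classes = c("a", "b"))
  expect_equal(rep1$metrics[["auc"]], rep2$metrics[["auc"]],
               tolerance = 1e-12)
  ref <- as.numeric(pROC::auc(pROC::roc(truth == "b", s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(rep1$metrics[["auc"]], ref, tolerance = 1e-10)
})

test_that("multiclass metrics macro-average one-vs-rest", {
  truth <- c("a", "a", "b", "b", "c", "c")
  pred <- c("a", "b", "b", "b", "c", "a")
  rep <- compute_metrics(truth, pred, classes = c("a", "b", "c"))
  expect_equal(rep$metrics[["accuracy"]], 4 / 6, tolerance = 1e-12)
  per <- vapply(c("a", "b", "c"), function(cl)
    oracle_binary_metrics(truth, pred, cl)[["recall"]], numeric(1))
  expect_equal(rep$metrics[["recall"]], mean(per), tolerance = 1e-12)
})

test_that("the database/query protocol is exact on a trained separable fit", {
  fit <- small_fsl_fit()
  eval_qrs <- qrs_dataset_cached(2, 8, seed = 909)
  rep1 <- fsl_evaluate(fit, eval_qrs, seed = 4)
  expect_identical(sum(rep1$confusion), rep1$n)
  rep2 <- fsl_evaluate(fit, eval_qrs, seed = 4)
  expect_identical(rep1$metrics, rep2$metrics)   # fixed rng, fixed report
  expect_gte(rep1$metrics[["accuracy"]], 0.95)
})

test_that("downstream heads hit the easy cases and reject unknown names", {
  set.seed(3)
  tr <- cbind(matrix(rnorm(20 * 15, 0), 20), matrix(rnorm(20 * 15, 6), 20))
  labs <- rep(c("A", "B"), each = 15)
  te <- tr[, c(1:5, 16:20)]
  telabs <- labs[c(1:5, 16:20)]
  # knn-5 with exact duplicates in the training set
  expect_equal(downstream_classify(tr, labs, te, telabs,
                                   "knn-5")$metrics[["accuracy"]], 1)
  expect_equal(downstream_classify(tr, labs, te, telabs,
                                   "svm-linear")$metrics[["accuracy"]], 1)
  r1 <- downstream_classify(tr, labs, te, telabs, "random-forest", seed = 9)
  r2 <- downstream_classify(tr, labs, te, telabs, "random-forest", seed = 9)
  expect_identical(r1$metrics, r2$metrics)
  expect_error(downstream_classify(tr, labs, te, telabs, "perceptron"),
               "unknown model")
})

test_that("repeated-split aggregation keeps averages inside the range", {
  qrs <- qrs_dataset_cached(2, 10)
  cfg <- training_config(seed = 31, max_epochs = 3L, patience = 3L,
                         batch_size = 6L)
  cv <- crossvalidate(qrs, method = "head:knn-5", config = cfg, k = 3L)
  expect_identical(nrow(cv$per_fold), 3L)
  expect_length(unique(cv$seeds), 3L)
  for (m in rownames(cv$summary)) {
    if (any(is.na(cv$summary[m, ]))) next
    expect_gte(cv$summary[m, "avg"], cv$summary[m, "min"])
    expect_lte(cv$summary[m, "avg"], cv$summary[m, "max"])
  }
})

test_that("the ablation sweeps fractions and keeps the full set exact", {
  fit <- small_fsl_fit()
  tr <- c(fit$splits$train, fit$splits$validation)
  te <- qrs_dataset_cached(2, 8, seed = 909)
  ab <- subset_ablation(fit, tr, te, fractions = c(0.5, 1), seed = 6)
  expect_identical(nrow(ab), 2L)
  expect_identical(ab$n[2], length(te))
  full <- downstream_classify(
    predict(fit, tr, type = "embedding"),
    vapply(tr, `[[`, character(1), "superclass"),
    predict(fit, te, type = "embedding"),
    vapply(te, `[[`, character(1), "superclass"),
    model = "random-forest", seed = derive_seed(6, 2L))
  expect_equal(ab$accuracy[2], full$metrics[["accuracy"]])
})
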