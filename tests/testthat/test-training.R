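test_that("distance and loss functions reproduce their closed forms", {
  expect_identical(euclidean_distance(c(1, 2), c(1, 2)), 0)
  expect_identical(euclidean_distance(c(0, 0), c(3, 4)), 5)
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(5); y <- rnorm(5)
    expect_equal(euclidean_distance(x, y), euclidean_distance(y, x))
  }
  expect_error(euclidean_distance(1:3, 1:4), "mismatch")

  a <- c(0, 0)
  expect_identical(triplet_margin_loss(a, a, a, m = 1), 1)
  expect_identical(triplet_margin_loss(a, a, c(0, 2), m = 1), 0)
  expect_identical(triplet_margin_loss(a, c(3, 4), c(1, 0), m = 1), 5)
  expect_error(triplet_margin_loss(a, a, a, m = 0), "positive")
  # loss is zero exactly on the margin-satisfied region
  set.seed(9)
  for (i in 1:50) {
    a <- rnorm(4); p <- rnorm(4); n <- rnorm(4)
    l <- triplet_margin_loss(a, p, n, m = 1)
    expect_gte(l, 0)
    sat <- euclidean_distance(a, p) <= euclidean_distance(a, n) - 1
    expect_identical(l == 0, sat)
  }
})

test_that("cross-entropy matches its closed form and monotonicity", {
  expect_identical(cross_entropy(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(cross_entropy(rep(0.2, 5), c(0, 1, 0, 0, 0)), log(5))
  expect_error(cross_entropy(c(1, 0), c(0, 1)), "zero probability")
  p_at <- function(p1) cross_entropy(c(p1, rep((1 - p1) / 4, 4)),
                                     c(1, 0, 0, 0, 0))
  ps <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(vapply(ps, p_at, numeric(1))) < 0))
})

test_that("splits are seeded partitions with rounded sizes", {
  ds <- as.list(1:100)
  sp <- split_dataset(ds, seed = 3)
  expect_length(sp$train, 70L)
  expect_length(sp$validation, 15L)
  expect_length(sp$test, 15L)
  all_items <- c(unlist(sp$train), unlist(sp$validation), unlist(sp$test))
  expect_setequal(all_items, 1:100)
  expect_identical(split_dataset(ds, seed = 3), sp)
  # the published filtered-corpus size splits as 12,062 / 2,585 / 2,585
  big <- split_dataset(as.list(seq_len(17232)), seed = 1)
  expect_identical(lengths(big)[["train"]], 12062L)
  expect_identical(lengths(big)[["validation"]], 2585L)
  expect_identical(lengths(big)[["test"]], 2585L)
  expect_error(split_dataset(list(), seed = 1), "empty")
})

test_that("triplet batches are homogeneous in count and class-consistent", {
  qrs <- qrs_dataset_cached(2, 10)
  set.seed(5)
  batch <- sample_triplet_batch(qrs, batch_size = 12L)
  counts <- vapply(c(batch$anchors, batch$positives, batch$negatives),
                   n_beats, integer(1))
  expect_identical(unique(counts), batch$qrs_count)
  for (b in seq_len(12L)) {
    expect_identical(batch$anchors[[b]]$superclass,
                     batch$positives[[b]]$superclass)
    expect_false(identical(batch$anchors[[b]]$superclass,
                           batch$negatives[[b]]$superclass))
  }
  set.seed(5)
  batch2 <- sample_triplet_batch(qrs, batch_size = 12L)
  expect_identical(batch, batch2)             # seeded determinism
})

test_that("a degenerate count distribution pins the batch count", {
  rec <- generate_record(demo_class_specs(1, noise_sd = 0)[[1]], seed = 1)
  base <- extract_qrs(rec, rec$truth_rpeaks)
  ds <- list()
  for (i in 1:6) {
    q <- base
    q$superclass <- if (i <= 3) "A" else "B"
    q$record_id <- paste0("r", i)
    ds[[i]] <- q
  }
  set.seed(1)
  batch <- sample_triplet_batch(ds, batch_size = 4L)
  expect_identical(batch$qrs_count, n_beats(base))
  # single class cannot form triplets
  one <- ds[1:3]
  expect_error(sample_triplet_batch(one, 4L), "2 classes")
})

test_that("anchor classes follow the dataset class frequencies", {
  # a 3:1 imbalanced two-class pool sharing one QRS count
  pool <- list()
  base <- qrs_dataset_cached(2, 10)[[1]]
  for (i in 1:40) {
    q <- base
    q$superclass <- if (i <= 30) "maj" else "min"
    pool[[i]] <- q
  }
  set.seed(77)
  anchors <- character(0)
  for (i in 1:40) {
    b <- sample_triplet_batch(pool, batch_size = 25L)
    anchors <- c(anchors, vapply(b$anchors, `[[`, character(1),
                                 "superclass"))
  }
  tab <- table(factor(anchors, c("maj", "min")))
  chi <- stats::chisq.test(tab, p = c(0.75, 0.25))
  expect_gt(chi$p.value, 0.001)
})

test_that("a frozen optimizer stops after patience runs out", {
  qrs <- qrs_dataset_cached(2, 6)
  cfg <- training_config(seed = 2, lr = 0, patience = 1L, max_epochs = 10L,
                         batch_size = 4L)
  fit <- train_fsl(qrs, cfg)
  expect_lte(nrow(fit$history), 2L)
})

test_that("the checkpoint is the argmax of validation accuracy", {
  fit <- small_fsl_fit()
  h <- fit$history
  expect_identical(h$val_accuracy[fit$best_epoch], max(h$val_accuracy))
  expect_identical(fit$best_val_accuracy, max(h$val_accuracy))
})

test_that("training histories are reproducible under fixed seeds", {
  qrs <- qrs_dataset_cached(2, 6)
  cfg <- training_config(seed = 13, max_epochs = 3L, patience = 3L,
                         batch_size = 4L)
  f1 <- train_fsl(qrs, cfg)
  f2 <- train_fsl(qrs, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$weights$fc$W, f2$weights$fc$W)
})

test_that("softmax training descends on separable data and is seeded", {
  qrs <- qrs_dataset_cached(2, 6)
  cfg <- training_config(seed = 21, max_epochs = 6L, patience = 6L,
                         batch_size = 4L)
  fit <- train_softmax(qrs, config = cfg)
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  fit2 <- train_softmax(qrs, config = cfg)
  expect_identical(fit$history, fit2$history)
})
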