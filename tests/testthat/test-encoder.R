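test_that("the architecture's weight counts match the layer plan", {
  cfg <- encoder_config()
  expect_identical(count_parameters(cfg, 7L), 192L)       # 1x1 reduction
  expect_identical(count_parameters(cfg, 1L), 864L)       # 12 * 24 * 3
  expect_identical(count_parameters(cfg, 2L), 0L)         # pooling
  expect_error(count_parameters(cfg, 8L), "invalid")
})

test_that("the shape chain runs 12x100 -> 24 -> 48 -> 20", {
  w <- init_encoder_weights(seed = 1)
  q <- matrix(rnorm(1200), 12, 100)
  z <- encode_qrs(q, w)
  expect_length(z, 24L)
  emb <- embed_record(replicate(4, matrix(rnorm(1200), 12, 100),
                                simplify = FALSE), w)
  expect_length(emb$pooled, 48L)
  expect_length(emb$f, 20L)
  expect_identical(emb$pooled, c(emb$z_max, emb$z_avg))
  expect_true(all(emb$z_max >= emb$z_avg))
  expect_error(encode_qrs(matrix(0, 12, 90), w), "100 samples")
})

test_that("zero weights fix the origin through the leaky activations", {
  w <- init_encoder_weights(seed = 1)
  for (i in seq_along(w$conv)) {
    w$conv[[i]]$W[] <- 0
    w$conv[[i]]$b[] <- 0
  }
  z <- encode_qrs(matrix(rnorm(1200), 12, 100), w)
  expect_identical(z, rep(0, 24))
})

test_that("the conv stack agrees with the direct-summation oracle", {
  for (draw in 1:5) {
    w <- init_encoder_weights(seed = 100 + draw)
    set.seed(200 + draw)
    q <- matrix(rnorm(1200), 12, 100)
    expect_equal(encode_qrs(q, w), naive_encode_qrs(q, w),
                 tolerance = 1e-10)
  }
})

test_that("set pooling computes per-dimension max and mean", {
  z1 <- c(1, 0, rep(0.5, 22))
  z2 <- c(0, 2, rep(0.5, 22))
  a <- aggregate_features(list(z1, z2))
  expect_equal(a[1:2], c(1, 2))
  expect_equal(a[25:26], c(0.5, 1))
  single <- rnorm(24)
  expect_equal(aggregate_features(list(single)), c(single, single))
  zs <- replicate(6, rnorm(24), simplify = FALSE)
  expect_equal(aggregate_features(zs), aggregate_features(rev(zs)))
  expect_error(aggregate_features(list()), "empty|length")
})

test_that("record embedding is permutation- and duplication-stable", {
  w <- init_encoder_weights(seed = 2)
  qs <- replicate(5, matrix(rnorm(1200), 12, 100), simplify = FALSE)
  f1 <- embed_record(qs, w)$f
  f2 <- embed_record(qs[c(4, 2, 5, 1, 3)], w)$f
  expect_identical(f1, f2)
  zmax1 <- embed_record(qs, w)$z_max
  zmax2 <- embed_record(c(qs, qs[3]), w)$z_max
  expect_equal(zmax1, zmax2, tolerance = 1e-12)
})

test_that("the softmax head produces shift-invariant distributions", {
  w <- init_encoder_weights(n_classes = 5, seed = 3)
  f <- rnorm(20)
  p <- softmax_head(f, w)
  expect_length(p, 5L)
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1)
  # equal logits -> uniform
  head0 <- list(W = matrix(0, 5, 20), b = rep(2, 5))
  expect_equal(softmax_head(f, head0), rep(0.2, 5))
  # log-odds example and shift invariance
  head13 <- list(W = matrix(0, 2, 20), b = log(c(1, 3)))
  expect_equal(softmax_head(f, head13), c(0.25, 0.75))
  head13s <- list(W = matrix(0, 2, 20), b = log(c(1, 3)) + 7)
  expect_equal(softmax_head(f, head13s), c(0.25, 0.75))
})

test_that("checkpoints round-trip and validate their shapes", {
  w <- init_encoder_weights(n_classes = 4, seed = 5)
  path <- file.path(tempdir(), "ckpt.json")
  write_weights(w, path)
  back <- read_weights(path)
  expect_equal(back$conv[[1]]$W, w$conv[[1]]$W, tolerance = 1e-12)
  expect_equal(back$fc$b, w$fc$b, tolerance = 1e-12)
  expect_equal(back$head$W, w$head$W, tolerance = 1e-12)
  # corrupt a layer shape
  bad <- jsonlite::read_json(path, simplifyVector = FALSE)
  bad$conv[[1]]$dim <- list(2L, 2L)
  bad$conv[[1]]$W <- as.list(rep(0, 4))
  jsonlite::write_json(bad, path, digits = NA, null = "null")
  expect_error(read_weights(path), "shape mismatch")
})

test_that("training gradients match finite differences", {
  w <- init_encoder_weights(seed = 11)
  sets <- replicate(3, replicate(3, matrix(rnorm(1200), 12, 100),
                                 simplify = FALSE), simplify = FALSE)
  tgt <- matrix(rnorm(60), 20, 3)
  fwd <- embed_sets_forward(sets, w)
  grads <- embed_sets_backward(fwd$F - tgt, fwd, w)
  loss_of <- function(wts) sum((embed_sets_forward(sets, wts)$F - tgt)^2) / 2
  params <- weights_to_params(w)
  set.seed(1)
  for (nm in c("convW1", "convW4", "convb2", "fcW", "fcb")) {
    i <- sample(length(params[[nm]]), 1)
    eps <- 1e-5
    pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
    num <- (loss_of(params_to_weights(pp, w)) -
              loss_of(params_to_weights(pm, w))) / (2 * eps)
    expect_equal(grads[[nm]][i], num, tolerance = 1e-4)
  }
})
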