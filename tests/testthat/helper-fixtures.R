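# Shared fixtures and independent oracles. Expensive fixtures are memoized
# per test run so several files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# labeled QRS datasets built from generator ground truth (no detector in the
# loop), for fast training/evaluation tests
make_qrs_dataset <- function(n_classes = 2, n_per_class = 10, noise_sd = 0,
                             seed = 11) {
  specs <- demo_class_specs(n_classes, noise_sd = noise_sd)
  recs <- generate_dataset(specs, n_per_class = n_per_class, seed = seed)
  lapply(recs, function(r) extract_qrs(r, r$truth_rpeaks))
}

qrs_dataset_cached <- function(n_classes = 2, n_per_class = 10, noise_sd = 0,
                               seed = 11) {
  key <- sprintf("qrs_%d_%d_%g_%d", n_classes, n_per_class, noise_sd, seed)
  memo(key, make_qrs_dataset(n_classes, n_per_class, noise_sd, seed))
}

# a small trained few-shot fit shared by method/evaluation tests
small_fsl_fit <- function() {
  memo("small_fsl_fit", {
    qrs <- qrs_dataset_cached(2, 12)
    train_fsl(qrs, training_config(seed = 42, max_epochs = 30, patience = 5,
                                   batch_size = 8))
  })
}

# independent per-position direct-summation conv/pool oracle for the encoder
# (cross-correlation definition, no im2col)
naive_encode_qrs <- function(q, w) {
  cfg <- w$config
  cur <- q
  ci <- 0L
  for (lay in cfg$layers) {
    if (lay$type == "conv") {
      ci <- ci + 1L
      W <- w$conv[[ci]]$W
      b <- w$conv[[ci]]$b
      xp <- cbind(matrix(0, nrow(cur), lay$p), cur,
                  matrix(0, nrow(cur), lay$p))
      l_out <- (ncol(cur) + 2 * lay$p - lay$k) %/% lay$s + 1
      out <- matrix(0, lay$c_out, l_out)
      for (pos in seq_len(l_out)) {
        patch <- xp[, (pos - 1) * lay$s + seq_len(lay$k), drop = FALSE]
        # weight layout j = c + (kk-1)*c_in, matching as.vector(patch)
        out[, pos] <- W %*% as.vector(patch) + b
      }
      cur <- pmax(out, 0) + cfg$slope * pmin(out, 0)
    } else {
      l_out <- ncol(cur) %/% 2L
      out <- matrix(0, nrow(cur), l_out)
      for (pos in seq_len(l_out))
        out[, pos] <- pmax(cur[, 2 * pos - 1], cur[, 2 * pos])
      cur <- out
    }
  }
  as.numeric(t(cur))                # channel-major flatten
}

# brute-force nested-loop confusion counting oracle for the metric panel
oracle_binary_metrics <- function(truth, pred, positive) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == positive && pred[i] == positive) tp <- tp + 1L
    else if (truth[i] != positive && pred[i] == positive) fp <- fp + 1L
    else if (truth[i] == positive && pred[i] != positive) fn <- fn + 1L
    else tn <- tn + 1L
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  c(accuracy = (tp + tn) / length(truth), precision = prec, recall = rec,
    f1 = if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    sensitivity = rec)
}

# candidate_set builder for consensus tests
fake_candidates <- function(streams, fs = 500) {
  structure(streams, fs = fs, class = "candidate_set")
}

expect_sorted_unique <- function(x) {
  expect_true(all(diff(x) > 0))
}
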