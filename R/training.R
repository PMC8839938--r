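# Metric-learning and softmax training: loss functions, the homogeneous-
# QRS-count triplet/batch samplers, the 70/15/15 split, and the epoch loop
# with best-on-validation checkpointing and early stopping.

#' Euclidean distance between two vectors
#' @param x,y numeric vectors of equal length.
#' @return non-negative scalar.
#' @export
euclidean_distance <- function(x, y) {
  if (length(x) != length(y)) stop("dimension mismatch")
  sqrt(sum((x - y)^2))
}

#' Triplet margin loss
#'
#' `L(a, p, n) = max(d(a, p) - d(a, n) + m, 0)` with Euclidean `d`: zero
#' exactly when the positive sits at least the margin closer to the anchor
#' than the negative does.
#'
#' @param a,p,n anchor, positive and negative vectors (equal length).
#' @param m margin (> 0, default 1).
#' @return non-negative scalar.
#' @export
triplet_margin_loss <- function(a, p, n, m = 1) {
  if (m <= 0) stop("margin must be positive")
  max(euclidean_distance(a, p) - euclidean_distance(a, n) + m, 0)
}

#' Cross-entropy between a probability vector and a one-hot target
#'
#' @param p probability vector (sums to 1).
#' @param y one-hot target of the same length (or the 1-based true-class
#'   index).
#' @return non-negative scalar, `-sum(y * log(p))`.
#' @export
cross_entropy <- function(p, y) {
  if (length(y) == 1L) {
    yi <- as.integer(y)
    if (p[yi] <= 0) stop("zero probability at the true class")
    return(-log(p[yi]))
  }
  if (length(p) != length(y)) stop("dimension mismatch")
  if (any(y == 1 & p <= 0)) stop("zero probability at the true class")
  -sum(y * log(ifelse(y > 0, p, 1)))
}

#' Training configuration
#'
#' @param margin triplet margin (default 1).
#' @param lr Adam learning rate (default 1e-3).
#' @param beta1,beta2,eps Adam moment parameters.
#' @param batch_size triplets (or records, for the softmax trainer) per
#'   batch (default 32).
#' @param max_epochs hard cap on training epochs (default 10000).
#' @param patience epochs without a new validation best before stopping
#'   (default 50).
#' @param fractions train/validation/test split fractions (default
#'   0.70/0.15/0.15).
#' @param seed root seed for splitting, initialization and sampling.
#' @param class_sampling `"frequency"` (anchor classes drawn with dataset
#'   frequency, the default) or `"uniform"`.
#' @param label_field record field carrying the class label
#'   (`"superclass"` or `"subclass"`).
#' @return an object of class `training_config`.
#' @export
training_config <- function(margin = 1, lr = 1e-3, beta1 = 0.9,
                            beta2 = 0.999, eps = 1e-8, batch_size = 32L,
                            max_epochs = 10000L, patience = 50L,
                            fractions = c(0.70, 0.15, 0.15), seed = 1L,
                            class_sampling = c("frequency", "uniform"),
                            label_field = "superclass") {
  stopifnot(margin > 0, patience >= 1L, length(fractions) == 3L)
  if (abs(sum(fractions) - 1) > 1e-8) stop("`fractions` must sum to 1")
  structure(list(margin = margin, lr = lr, beta1 = beta1, beta2 = beta2,
                 eps = eps, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), fractions = fractions,
                 seed = as.integer(seed),
                 class_sampling = match.arg(class_sampling),
                 label_field = label_field),
            class = "training_config")
}

labels_of <- function(dataset, label_field = "superclass") {
  vapply(dataset, function(r) as.character(r[[label_field]]), character(1))
}

#' Random 70/15/15 split of a dataset
#'
#' Seeded shuffle followed by contiguous cuts at `round(cumsum(fractions)*n)`:
#' a record-level partition (no record appears in two splits), unstratified.
#'
#' @param dataset a list (of `qrs_set` or records).
#' @param fractions length-3 fractions summing to 1.
#' @param seed integer seed.
#' @return list with elements `train`, `validation`, `test`.
#' @export
split_dataset <- function(dataset, fractions = c(0.70, 0.15, 0.15),
                          seed = 1L) {
  n <- length(dataset)
  if (n == 0L) stop("empty dataset")
  if (abs(sum(fractions) - 1) > 1e-8) stop("`fractions` must sum to 1")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  ord <- sample.int(n)
  c1 <- round(fractions[1] * n)
  c2 <- round((fractions[1] + fractions[2]) * n)
  list(train = dataset[ord[seq_len(c1)]],
       validation = dataset[ord[(c1 + 1):c2]],
       test = dataset[ord[(c2 + 1):n]])
}

#' Sample one homogeneous-cardinality triplet batch
#'
#' First draws the batch's QRS count from the frequency-weighted distribution
#' of beat counts in the dataset, then restricts to records with that count
#' and draws `batch_size` (anchor, positive, negative) triplets within the
#' restriction: the anchor class comes from the class-frequency distribution
#' (or uniform), the positive shares the anchor's class, the negative does
#' not. Counts whose restriction cannot host a triplet are redrawn, up to
#' `max_attempts`. Uses the session RNG; seed upstream for reproducibility.
#'
#' @param dataset list of labeled `qrs_set`.
#' @param batch_size triplets per batch.
#' @param class_sampling `"frequency"` or `"uniform"`.
#' @param label_field label field name.
#' @param max_attempts redraw cap before erroring.
#' @return an object of class `triplet_batch`: list with `anchors`,
#'   `positives`, `negatives` (lists of `qrs_set`) and `qrs_count`.
#' @export
sample_triplet_batch <- function(dataset, batch_size = 32L,
                                 class_sampling = "frequency",
                                 label_field = "superclass",
                                 max_attempts = 1000L) {
  labs <- labels_of(dataset, label_field)
  if (length(unique(labs)) < 2L) stop("need at least 2 classes")
  counts <- vapply(dataset, n_beats, integer(1))
  count_vals <- sort(unique(counts))
  count_freq <- as.numeric(table(factor(counts, levels = count_vals)))
  for (attempt in seq_len(max_attempts)) {
    cval <- if (length(count_vals) == 1L) count_vals
            else sample(count_vals, 1L, prob = count_freq)
    sel <- which(counts == cval)
    sl <- labs[sel]
    tab <- table(sl)
    feasible <- names(tab)[tab >= 2L & sum(tab) - tab >= 1L]
    if (!length(feasible)) next
    anchors <- positives <- negatives <- vector("list", batch_size)
    ok <- TRUE
    for (b in seq_len(batch_size)) {
      prob <- if (class_sampling == "frequency")
        as.numeric(tab[feasible]) else rep(1, length(feasible))
      acl <- if (length(feasible) == 1L) feasible
             else sample(feasible, 1L, prob = prob)
      same <- sel[sl == acl]
      diff <- sel[sl != acl]
      if (length(same) < 2L || !length(diff)) { ok <- FALSE; break }
      ap <- sample(same, 2L)
      anchors[[b]] <- dataset[[ap[1]]]
      positives[[b]] <- dataset[[ap[2]]]
      negatives[[b]] <- dataset[[if (length(diff) == 1L) diff
                                 else sample(diff, 1L)]]
    }
    if (ok)
      return(structure(list(anchors = anchors, positives = positives,
                            negatives = negatives, qrs_count = cval),
                       class = "triplet_batch"))
  }
  stop("no QRS count supports a triplet after ", max_attempts, " attempts")
}

# batch of labeled records sharing one QRS count (softmax trainer)
sample_label_batch <- function(dataset, batch_size, labs, max_attempts = 1000L) {
  counts <- vapply(dataset, n_beats, integer(1))
  count_vals <- sort(unique(counts))
  count_freq <- as.numeric(table(factor(counts, levels = count_vals)))
  for (attempt in seq_len(max_attempts)) {
    cval <- if (length(count_vals) == 1L) count_vals
            else sample(count_vals, 1L, prob = count_freq)
    sel <- which(counts == cval)
    if (!length(sel)) next
    idx <- sel[sample.int(length(sel), batch_size, replace = TRUE)]
    return(list(records = dataset[idx], labels = labs[idx],
                qrs_count = cval))
  }
  stop("could not form a batch")
}

# proximity accuracy of `weights` on validation records, with class centers
# computed from the training split
proximity_accuracy <- function(weights, train, validation, label_field) {
  emb_tr <- embed_many(train, weights)
  emb_va <- embed_many(validation, weights)
  centers <- class_centers(emb_tr, labels_of(train, label_field))
  pred <- apply(emb_va, 2L, function(f)
    nearest_center_classify(f, centers)$label)
  mean(pred == labels_of(validation, label_field))
}

# 20 x n matrix of record embeddings
embed_many <- function(records, weights) {
  if (!length(records)) return(matrix(0, weights$config$embed_dim, 0))
  embed_sets_forward(records, weights)$F
}

#' Train the few-shot encoder with triplet margin loss
#'
#' Optimizes the encoder with Adam over sampled homogeneous-cardinality
#' triplet batches (an epoch is `ceil(n_train / batch_size)` batches). After
#' each epoch the validation proximity accuracy is computed (class centers
#' from the training split); weights are checkpointed whenever it improves,
#' and training stops when `patience` epochs pass without improvement or at
#' `max_epochs`.
#'
#' @param dataset list of labeled `qrs_set` covering >= 2 classes, or a
#'   pre-made split as returned by [split_dataset()].
#' @param config a [training_config()].
#' @return an object of class `ecg_encoder_fit` (method `"fsl"`) with the
#'   best-checkpoint weights, training history, and class centers from the
#'   training split; see [predict.ecg_encoder_fit()].
#' @export
train_fsl <- function(dataset, config = training_config()) {
  run_training(dataset, config, method = "fsl", n_classes = NULL)
}

#' Train the softmax-baseline classifier
#'
#' Identical protocol to [train_fsl()] but with the class-sized fully
#' connected head, softmax activation, cross-entropy loss, and batches of
#' labeled records sharing one QRS count. Validation accuracy is plain
#' argmax accuracy.
#'
#' @param dataset as in [train_fsl()].
#' @param n_classes number of classes; default the number observed.
#' @param config a [training_config()].
#' @return an `ecg_encoder_fit` (method `"softmax"`).
#' @export
train_softmax <- function(dataset, n_classes = NULL,
                          config = training_config()) {
  run_training(dataset, config, method = "softmax", n_classes = n_classes)
}

run_training <- function(dataset, config, method, n_classes) {
  if (is.list(dataset) && !is.null(dataset$train)) {
    splits <- dataset
  } else {
    splits <- split_dataset(dataset, config$fractions,
                            seed = derive_seed(config$seed, 1L))
  }
  train <- splits$train
  validation <- splits$validation
  lf <- config$label_field
  classes <- sort(unique(c(labels_of(train, lf), labels_of(validation, lf))))
  if (length(classes) < 2L) stop("need >= 2 classes in train and validation")
  if (method == "softmax") {
    if (is.null(n_classes)) n_classes <- length(classes)
    if (length(classes) > n_classes) stop("labels exceed `n_classes`")
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(derive_seed(config$seed, 2L))
  weights <- init_encoder_weights(
    n_classes = if (method == "softmax") n_classes else NULL,
    seed = derive_seed(config$seed, 3L))
  params <- weights_to_params(weights)
  state <- adam_init(params)
  n_batches <- max(1L, ceiling(length(train) / config$batch_size))
  train_labs <- labels_of(train, lf)

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_accuracy = numeric())
  best_acc <- -Inf
  best_epoch <- 0L
  best_params <- params
  for (epoch in seq_len(config$max_epochs)) {
    loss_sum <- 0
    for (b in seq_len(n_batches)) {
      weights <- params_to_weights(params, weights)
      if (method == "fsl") {
        step <- fsl_batch_step(train, weights, config)
      } else {
        step <- softmax_batch_step(train, train_labs, classes, weights,
                                   config)
      }
      loss_sum <- loss_sum + step$loss
      upd <- adam_step(params, step$grads, state, lr = config$lr,
                       beta1 = config$beta1, beta2 = config$beta2,
                       eps = config$eps)
      params <- upd$params
      state <- upd$state
    }
    weights <- params_to_weights(params, weights)
    acc <- if (method == "fsl") {
      proximity_accuracy(weights, train, validation, lf)
    } else {
      emb <- embed_many(validation, weights)
      pr <- apply(emb, 2L, function(f)
        classes[which.max(softmax_head(f, weights))])
      mean(pr == labels_of(validation, lf))
    }
    history <- rbind(history,
                     data.frame(epoch = epoch,
                                train_loss = loss_sum / n_batches,
                                val_accuracy = acc))
    if (acc > best_acc) {
      best_acc <- acc
      best_epoch <- epoch
      best_params <- params
    }
    if (epoch - best_epoch >= config$patience) break
  }
  best_weights <- params_to_weights(best_params, weights)
  emb_tr <- embed_many(train, best_weights)
  centers <- class_centers(emb_tr, train_labs)
  structure(list(method = method, weights = best_weights,
                 final_weights = params_to_weights(params, weights),
                 config = config, history = history,
                 best_epoch = best_epoch, best_val_accuracy = best_acc,
                 classes = classes, centers = centers, splits = splits),
            class = "ecg_encoder_fit")
}

# one triplet batch: returns mean loss and parameter gradients
fsl_batch_step <- function(train, weights, config) {
  batch <- sample_triplet_batch(train, config$batch_size,
                                class_sampling = config$class_sampling,
                                label_field = config$label_field)
  B <- length(batch$anchors)
  sets <- c(batch$anchors, batch$positives, batch$negatives)
  fwd <- embed_sets_forward(sets, weights)
  F <- fwd$F
  ai <- seq_len(B); pi <- B + ai; ni <- 2L * B + ai
  dF <- matrix(0, nrow(F), ncol(F))
  loss <- 0
  for (b in seq_len(B)) {
    a <- F[, ai[b]]; p <- F[, pi[b]]; n <- F[, ni[b]]
    dap <- sqrt(sum((a - p)^2))
    dan <- sqrt(sum((a - n)^2))
    l <- dap - dan + config$margin
    if (l > 0) {
      loss <- loss + l
      gap <- if (dap > 0) (a - p) / dap else 0 * a
      gan <- if (dan > 0) (a - n) / dan else 0 * a
      dF[, ai[b]] <- dF[, ai[b]] + (gap - gan) / B
      dF[, pi[b]] <- dF[, pi[b]] - gap / B
      dF[, ni[b]] <- dF[, ni[b]] + gan / B
    }
  }
  list(loss = loss / B, grads = embed_sets_backward(dF, fwd, weights))
}

softmax_batch_step <- function(train, train_labs, classes, weights, config) {
  batch <- sample_label_batch(train, config$batch_size, train_labs)
  B <- length(batch$records)
  fwd <- embed_sets_forward(batch$records, weights)
  F <- fwd$F
  logits <- weights$head$W %*% F + weights$head$b
  probs <- apply(logits, 2L, softmax)
  yidx <- match(batch$labels, classes)
  loss <- -mean(log(pmax(probs[cbind(yidx, seq_len(B))], 1e-12)))
  dlogits <- probs
  dlogits[cbind(yidx, seq_len(B))] <- dlogits[cbind(yidx, seq_len(B))] - 1
  dlogits <- dlogits / B
  dF <- crossprod(weights$head$W, dlogits)
  grads <- embed_sets_backward(dF, fwd, weights)
  grads$headW <- dlogits %*% t(F)
  grads$headb <- rowSums(dlogits)
  list(loss = loss, grads = grads)
}
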