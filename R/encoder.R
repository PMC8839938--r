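# The record encoder: a compact 1-D convolutional network mapping one
# 12 x 100 QRS complex to a 24-D feature vector, permutation-invariant
# max/average set pooling over a record's beats into a 48-D vector, and a
# fully connected 48 -> 20 map producing the record embedding. The final
# 1x1 convolution performs GoogLeNet-style channel reduction (96 -> 2) and
# carries only 192 multiplicative weights.

#' Encoder architecture configuration
#'
#' Layer plan of the per-QRS convolutional encoder. Channel plan
#' 12 -> 24 -> 48 -> 96 -> 2 with kernel-2 stride-2 max pooling between
#' convolutions and a leaky rectifier (slope 0.01) after every convolution;
#' sample-axis lengths run 100 -> 50 -> 48 -> 24 -> 24 -> 12, so the final
#' two-channel map flattens (channel-major) to the 24-D per-QRS feature
#' vector. The third convolution uses padding 1: that is the unique padding
#' choice under which the published channel plan yields a 24-D flatten.
#'
#' @return an object of class `encoder_config`.
#' @export
encoder_config <- function() {
  structure(list(
    layers = list(
      list(type = "conv", c_in = 12L, c_out = 24L, k = 3L, p = 1L, s = 1L),
      list(type = "pool", k = 2L, s = 2L),
      list(type = "conv", c_in = 24L, c_out = 48L, k = 3L, p = 0L, s = 1L),
      list(type = "pool", k = 2L, s = 2L),
      list(type = "conv", c_in = 48L, c_out = 96L, k = 3L, p = 1L, s = 1L),
      list(type = "pool", k = 2L, s = 2L),
      list(type = "conv", c_in = 96L, c_out = 2L, k = 1L, p = 0L, s = 1L)),
    slope = 0.01, input_len = 100L, feat_dim = 24L, pooled_dim = 48L,
    embed_dim = 20L), class = "encoder_config")
}

#' Count multiplicative weights of one encoder layer
#'
#' Biases are excluded: a convolution carries
#' `in_channels * out_channels * kernel` weights, a pooling layer none.
#'
#' @param config an [encoder_config()].
#' @param layer 1-based index into the layer list.
#' @return integer weight count.
#' @export
count_parameters <- function(config = encoder_config(), layer) {
  if (layer < 1L || layer > length(config$layers)) stop("invalid layer index")
  lay <- config$layers[[layer]]
  if (lay$type != "conv") return(0L)
  as.integer(lay$c_in) * as.integer(lay$c_out) * as.integer(lay$k)
}

#' Initialize encoder weights
#'
#' Uniform fan-in scaled initialization, `U(-1/sqrt(fan_in), 1/sqrt(fan_in))`,
#' from an explicit seed.
#'
#' @param config an [encoder_config()].
#' @param n_classes if non-NULL, also creates the softmax head (a fully
#'   connected `embed_dim -> n_classes` layer).
#' @param seed integer seed.
#' @return an object of class `encoder_weights`.
#' @export
init_encoder_weights <- function(config = encoder_config(), n_classes = NULL,
                                 seed = 1L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  uinit <- function(nr, nc, fan_in) {
    lim <- 1 / sqrt(fan_in)
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  conv <- list()
  for (lay in config$layers) {
    if (lay$type != "conv") next
    fan <- lay$c_in * lay$k
    conv[[length(conv) + 1L]] <-
      list(W = uinit(lay$c_out, fan, fan),
           b = stats::runif(lay$c_out, -1 / sqrt(fan), 1 / sqrt(fan)))
  }
  fc <- list(W = uinit(config$embed_dim, config$pooled_dim, config$pooled_dim),
             b = stats::runif(config$embed_dim, -1 / sqrt(config$pooled_dim),
                              1 / sqrt(config$pooled_dim)))
  head <- NULL
  if (!is.null(n_classes)) {
    if (n_classes < 2L) stop("`n_classes` must be >= 2")
    head <- list(W = uinit(n_classes, config$embed_dim, config$embed_dim),
                 b = stats::runif(n_classes, -1 / sqrt(config$embed_dim),
                                  1 / sqrt(config$embed_dim)))
  }
  structure(list(conv = conv, fc = fc, head = head, config = config),
            class = "encoder_weights")
}

as_qrs_matrix <- function(q) {
  if (is.list(q) && !is.null(q$qrs)) stop("got a qrs_set; pass a single beat")
  if (!is.matrix(q) || nrow(q) != 12L)
    stop("a QRS complex must be a 12 x L numeric matrix")
  q
}

#' Encode one QRS complex into its 24-D feature vector
#'
#' @param q a 12 x 100 numeric matrix (one beat, mV).
#' @param weights an [init_encoder_weights()] object.
#' @return numeric vector of length 24.
#' @export
encode_qrs <- function(q, weights) {
  q <- as_qrs_matrix(q)
  cfg <- weights$config
  if (ncol(q) != cfg$input_len)
    stop("expected ", cfg$input_len, " samples per lead, got ", ncol(q))
  fwd <- encoder_stack_forward(array(q, c(12L, cfg$input_len, 1L)), weights)
  as.numeric(fwd$Z[, 1L])
}

#' Max/average set pooling of per-QRS feature vectors
#'
#' The first 24 output entries are the per-dimension maximum over the set,
#' the last 24 the per-dimension mean; both are permutation-invariant and the
#' max half is duplication-invariant.
#'
#' @param zs a 24 x n matrix or a list of length-24 vectors (n >= 1).
#' @return numeric vector of length 48.
#' @export
aggregate_features <- function(zs) {
  if (is.list(zs)) {
    if (!length(zs)) stop("empty feature set")
    zs <- do.call(cbind, zs)
  }
  if (!is.matrix(zs)) zs <- matrix(zs, ncol = 1L)
  if (ncol(zs) < 1L) stop("empty feature set")
  if (nrow(zs) != 24L) stop("feature vectors must have length 24")
  c(apply(zs, 1L, max), rowMeans(zs))
}

#' Embed a record's QRS set into the 20-D record embedding
#'
#' Encodes each beat, pools the per-beat features with max/average set
#' pooling, and applies the fully connected 48 -> 20 map. All intermediates
#' are returned.
#'
#' @param x a `qrs_set` (see [extract_qrs()]) or a list of 12 x 100 matrices.
#' @param weights an [init_encoder_weights()] object.
#' @return an object of class `record_embedding`: list with `z_per_qrs`
#'   (24 x n), `z_max`, `z_avg`, `pooled` (48), `f` (20).
#' @export
embed_record <- function(x, weights) {
  beats <- if (inherits(x, "qrs_set")) x$qrs else x
  if (!length(beats)) stop("empty QRS set")
  cfg <- weights$config
  arr <- array(0, c(12L, cfg$input_len, length(beats)))
  for (i in seq_along(beats)) arr[, , i] <- as_qrs_matrix(beats[[i]])
  fwd <- encoder_stack_forward(arr, weights)
  z_max <- apply(fwd$Z, 1L, max)
  z_avg <- rowMeans(fwd$Z)
  pooled <- c(z_max, z_avg)
  f <- as.numeric(weights$fc$W %*% pooled + weights$fc$b)
  structure(list(z_per_qrs = fwd$Z, z_max = z_max, z_avg = z_avg,
                 pooled = pooled, f = f),
            class = "record_embedding")
}

#' Softmax classification head
#'
#' Applies the class-sized fully connected layer to a record embedding and
#' the softmax map, yielding a class probability distribution.
#'
#' @param f numeric embedding vector (length `embed_dim`).
#' @param weights an [init_encoder_weights()] object created with
#'   `n_classes`, or a list with elements `W`, `b`.
#' @return numeric probability vector (non-negative, sums to 1).
#' @export
softmax_head <- function(f, weights) {
  head <- if (inherits(weights, "encoder_weights")) weights$head else weights
  if (is.null(head)) stop("weights carry no softmax head")
  logits <- as.numeric(head$W %*% f + head$b)
  softmax(logits)
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# joint embedding of many sets in one conv pass; sets is a list of qrs_set
# (or lists of 12x100 matrices). Returns embeddings plus everything the
# backward pass needs.
embed_sets_forward <- function(sets, weights) {
  cfg <- weights$config
  counts <- vapply(sets, function(s)
    length(if (inherits(s, "qrs_set")) s$qrs else s), integer(1))
  m <- sum(counts)
  arr <- array(0, c(12L, cfg$input_len, m))
  pos <- 0L
  for (s in sets) {
    beats <- if (inherits(s, "qrs_set")) s$qrs else s
    for (b in beats) {
      pos <- pos + 1L
      arr[, , pos] <- b
    }
  }
  fwd <- encoder_stack_forward(arr, weights)
  ends <- cumsum(counts)
  groups <- mapply(function(s, e) s:e, ends - counts + 1L, ends,
                   SIMPLIFY = FALSE)
  S <- length(sets)
  A <- matrix(0, cfg$pooled_dim, S)
  amax <- matrix(0L, cfg$feat_dim, S)
  for (i in seq_len(S)) {
    Zg <- fwd$Z[, groups[[i]], drop = FALSE]
    amax[, i] <- max.col(Zg, ties.method = "first")
    A[, i] <- c(Zg[cbind(seq_len(cfg$feat_dim), amax[, i])], rowMeans(Zg))
  }
  F <- weights$fc$W %*% A + weights$fc$b
  list(F = F, A = A, amax = amax, groups = groups, stack = fwd, m = m)
}

# backward from dF (embed_dim x S) to all encoder gradients
embed_sets_backward <- function(dF, fwd, weights) {
  cfg <- weights$config
  dWfc <- dF %*% t(fwd$A)
  dbfc <- rowSums(dF)
  dA <- crossprod(weights$fc$W, dF)              # pooled_dim x S
  dZ <- matrix(0, cfg$feat_dim, fwd$m)
  for (i in seq_along(fwd$groups)) {
    g <- fwd$groups[[i]]
    n <- length(g)
    dmax <- dA[seq_len(cfg$feat_dim), i]
    davg <- dA[cfg$feat_dim + seq_len(cfg$feat_dim), i] / n
    dZ[, g] <- dZ[, g] + davg
    cols <- g[fwd$amax[, i]]
    dZ[cbind(seq_len(cfg$feat_dim), cols)] <-
      dZ[cbind(seq_len(cfg$feat_dim), cols)] + dmax
  }
  conv_grads <- encoder_stack_backward(dZ, fwd$stack, weights)
  grads <- list()
  for (i in seq_along(conv_grads)) {
    grads[[paste0("convW", i)]] <- conv_grads[[i]]$dW
    grads[[paste0("convb", i)]] <- conv_grads[[i]]$db
  }
  grads$fcW <- dWfc
  grads$fcb <- dbfc
  grads
}

#' Write encoder weights as a versioned JSON checkpoint
#'
#' @param weights an `encoder_weights` object.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  flat <- function(l) list(W = as.vector(l$W), b = as.numeric(l$b),
                           dim = dim(l$W))
  payload <- list(
    version = 1L,
    config = list(slope = weights$config$slope,
                  embed_dim = weights$config$embed_dim),
    conv = lapply(weights$conv, flat),
    fc = flat(weights$fc),
    head = if (!is.null(weights$head)) flat(weights$head))
  jsonlite::write_json(payload, path, digits = NA, null = "null")
  invisible(path)
}

#' Read an encoder checkpoint, validating shapes against the architecture
#'
#' @param path checkpoint written by [write_weights()].
#' @return an `encoder_weights` object.
#' @export
read_weights <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg <- encoder_config()
  unflat <- function(l) list(W = matrix(unlist(l$W), unlist(l$dim)[1],
                                        unlist(l$dim)[2]),
                             b = as.numeric(unlist(l$b)))
  conv_layers <- Filter(function(l) l$type == "conv", cfg$layers)
  if (length(p$conv) != length(conv_layers))
    stop("checkpoint has ", length(p$conv), " conv layers, architecture has ",
         length(conv_layers))
  conv <- lapply(p$conv, unflat)
  for (i in seq_along(conv)) {
    lay <- conv_layers[[i]]
    if (!all(dim(conv[[i]]$W) == c(lay$c_out, lay$c_in * lay$k)))
      stop("checkpoint layer ", i, " shape mismatch")
  }
  fc <- unflat(p$fc)
  if (!all(dim(fc$W) == c(cfg$embed_dim, cfg$pooled_dim)))
    stop("checkpoint fully connected layer shape mismatch")
  head <- if (!is.null(p$head)) unflat(p$head)
  structure(list(conv = conv, fc = fc, head = head, config = cfg),
            class = "encoder_weights")
}
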