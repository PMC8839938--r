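# Internal neural-network machinery: batched 1-D convolution via im2col,
# max pooling, leaky rectifier, and Adam. Inputs to the conv stack are
# 12 x 100 x m arrays (m = total QRS complexes across all sets in a batch);
# all QRS share the 100-sample grid, so patch index matrices depend only on
# the layer geometry and m and are rebuilt cheaply per call.

conv_out_len <- function(l_in, k, p, s) (l_in + 2L * p - k) %/% s + 1L

# patch index matrix for one sample: (c_in*k) x l_out linear indices into the
# padded (c_in x l_pad) sample, weight layout j = c + (kk-1)*c_in
im2col_index <- function(c_in, l_in, k, p, s) {
  l_out <- conv_out_len(l_in, k, p, s)
  starts <- (seq_len(l_out) - 1L) * s          # 0-based start in padded signal
  idx <- matrix(0L, c_in * k, l_out)
  for (kk in seq_len(k)) {
    cols_pad <- starts + kk                     # 1-based padded position
    lin <- outer(seq_len(c_in), (cols_pad - 1L) * c_in, "+")
    idx[(kk - 1L) * c_in + seq_len(c_in), ] <- lin
  }
  idx
}

# forward one conv layer over an array x (c_in x l_in x m)
conv_forward <- function(x, W, b, k, p, s) {
  dm <- dim(x)
  c_in <- dm[1]; l_in <- dm[2]; m <- dm[3]
  l_pad <- l_in + 2L * p
  if (p > 0L) {
    xp <- array(0, c(c_in, l_pad, m))
    xp[, (p + 1L):(p + l_in), ] <- x
  } else xp <- x
  idx1 <- im2col_index(c_in, l_in, k, p, s)
  l_out <- ncol(idx1)
  per <- c_in * l_pad
  big <- rep(as.vector(idx1), m) +
    rep((seq_len(m) - 1L) * per, each = length(idx1))
  P <- matrix(as.vector(xp)[big], nrow = c_in * k)
  y <- W %*% P + b
  list(y = y, P = P, big = big, c_in = c_in, l_in = l_in, l_pad = l_pad,
       l_out = l_out, m = m, p = p)
}

# backward through the same layer; dy is c_out x (l_out*m)
conv_backward <- function(dy, cache, W) {
  dW <- dy %*% t(cache$P)
  db <- rowSums(dy)
  dP <- crossprod(W, dy)                        # (c_in*k) x (l_out*m)
  acc <- rowsum(as.vector(dP), cache$big)
  dxp <- numeric(cache$c_in * cache$l_pad * cache$m)
  dxp[as.integer(rownames(acc))] <- acc
  dxp <- array(dxp, c(cache$c_in, cache$l_pad, cache$m))
  dx <- if (cache$p > 0L)
    dxp[, (cache$p + 1L):(cache$p + cache$l_in), , drop = FALSE]
  else dxp
  list(dW = dW, db = db, dx = dx)
}

lrelu <- function(y, slope) pmax(y, 0) + slope * pmin(y, 0)
lrelu_grad <- function(y, slope) ifelse(y > 0, 1, slope)

# kernel-2 stride-2 max pool on y (c x (l*m) matrix, l even per sample)
pool2_forward <- function(y) {
  odd <- y[, seq(1L, ncol(y), 2L), drop = FALSE]
  even <- y[, seq(2L, ncol(y), 2L), drop = FALSE]
  mask <- odd >= even
  list(y = pmax(odd, even), mask = mask)
}

pool2_backward <- function(dy, mask) {
  out <- matrix(0, nrow(dy), 2L * ncol(dy))
  out[, seq(1L, ncol(out), 2L)] <- dy * mask
  out[, seq(2L, ncol(out), 2L)] <- dy * !mask
  out
}

# full conv-stack forward: x is 12 x 100 x m; returns Z (feat_dim x m) and
# caches for the backward pass
encoder_stack_forward <- function(x, weights, config = weights$config) {
  m <- dim(x)[3]
  cur <- x
  caches <- vector("list", length(config$layers))
  ci <- 0L
  for (li in seq_along(config$layers)) {
    lay <- config$layers[[li]]
    if (lay$type == "conv") {
      ci <- ci + 1L
      cf <- conv_forward(cur, weights$conv[[ci]]$W, weights$conv[[ci]]$b,
                         lay$k, lay$p, lay$s)
      act <- lrelu(cf$y, config$slope)
      caches[[li]] <- list(type = "conv", cf = cf, pre = cf$y, ci = ci)
      cur <- array(act, c(lay$c_out, cf$l_out, m))
    } else {
      ym <- matrix(cur, dim(cur)[1], dim(cur)[2] * m)
      pf <- pool2_forward(ym)
      caches[[li]] <- list(type = "pool", mask = pf$mask)
      cur <- array(pf$y, c(dim(cur)[1], dim(cur)[2] %/% 2L, m))
    }
  }
  # channel-major flatten: channel 1's positions first, then channel 2's
  dm <- dim(cur)                                 # 2 x 12 x m
  Z <- matrix(aperm(cur, c(2, 1, 3)), dm[1] * dm[2], m)
  list(Z = Z, caches = caches, out_dim = dm)
}

encoder_stack_backward <- function(dZ, fwd, weights, config = weights$config) {
  dm <- fwd$out_dim
  m <- dm[3]
  cur <- aperm(array(dZ, c(dm[2], dm[1], m)), c(2, 1, 3))
  grads <- lapply(weights$conv, function(wc)
    list(dW = matrix(0, nrow(wc$W), ncol(wc$W)), db = numeric(length(wc$b))))
  for (li in rev(seq_along(config$layers))) {
    cache <- fwd$caches[[li]]
    if (cache$type == "conv") {
      dy <- matrix(cur, dim(cur)[1], dim(cur)[2] * m) *
        lrelu_grad(cache$pre, config$slope)
      cb <- conv_backward(dy, cache$cf, weights$conv[[cache$ci]]$W)
      grads[[cache$ci]] <- list(dW = cb$dW, db = cb$db)
      cur <- cb$dx
    } else {
      dy <- matrix(cur, dim(cur)[1], dim(cur)[2] * m)
      up <- pool2_backward(dy, cache$mask)
      cur <- array(up, c(dim(cur)[1], dim(cur)[2] * 2L, m))
    }
  }
  grads
}

# Adam optimizer state over a flat named list of parameter arrays
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# flatten / restore weights <-> named parameter list (for Adam)
weights_to_params <- function(w) {
  out <- list()
  for (i in seq_along(w$conv)) {
    out[[paste0("convW", i)]] <- w$conv[[i]]$W
    out[[paste0("convb", i)]] <- w$conv[[i]]$b
  }
  out$fcW <- w$fc$W; out$fcb <- w$fc$b
  if (!is.null(w$head)) { out$headW <- w$head$W; out$headb <- w$head$b }
  out
}

params_to_weights <- function(params, w) {
  for (i in seq_along(w$conv)) {
    w$conv[[i]]$W <- params[[paste0("convW", i)]]
    w$conv[[i]]$b <- params[[paste0("convb", i)]]
  }
  w$fc$W <- params$fcW; w$fc$b <- params$fcb
  if (!is.null(w$head)) { w$head$W <- params$headW; w$head$b <- params$headb }
  w
}
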