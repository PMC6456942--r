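# Primitive differentiable ops over channel-major batches.
#
# All spatial tensors use one layout: a C x (n*L) matrix ("cmat") whose
# columns are positions, grouped example-major, so convolutions reduce to
# contiguous GEMMs (src/conv1d.cpp).  Every *_fwd returns what its *_bwd
# needs as `cache`; backward returns `dx` plus gradients named like the
# parameters so the whole parameter tree can be updated by a parallel walk.

conv_fwd <- function(x, W, b, n, L) {
  cpp_conv1d_fwd(x, W, b, n, L)
}

conv_bwd <- function(x, W, dy, n, L) {
  cpp_conv1d_bwd(x, W, dy, n, L)
}

relu_fwd <- function(x) {
  list(out = x * (x > 0), cache = x > 0)
}

relu_bwd <- function(dy, cache) {
  dy * cache
}

# Batch normalization per channel (rows).  Training mode uses batch moments
# and updates the running estimates in the returned `state`; evaluation mode
# applies the frozen running statistics so the forward pass is deterministic.
bn_fwd <- function(x, p, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- rowMeans(x)
    v <- rowMeans(x * x) - mu * mu
    v <- pmax(v, 0)
    inv_sd <- 1 / sqrt(v + eps)
    xhat <- (x - mu) * inv_sd
    state <- list(run_mean = (1 - momentum) * p$run_mean + momentum * mu,
                  run_var = (1 - momentum) * p$run_var + momentum * v)
    cache <- list(xhat = xhat, inv_sd = inv_sd, gamma = p$gamma)
  } else {
    inv_sd <- 1 / sqrt(p$run_var + eps)
    xhat <- (x - p$run_mean) * inv_sd
    state <- NULL
    cache <- NULL
  }
  list(out = p$gamma * xhat + p$beta, cache = cache, state = state)
}

bn_bwd <- function(dy, cache) {
  xhat <- cache$xhat
  N <- ncol(xhat)
  dgamma <- rowSums(dy * xhat)
  dbeta <- rowSums(dy)
  dxhat <- dy * cache$gamma
  dx <- cache$inv_sd * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# Max pooling along positions with width = stride = `pool`; trailing
# positions that do not fill a window are dropped.
pool_fwd <- function(x, n, L, pool) {
  Lq <- L %/% pool
  i <- rep(seq_len(n) - 1L, each = Lq)
  q <- rep(seq_len(Lq) - 1L, n)
  base <- i * L + q * pool
  cur <- x[, base + 1L, drop = FALSE]
  sel <- matrix(1L, nrow = nrow(x), ncol = length(base))
  for (s in 2:pool) {
    xs <- x[, base + s, drop = FALSE]
    m <- xs > cur
    sel[m] <- s
    cur[m] <- xs[m]
  }
  list(out = cur, cache = list(sel = sel, base = base, L = L, n = n,
                               pool = pool, C = nrow(x)))
}

pool_bwd <- function(dy, cache) {
  dx <- matrix(0, nrow = cache$C, ncol = cache$n * cache$L)
  for (s in seq_len(cache$pool)) {
    tmp <- matrix(0, nrow = cache$C, ncol = length(cache$base))
    m <- cache$sel == s
    tmp[m] <- dy[m]
    dx[, cache$base + s] <- tmp
  }
  dx
}

# Fully connected layer on example-major feature matrices (n x D).
fc_fwd <- function(x, W, b) {
  sweep(x %*% W, 2L, b, "+")
}

fc_bwd <- function(x, W, dy) {
  list(dx = dy %*% t(W), grads = list(W = crossprod(x, dy), b = colSums(dy)))
}

# Flatten a cmat (C x n*L) into an n x (C*L) feature matrix and back.
flatten_fwd <- function(x, n) {
  t(matrix(x, nrow = nrow(x) * (ncol(x) / n), ncol = n))
}

flatten_bwd <- function(dy, C, n) {
  matrix(t(dy), nrow = C)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Adam: walk the gradient tree (whose structure mirrors the trainable subset
# of the parameter tree) and update parameters and moment estimates in step.
adam_step <- function(params, grads, state, t, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.list(grads)) {
    if (is.null(state)) state <- vector("list", length(grads))
    names(state) <- names(grads)
    for (nm in names(grads)) {
      res <- adam_step(params[[nm]], grads[[nm]], state[[nm]], t, lr,
                       beta1, beta2, eps)
      params[[nm]] <- res$params
      state[[nm]] <- res$state
    }
    return(list(params = params, state = state))
  }
  if (is.null(state)) state <- list(m = grads * 0, v = grads * 0)
  state$m <- beta1 * state$m + (1 - beta1) * grads
  state$v <- beta2 * state$v + (1 - beta2) * grads * grads
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  params <- params - lr * mhat / (sqrt(vhat) + eps)
  list(params = params, state = state)
}
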