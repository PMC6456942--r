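#' Define the architecture of the dual-branch dense convolutional network
#'
#' The standard network has a DNA branch (one-hot sequence input, 4 input
#' channels), a DNase branch (per-base openness, 1 input channel) with the
#' identical architecture apart from its one-dimensional initial convolution,
#' and a joint feedforward head ending in `n_markers` independent sigmoid
#' outputs.  Each branch is: initial convolution (`init_kernels` kernels of
#' length `kernel_len`) followed by `n_dense_blocks` repetitions of a
#' densely connected convolutional block (three pre-activation BN-ReLU-conv
#' layers whose outputs are concatenated onto their input, growth
#' `growth` channels per layer), a 1x1 transition convolution back to
#' `init_kernels` channels and a max-pooling layer of width `pool_len`.
#' `dna_only` / `dnase_only` drop the other branch and feed the remaining
#' feature vector to the head.
#'
#' @param mode `"standard"`, `"dna_only"` or `"dnase_only"`.
#' @param seq_len Input region length in bp (default 1000).
#' @param n_markers Number of sigmoid outputs (default 7).
#' @param init_kernels Kernels in the initial convolution (default 128).
#' @param kernel_len Convolution kernel length; must be odd (default 9).
#' @param growth Channels added by each dense-block layer (default 128).
#' @param dense_block_layers Convolution layers per dense block (default 3).
#' @param n_dense_blocks Dense blocks per branch (default 2).
#' @param pool_len Max-pooling width/stride (default 4). Pooling uses floor
#'   semantics: trailing positions that do not fill a window are dropped.
#' @param head_hidden Width of the hidden feedforward layer (default 256).
#' @param init_gain Scale factor on the He initialization of every
#'   convolution (default 0.03). All convolutions feed a batch
#'   normalization, which makes their initial magnitude redundant; a small
#'   initial norm lets Adam rotate kernel directions quickly, which speeds
#'   convergence and drives first-layer kernels toward clean data-driven
#'   motifs.
#' @return A validated `network_spec` list.
#' @export
network_spec <- function(mode = c("standard", "dna_only", "dnase_only"),
                         seq_len = 1000L, n_markers = 7L, init_kernels = 128L,
                         kernel_len = 9L, growth = 128L,
                         dense_block_layers = 3L, n_dense_blocks = 2L,
                         pool_len = 4L, head_hidden = 256L,
                         init_gain = 0.03) {
  mode <- match.arg(mode)
  if (kernel_len %% 2L != 1L || kernel_len < 1L) {
    ed_stop("kernel_len must be odd and positive", "construction")
  }
  if (min(seq_len, init_kernels, growth, head_hidden, pool_len) < 1L) {
    ed_stop("all sizes must be positive", "construction")
  }
  if (init_gain <= 0) ed_stop("init_gain must be positive", "construction")
  L <- seq_len
  for (b in seq_len(n_dense_blocks)) {
    L <- L %/% pool_len
    if (L < 1L) {
      ed_stop(sprintf(
        "pooling stage %d reduces the feature length to zero (seq_len %d, pool %d)",
        b, seq_len, pool_len), "construction")
    }
  }
  structure(list(mode = mode, seq_len = as.integer(seq_len),
                 n_markers = as.integer(n_markers),
                 init_kernels = as.integer(init_kernels),
                 kernel_len = as.integer(kernel_len),
                 growth = as.integer(growth),
                 dense_block_layers = as.integer(dense_block_layers),
                 n_dense_blocks = as.integer(n_dense_blocks),
                 pool_len = as.integer(pool_len),
                 head_hidden = as.integer(head_hidden),
                 init_gain = init_gain,
                 final_len = as.integer(L)),
            class = "network_spec")
}

# Convolution parameters: He initialization scaled by the spec's init_gain
# (every convolution feeds a batchnorm, so the initial magnitude is
# redundant and a small norm speeds direction learning under Adam).
# W is a (C_out, C_in, k) array.
init_conv <- function(c_out, c_in, k, gain) {
  sd <- gain * sqrt(2 / (c_in * k))
  list(W = array(rnorm(c_out * c_in * k, sd = sd), dim = c(c_out, c_in, k)),
       b = numeric(c_out))
}

init_bn <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c), run_mean = numeric(c),
       run_var = rep(1, c))
}

init_branch <- function(spec, c_in) {
  K <- spec$init_kernels
  g <- spec$growth
  nl <- spec$dense_block_layers
  branch <- list(conv0 = init_conv(K, c_in, spec$kernel_len,
                                   spec$init_gain))
  for (b in seq_len(spec$n_dense_blocks)) {
    block <- list()
    c_cur <- K
    for (l in seq_len(nl)) {
      # named layers: the gradient tree is walked by name during updates
      block[[paste0("l", l)]] <- list(bn = init_bn(c_cur),
                                      conv = init_conv(g, c_cur,
                                                       spec$kernel_len,
                                                       spec$init_gain))
      c_cur <- c_cur + g
    }
    branch[[paste0("block", b)]] <- block
    branch[[paste0("trans", b)]] <- list(bn = init_bn(c_cur),
                                         conv = init_conv(K, c_cur, 1L,
                                                          spec$init_gain))
  }
  branch$bn_final <- init_bn(K)
  branch
}

#' Build a network with seeded initial parameters
#'
#' Identical seeds give identical initial parameters, and together with a
#' seeded training run make the whole fit reproducible.
#'
#' @param spec A [network_spec()].
#' @param seed Integer RNG seed for initialization.
#' @return An `epideep_model` (parameter container with the spec embedded).
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  set.seed(seed)
  params <- list()
  if (spec$mode != "dnase_only") params$dna <- init_branch(spec, 4L)
  if (spec$mode != "dna_only") params$dnase <- init_branch(spec, 1L)
  n_branch <- length(params)
  d_in <- n_branch * spec$init_kernels * spec$final_len
  params$head <- list(
    fc1 = list(W = matrix(rnorm(d_in * spec$head_hidden,
                                sd = sqrt(2 / d_in)),
                          nrow = d_in),
               b = numeric(spec$head_hidden)),
    fc2 = list(W = matrix(rnorm(spec$head_hidden * spec$n_markers,
                                sd = sqrt(1 / spec$head_hidden)),
                          nrow = spec$head_hidden),
               b = numeric(spec$n_markers))
  )
  structure(list(spec = spec, params = params, seed = seed,
                 training_log = NULL),
            class = "epideep_model")
}

# ---- forward / backward ----------------------------------------------------
# Branch caches hold every intermediate needed for the hand-derived backward
# pass; `training` toggles batch-statistic batchnorm + running-stat updates.

block_fwd <- function(block, x, n, L, training) {
  caches <- vector("list", length(block))
  for (l in seq_along(block)) {
    bn <- bn_fwd(x, block[[l]]$bn, training)
    if (training && !is.null(bn$state)) {
      block[[l]]$bn[c("run_mean", "run_var")] <- bn$state
    }
    r <- relu_fwd(bn$out)
    h <- conv_fwd(r$out, block[[l]]$conv$W, block[[l]]$conv$b, n, L)
    caches[[l]] <- list(bn = bn$cache, relu = r$cache, conv_in = r$out,
                        c_in = nrow(x))
    x <- rbind(x, h)
  }
  list(out = x, caches = caches, block = block)
}

block_bwd <- function(block, dout, caches, n, L) {
  grads <- setNames(vector("list", length(block)), names(block))
  for (l in rev(seq_along(block))) {
    ca <- caches[[l]]
    c_in <- ca$c_in
    g <- nrow(dout) - c_in
    dh <- dout[(c_in + 1L):(c_in + g), , drop = FALSE]
    dout <- dout[seq_len(c_in), , drop = FALSE]
    cb <- conv_bwd(ca$conv_in, block[[l]]$conv$W, dh, n, L)
    dr <- relu_bwd(cb$dx, ca$relu)
    bb <- bn_bwd(dr, ca$bn)
    dout <- dout + bb$dx
    grads[[l]] <- list(bn = bb$grads, conv = list(W = cb$dW, b = cb$db))
  }
  list(dx = dout, grads = grads)
}

branch_fwd <- function(branch, x, n, spec, training) {
  L <- spec$seq_len
  cache <- list(conv0_in = x, L0 = L)
  x <- conv_fwd(x, branch$conv0$W, branch$conv0$b, n, L)
  for (b in seq_len(spec$n_dense_blocks)) {
    bk <- paste0("block", b)
    tk <- paste0("trans", b)
    bf <- block_fwd(branch[[bk]], x, n, L, training)
    branch[[bk]] <- bf$block
    bn <- bn_fwd(bf$out, branch[[tk]]$bn, training)
    if (training && !is.null(bn$state)) {
      branch[[tk]]$bn[c("run_mean", "run_var")] <- bn$state
    }
    r <- relu_fwd(bn$out)
    xc <- conv_fwd(r$out, branch[[tk]]$conv$W, branch[[tk]]$conv$b, n, L)
    pf <- pool_fwd(xc, n, L, spec$pool_len)
    cache[[bk]] <- bf$caches
    cache[[tk]] <- list(bn = bn$cache, relu = r$cache, conv_in = r$out,
                        block_out = bf$out, pool = pf$cache, L = L)
    x <- pf$out
    L <- L %/% spec$pool_len
  }
  bnf <- bn_fwd(x, branch$bn_final, training)
  if (training && !is.null(bnf$state)) {
    branch$bn_final[c("run_mean", "run_var")] <- bnf$state
  }
  rf <- relu_fwd(bnf$out)
  cache$final <- list(bn = bnf$cache, relu = rf$cache, L = L)
  feat <- flatten_fwd(rf$out, n)
  list(feat = feat, cache = cache, branch = branch, L_final = L)
}

branch_bwd <- function(branch, dfeat, cache, n, spec) {
  K <- spec$init_kernels
  grads <- list()
  dx <- flatten_bwd(dfeat, K, n)
  dr <- relu_bwd(dx, cache$final$relu)
  bb <- bn_bwd(dr, cache$final$bn)
  grads$bn_final <- bb$grads
  dx <- bb$dx
  for (b in rev(seq_len(spec$n_dense_blocks))) {
    bk <- paste0("block", b)
    tk <- paste0("trans", b)
    tc <- cache[[tk]]
    dxc <- pool_bwd(dx, tc$pool)
    cb <- conv_bwd(tc$conv_in, branch[[tk]]$conv$W, dxc, n, tc$L)
    dr <- relu_bwd(cb$dx, tc$relu)
    bnb <- bn_bwd(dr, tc$bn)
    grads[[tk]] <- list(bn = bnb$grads, conv = list(W = cb$dW, b = cb$db))
    blb <- block_bwd(branch[[bk]], bnb$dx, cache[[bk]], n, tc$L)
    grads[[bk]] <- blb$grads
    dx <- blb$dx
  }
  cb <- conv_bwd(cache$conv0_in, branch$conv0$W, dx, n, cache$L0)
  grads$conv0 <- list(W = cb$dW, b = cb$db)
  grads
}

# Full forward pass on cmat inputs; returns logits and (optionally) caches,
# plus params with updated batchnorm running statistics when training.
net_fwd <- function(model, xseq, xopn, n, training = FALSE) {
  spec <- model$spec
  params <- model$params
  feats <- list()
  caches <- list()
  if (spec$mode != "dnase_only") {
    bf <- branch_fwd(params$dna, xseq, n, spec, training)
    params$dna <- bf$branch
    feats$dna <- bf$feat
    caches$dna <- bf$cache
  }
  if (spec$mode != "dna_only") {
    bf <- branch_fwd(params$dnase, xopn, n, spec, training)
    params$dnase <- bf$branch
    feats$dnase <- bf$feat
    caches$dnase <- bf$cache
  }
  feat <- do.call(cbind, unname(feats))
  z1 <- fc_fwd(feat, params$head$fc1$W, params$head$fc1$b)
  r1 <- relu_fwd(z1)
  logits <- fc_fwd(r1$out, params$head$fc2$W, params$head$fc2$b)
  caches$head <- list(feat = feat, relu = r1$cache, hidden = r1$out)
  list(logits = logits, caches = caches, params = params)
}

# Backward from dlogits; returns the gradient tree (mirrors trainable params).
net_bwd <- function(model, dlogits, caches, n) {
  spec <- model$spec
  params <- model$params
  hc <- caches$head
  f2 <- fc_bwd(hc$hidden, params$head$fc2$W, dlogits)
  dr1 <- relu_bwd(f2$dx, hc$relu)
  f1 <- fc_bwd(hc$feat, params$head$fc1$W, dr1)
  grads <- list(head = list(fc1 = f1$grads, fc2 = f2$grads))
  dfeat <- f1$dx
  d_branch <- spec$init_kernels * spec$final_len
  off <- 0L
  if (spec$mode != "dnase_only") {
    grads$dna <- branch_bwd(params$dna, dfeat[, seq_len(d_branch),
                                              drop = FALSE],
                            caches$dna, n, spec)
    off <- d_branch
  }
  if (spec$mode != "dna_only") {
    grads$dnase <- branch_bwd(params$dnase,
                              dfeat[, off + seq_len(d_branch), drop = FALSE],
                              caches$dnase, n, spec)
  }
  grads
}

# ---- fast engine -----------------------------------------------------------
# Same math as net_fwd/net_bwd, with each branch executed by the fused
# single-precision C++ engine (src/branch.cpp); the head stays in R.

net_fwd_fast <- function(model, xseq, xopn, n, training = FALSE) {
  spec <- model$spec
  params <- model$params
  feats <- list()
  caches <- list()
  for (br in intersect(c("dna", "dnase"), names(params))) {
    x <- if (br == "dna") xseq else xopn
    r <- cpp_branch_fwd(params[[br]], x, n, spec$seq_len, spec$pool_len,
                        spec$n_dense_blocks, spec$dense_block_layers,
                        training)
    feats[[br]] <- r$feat
    if (training) {
      caches[[paste0("ws_", br)]] <- r$ws
      params[[br]] <- modifyList(params[[br]], r$bn_updates)
    }
  }
  feat <- do.call(cbind, unname(feats))
  z1 <- fc_fwd(feat, params$head$fc1$W, params$head$fc1$b)
  r1 <- relu_fwd(z1)
  logits <- fc_fwd(r1$out, params$head$fc2$W, params$head$fc2$b)
  caches$head <- list(feat = feat, relu = r1$cache, hidden = r1$out)
  list(logits = logits, caches = caches, params = params)
}

net_bwd_fast <- function(model, dlogits, caches, n) {
  spec <- model$spec
  params <- model$params
  hc <- caches$head
  f2 <- fc_bwd(hc$hidden, params$head$fc2$W, dlogits)
  dr1 <- relu_bwd(f2$dx, hc$relu)
  f1 <- fc_bwd(hc$feat, params$head$fc1$W, dr1)
  grads <- list(head = list(fc1 = f1$grads, fc2 = f2$grads))
  dfeat <- f1$dx
  d_branch <- spec$init_kernels * spec$final_len
  off <- 0L
  for (br in intersect(c("dna", "dnase"), names(params))) {
    grads[[br]] <- cpp_branch_bwd(params[[br]],
                                  caches[[paste0("ws_", br)]],
                                  dfeat[, off + seq_len(d_branch),
                                        drop = FALSE])
    off <- off + d_branch
  }
  grads
}

# Convert an encoded_batch (n x 4 x L arrays) to cmat layout.
batch_to_cmat <- function(batch) {
  n <- dim(batch$seq)[1]
  list(xseq = matrix(aperm(batch$seq, c(2, 3, 1)), nrow = 4L),
       xopn = matrix(aperm(batch$openness, c(2, 3, 1)), nrow = 1L),
       n = n)
}

# Fast path: cmat layout straight from an encoded_dataset's code/openness rows.
rows_to_cmat <- function(dataset, rows) {
  n <- length(rows)
  L <- dataset$region_bp
  v <- as.vector(t(dataset$codes[rows, , drop = FALSE]))
  xseq <- matrix(0, nrow = 4L, ncol = n * L)
  nz <- which(v > 0L)
  xseq[cbind(v[nz], nz)] <- 1
  xopn <- matrix(as.vector(t(dataset$openness[rows, , drop = FALSE])),
                 nrow = 1L)
  list(xseq = xseq, xopn = xopn, n = n)
}

#' Predict marker probabilities for an encoded batch
#'
#' Evaluation-state forward pass (frozen batchnorm statistics), deterministic
#' for fixed inputs.  Outputs are independent per-marker sigmoid
#' probabilities in (0,1); they are not constrained to sum to 1 across
#' markers.
#'
#' @param object An `epideep_model`.
#' @param batch An `encoded_batch` (see [build_batch()]) or a list with cmat
#'   components `xseq`, `xopn`, `n`.
#' @param engine `"cpp"` (fused single-precision engine, the default) or
#'   `"r"` (double-precision reference path); both implement the same
#'   forward pass.
#' @param ... Unused.
#' @return n x n_markers matrix of probabilities.
#' @export
predict.epideep_model <- function(object, batch, engine = c("cpp", "r"),
                                  ...) {
  engine <- match.arg(engine)
  cm <- if (inherits(batch, "encoded_batch")) batch_to_cmat(batch) else batch
  expected <- object$spec$seq_len * cm$n
  if (ncol(cm$xseq) != expected || ncol(cm$xopn) != expected) {
    ed_stop(sprintf("input length %d does not match spec seq_len %d",
                    ncol(cm$xseq) / cm$n, object$spec$seq_len), "dimension")
  }
  fw <- if (engine == "cpp") {
    net_fwd_fast(object, cm$xseq, cm$xopn, cm$n, training = FALSE)
  } else {
    net_fwd(object, cm$xseq, cm$xopn, cm$n, training = FALSE)
  }
  sigmoid(fw$logits)
}

# Eval-mode predictions over dataset rows, in chunks to bound memory.
predict_dataset <- function(model, dataset, rows = seq_len(nrow(dataset$codes)),
                            chunk = 512L) {
  out <- matrix(NA_real_, nrow = length(rows), ncol = model$spec$n_markers)
  idx <- split(seq_along(rows), ceiling(seq_along(rows) / chunk))
  for (ii in idx) {
    out[ii, ] <- predict(model, rows_to_cmat(dataset, rows[ii]))
  }
  colnames(out) <- dataset$markers
  out
}

#' First-layer kernels of the DNA branch
#'
#' @param model An `epideep_model` whose mode includes a DNA branch.
#' @return List of `init_kernels` weight matrices, each 4 x kernel_len with
#'   rows A, C, G, T, ordered by kernel index.
#' @export
first_layer_kernels <- function(model) {
  if (model$spec$mode == "dnase_only") {
    ed_stop("model has no DNA branch (mode dnase_only)", "mode")
  }
  W <- model$params$dna$conv0$W
  lapply(seq_len(dim(W)[1]), function(i) {
    m <- W[i, , , drop = TRUE]
    rownames(m) <- c("A", "C", "G", "T")
    m
  })
}

#' @export
print.epideep_model <- function(x, ...) {
  spec <- x$spec
  K <- spec$init_kernels
  g <- spec$growth
  cat(sprintf("<epideep_model> mode=%s seq_len=%d markers=%d\n", spec$mode,
              spec$seq_len, spec$n_markers))
  branch_desc <- function(name, c_in) {
    L <- spec$seq_len
    cat(sprintf("  %s branch:\n", name))
    cat(sprintf("    conv0 (%d,%d,%d)           -> %d x %d\n", K, c_in,
                spec$kernel_len, K, L))
    for (b in seq_len(spec$n_dense_blocks)) {
      cat(sprintf("    dense block %d (3x BN-ReLU-conv, growth %d) -> %d x %d\n",
                  b, g, K + spec$dense_block_layers * g, L))
      L <- L %/% spec$pool_len
      cat(sprintf("    transition conv (1x1) + maxpool (1,%d)      -> %d x %d\n",
                  spec$pool_len, K, L))
    }
    cat(sprintf("    BN-ReLU + flatten       -> %d\n", K * L))
  }
  if (spec$mode != "dnase_only") branch_desc("DNA", 4L)
  if (spec$mode != "dna_only") branch_desc("DNase", 1L)
  n_branch <- sum(spec$mode != "dnase_only", spec$mode != "dna_only")
  cat(sprintf("  joint head: %d -> %d (ReLU) -> %d sigmoid outputs\n",
              n_branch * K * spec$final_len, spec$head_hidden, spec$n_markers))
  invisible(x)
}

#' @method glance epideep_model
#' @export
glance.epideep_model <- function(x, ...) {
  count <- function(p) {
    if (is.list(p)) sum(vapply(p, count, numeric(1))) else length(p)
  }
  tibble(mode = x$spec$mode, seq_len = x$spec$seq_len,
         n_markers = x$spec$n_markers, init_kernels = x$spec$init_kernels,
         growth = x$spec$growth, n_parameters = count(x$params),
         trained = !is.null(x$training_log))
}

#' Save / load a model checkpoint with its spec embedded
#' @param model An `epideep_model`.
#' @param path Checkpoint path (.rds).
#' @return `path` invisibly (save); the model (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}
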