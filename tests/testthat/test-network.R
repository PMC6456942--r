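test_that("network specs are validated at construction", {
  expect_error(network_spec(kernel_len = 8), class = "epideep_construction")
  err <- tryCatch(network_spec(seq_len = 8, pool_len = 4),
                  error = function(e) conditionMessage(e))
  expect_match(err, "pooling stage 2")
  sp <- tiny_spec()
  expect_equal(sp$final_len, 2L)   # 32 -> 8 -> 2
})

test_that("seeded builds are bitwise reproducible", {
  sp <- tiny_spec()
  m1 <- build_network(sp, seed = 7)
  m2 <- build_network(sp, seed = 7)
  expect_identical(m1$params, m2$params)
  m3 <- build_network(sp, seed = 8)
  expect_false(identical(m3$params$head$fc1$W, m1$params$head$fc1$W))
})

test_that("forward pass honours mode, shape and probability-range contracts", {
  ds <- tiny_dataset(n = 8)
  cm <- epideep:::rows_to_cmat(ds, 1:3)
  for (mode in c("standard", "dna_only", "dnase_only")) {
    m <- build_network(tiny_spec(mode), seed = 1)
    p <- predict(m, cm)
    expect_equal(dim(p), c(3L, 3L))
    expect_true(all(p > 0 & p < 1))
    expect_identical(p, predict(m, cm))   # eval determinism
  }

  # zeroed final layer gives sigmoid(0) = 0.5 everywhere
  m <- build_network(tiny_spec(), seed = 1)
  m$params$head$fc2$W[] <- 0
  m$params$head$fc2$b[] <- 0
  expect_equal(unname(predict(m, cm)), matrix(0.5, 3, 3))

  # probability range over many random inputs
  set.seed(99)
  big <- tiny_dataset(n = 100, seed = 99)
  p <- epideep:::predict_dataset(build_network(tiny_spec(), 5), big)
  expect_true(all(p > 0 & p < 1))
})

test_that("ablations are invariant to the discarded input", {
  ds <- tiny_dataset(n = 6, seed = 3)
  ds2 <- ds
  ds2$openness <- matrix(runif(length(ds$openness), 0, 9),
                         nrow = nrow(ds$openness))
  ds3 <- ds
  set.seed(12)
  ds3$codes <- matrix(sample(0:4, length(ds$codes), TRUE),
                      nrow = nrow(ds$codes))

  dna <- build_network(tiny_spec("dna_only"), seed = 2)
  expect_identical(epideep:::predict_dataset(dna, ds),
                   epideep:::predict_dataset(dna, ds2))
  expect_false(identical(epideep:::predict_dataset(dna, ds),
                         epideep:::predict_dataset(dna, ds3)))

  dnase <- build_network(tiny_spec("dnase_only"), seed = 2)
  expect_identical(epideep:::predict_dataset(dnase, ds),
                   epideep:::predict_dataset(dnase, ds3))
  expect_false(identical(epideep:::predict_dataset(dnase, ds),
                         epideep:::predict_dataset(dnase, ds2)))
})

test_that("first-layer kernels are exposed as 4 x kernel_len matrices", {
  m <- build_network(tiny_spec(), seed = 7)
  ks <- first_layer_kernels(m)
  expect_length(ks, 5)
  expect_equal(dim(ks[[1]]), c(4L, 9L))
  expect_equal(rownames(ks[[1]]), c("A", "C", "G", "T"))
  expect_identical(ks, first_layer_kernels(build_network(tiny_spec(), 7)))
  expect_error(first_layer_kernels(build_network(tiny_spec("dnase_only"), 1)),
               class = "epideep_mode")
})

test_that("dense blocks carry both direct and skip connectivity", {
  sp <- tiny_spec()
  m <- build_network(sp, seed = 4)
  # structural: layer 3 of a block sees the block input plus both earlier
  # layers' channels; the block output keeps the input channels (skip path)
  expect_equal(dim(m$params$dna$block1$l3$conv$W)[2],
               sp$init_kernels + 2 * sp$growth)
  expect_equal(length(m$params$dna$trans1$bn$gamma),
               sp$init_kernels + 3 * sp$growth)

  # functional: zeroing the first layer's kernels changes predictions
  # (direct path), yet information still flows to the output (skip path)
  ds <- tiny_dataset(n = 4, seed = 6)
  cm <- epideep:::rows_to_cmat(ds, 1:4)
  p0 <- predict(m, cm)
  m_abl <- m
  m_abl$params$dna$block1$l1$conv$W[] <- 0
  m_abl$params$dna$block1$l1$conv$b[] <- 0
  p1 <- predict(m_abl, cm)
  expect_false(isTRUE(all.equal(p0, p1)))
  # with the first layer ablated, the input one-hot still reaches the output
  ds_alt <- ds
  ds_alt$codes[1, 5] <- (ds$codes[1, 5] + 1L) %% 5L
  expect_false(identical(predict(m_abl, epideep:::rows_to_cmat(ds_alt, 1:4)),
                         p1))
})

test_that("analytic gradients of the reference path match finite differences", {
  set.seed(42)
  sp <- tiny_spec()
  model <- build_network(sp, seed = 7)
  ds <- tiny_dataset(n = 4, seed = 42)
  cm <- epideep:::rows_to_cmat(ds, 1:4)
  labels <- ds$labels

  loss_of <- function(model) {
    fw <- epideep:::net_fwd(model, cm$xseq, cm$xopn, 4, training = TRUE)
    multi_label_loss(epideep:::sigmoid(fw$logits), labels)
  }
  fw <- epideep:::net_fwd(model, cm$xseq, cm$xopn, 4, training = TRUE)
  dlogits <- (epideep:::sigmoid(fw$logits) - labels) / length(labels)
  grads <- epideep:::net_bwd(model, dlogits, fw$caches, 4)

  paths <- list(list("head", "fc1", "W"), list("dna", "conv0", "W"),
                list("dna", "block1", "l2", "conv", "W"),
                list("dna", "block1", "l1", "bn", "gamma"),
                list("dna", "trans1", "conv", "W"),
                list("dnase", "block2", "l3", "conv", "W"),
                list("dna", "bn_final", "beta"))
  for (path in paths) {
    g <- grads
    p <- model$params
    for (k in path) {
      g <- g[[k]]
      p <- p[[k]]
    }
    for (ii in sample(length(p), 2)) {
      eps <- 1e-5
      bump <- function(node, depth, delta) {
        if (depth > length(path)) {
          node[ii] <- node[ii] + delta
          return(node)
        }
        node[[path[[depth]]]] <- bump(node[[path[[depth]]]], depth + 1, delta)
        node
      }
      m_p <- model; m_p$params <- bump(m_p$params, 1, eps)
      m_m <- model; m_m$params <- bump(m_m$params, 1, -eps)
      num <- (loss_of(m_p) - loss_of(m_m)) / (2 * eps)
      expect_equal(g[ii], num, tolerance = 1e-4,
                   label = paste(unlist(path), collapse = "/"))
    }
  }
})

test_that("the compiled engine reproduces the reference forward and backward", {
  set.seed(9)
  sp <- tiny_spec()
  model <- build_network(sp, seed = 21)
  ds <- tiny_dataset(n = 5, seed = 9)
  cm <- epideep:::rows_to_cmat(ds, 1:5)

  fa <- epideep:::net_fwd(model, cm$xseq, cm$xopn, 5, training = TRUE)
  fb <- epideep:::net_fwd_fast(model, cm$xseq, cm$xopn, 5, training = TRUE)
  expect_equal(fb$logits, fa$logits, tolerance = 1e-4)

  dlog <- (epideep:::sigmoid(fa$logits) - ds$labels) / length(ds$labels)
  ga <- epideep:::net_bwd(model, dlog, fa$caches, 5)
  gb <- epideep:::net_bwd_fast(model, dlog, fb$caches, 5)
  cmp <- function(a, b) {
    if (is.list(a)) {
      expect_setequal(names(b), names(a))
      for (nm in names(a)) cmp(a[[nm]], b[[nm]])
    } else {
      expect_equal(max(abs(a - b)) / max(max(abs(a)), 1e-3), 0,
                   tolerance = 1e-3)
    }
  }
  cmp(ga, gb)

  # batchnorm running statistics advance identically
  expect_equal(fb$params$dna$trans1$bn$run_var,
               fa$params$dna$trans1$bn$run_var, tolerance = 1e-5)
  expect_equal(predict(model, cm, engine = "r"),
               predict(model, cm, engine = "cpp"), tolerance = 1e-5)
})

test_that("model summaries and checkpoints work", {
  m <- build_network(tiny_spec(), seed = 1)
  expect_output(print(m), "DNA branch")
  expect_output(print(m), "sigmoid outputs")
  g <- glance(m)
  expect_equal(g$mode, "standard")
  expect_gt(g$n_parameters, 100)

  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(m2$params, m$params)
  expect_equal(m2$spec, m$spec)
})
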