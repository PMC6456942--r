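test_that("multi-label cross entropy matches its closed forms", {
  labels <- matrix(c(1, 0, 1, 1, 0, 0), 2, 3)
  expect_equal(multi_label_loss(matrix(0.5, 2, 3), labels), log(2))
  expect_lt(multi_label_loss(labels, labels), 2e-7)
  expect_equal(multi_label_loss(matrix(0.9), matrix(1)), -log(0.9))
  expect_error(multi_label_loss(matrix(0.5, 2, 2), labels),
               class = "epideep_dimension")
  # non-negative for arbitrary inputs
  set.seed(1)
  for (rep in 1:10) {
    q <- matrix(runif(12), 3, 4)
    p <- matrix(rbinom(12, 1, 0.5), 3, 4)
    expect_gte(multi_label_loss(q, p), 0)
    expect_equal(multi_label_loss(matrix(0.5, 3, 4), p), log(2))
  }
})

test_that("the analytic loss gradient matches numerical differentiation", {
  set.seed(2)
  for (rep in 1:5) {
    pred <- matrix(runif(12, 0.05, 0.95), 3, 4)
    labels <- matrix(rbinom(12, 1, 0.5), 3, 4)
    ana <- multi_label_loss_grad(pred, labels)
    eps <- 1e-6
    for (ii in sample(12, 4)) {
      p1 <- pred; p1[ii] <- p1[ii] + eps
      p2 <- pred; p2[ii] <- p2[ii] - eps
      num <- (multi_label_loss(p1, labels) - multi_label_loss(p2, labels)) /
        (2 * eps)
      expect_equal(ana[ii], num, tolerance = 1e-4)
    }
  }
})

test_that("fold assignment is a near-equal random partition", {
  f <- make_folds(10, 5, seed = 3)
  expect_equal(as.integer(table(f)), rep(2L, 5))
  expect_setequal(unique(f), 0:4)

  f2 <- make_folds(7, 5, seed = 3)
  expect_equal(sort(as.integer(table(f2))), c(1L, 1L, 1L, 2L, 2L))

  expect_identical(make_folds(100, 5, seed = 9), make_folds(100, 5, seed = 9))
  expect_false(identical(make_folds(100, 5, 9), make_folds(100, 5, 10)))
  expect_error(make_folds(3, 5), class = "epideep_config")
})

test_that("chromosome-aware folds keep whole chromosomes together", {
  st <- tibble::tibble(chrom = rep(paste0("chr", 1:4), c(5, 4, 3, 2)))
  f <- make_folds_by_chrom(st, 2)
  expect_true(all(tapply(f, st$chrom, function(x) length(unique(x))) == 1))
  expect_setequal(unique(f), 0:1)
  expect_error(make_folds_by_chrom(st, 5), class = "epideep_config")
})

test_that("training reduces holdout loss on a separable planted problem", {
  # plant a deterministic motif for each marker at the window centre
  set.seed(20)
  n <- 60
  L <- 32
  codes <- matrix(sample(1:4, n * L, TRUE), nrow = n)
  labels <- matrix(0L, n, 3)
  motifs <- list(c(1, 2, 3, 4, 1, 2, 3, 4, 1), rep(4L, 9),
                 c(2, 2, 2, 3, 3, 3, 2, 2, 2))
  for (i in seq_len(n)) {
    m <- (i - 1L) %% 3L + 1L
    codes[i, 12:20] <- motifs[[m]]
    labels[i, m] <- 1L
  }
  ds <- structure(list(codes = codes,
                       openness = matrix(1, n, L),
                       labels = labels, markers = tiny_markers(3),
                       region_bp = L),
                  class = "encoded_dataset")
  model <- build_network(tiny_spec(), seed = 5)
  config <- train_config(batch_size = 16, max_epochs = 8, patience = 8,
                         seed = 5, holdout_fraction = 0.2)
  fit <- train_fold(model, ds, seq_len(n), config)
  log <- fit$training_log
  expect_lt(log$holdout_loss[nrow(log)], log$holdout_loss[1])
  expect_lt(min(log$holdout_loss), log(2))
})

test_that("early stopping stops after the first non-improving epoch at patience 0", {
  ds <- tiny_dataset(n = 20, seed = 4)
  model <- build_network(tiny_spec(), seed = 2)
  config <- train_config(learning_rate = 1e-6, batch_size = 8,
                         max_epochs = 12, patience = 0, seed = 2)
  fit <- train_fold(model, ds, 1:20, config)
  log <- fit$training_log
  # with patience 0, every epoch except possibly the last must improve on
  # the running best, and an early stop means the last one failed to
  best <- cummin(log$holdout_loss)
  if (nrow(log) > 1L) {
    expect_true(all(log$holdout_loss[2:nrow(log) - 1] ==
                      best[2:nrow(log) - 1]))
  }
  if (nrow(log) < config$max_epochs) {
    expect_gte(log$holdout_loss[nrow(log)], best[nrow(log) - 1])
  }
})

test_that("training is deterministic for fixed seeds", {
  ds <- tiny_dataset(n = 24, seed = 6)
  config <- train_config(batch_size = 8, max_epochs = 2, patience = 2,
                         seed = 11)
  f1 <- train_fold(build_network(tiny_spec(), 3), ds, 1:24, config)
  f2 <- train_fold(build_network(tiny_spec(), 3), ds, 1:24, config)
  expect_identical(f1$training_log, f2$training_log)
  expect_identical(f1$params, f2$params)
})

test_that("cross-validation covers every example exactly once", {
  ds <- tiny_dataset(n = 30, seed = 8)
  config <- train_config(batch_size = 8, max_epochs = 1, patience = 1,
                         folds = 3, seed = 13)
  cv <- run_cv(ds, spec = tiny_spec(), config = config)
  expect_s3_class(cv, "epideep_cv")
  expect_false(anyNA(cv$oof))
  expect_equal(dim(cv$oof), c(30L, 3L))
  expect_length(cv$models, 3L)
  expect_equal(sort(as.integer(table(cv$fold_of))), rep(10L, 3))

  # out-of-fold predictions partition by fold: re-predicting fold 0's rows
  # with fold 0's model reproduces the stored rows
  rows <- which(cv$fold_of == 0L)
  expect_equal(cv$oof[rows, ],
               epideep:::predict_dataset(cv$models[[1]], ds, rows),
               tolerance = 1e-6)

  # 2 folds on 10 rows trains on 5 and tests on 5
  ds10 <- tiny_dataset(n = 10, seed = 9)
  cfg2 <- train_config(batch_size = 5, max_epochs = 1, patience = 1,
                       folds = 2, seed = 1, holdout_fraction = 0.2)
  cv2 <- run_cv(ds10, spec = tiny_spec(), config = cfg2)
  expect_equal(as.integer(table(cv2$fold_of)), c(5L, 5L))
})

test_that("degenerate single-class markers are flagged, others evaluated", {
  ds <- tiny_dataset(n = 12, seed = 10)
  ds$labels[, 2] <- 1L   # marker 2 has no negatives
  config <- train_config(batch_size = 6, max_epochs = 1, patience = 1,
                         folds = 2, seed = 3)
  cv <- run_cv(ds, spec = tiny_spec(), config = config)
  m <- cv_metrics(cv)
  expect_false(m$defined[m$marker == "m2"])
  expect_true(is.na(m$auroc[m$marker == "m2"]))
  expect_true(all(m$defined[m$marker != "m2"]))
  g <- glance(cv)
  expect_equal(g$n_examples, 12L)
  expect_equal(g$folds, 2L)
})

test_that("training configuration is validated", {
  expect_error(train_config(learning_rate = 0), class = "epideep_config")
  expect_error(train_config(folds = 1), class = "epideep_config")
  expect_error(train_config(holdout_fraction = 1), class = "epideep_config")
})
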