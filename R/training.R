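#' Training configuration
#'
#' @param learning_rate Adam initial learning rate (default 0.001; all other
#'   Adam parameters at their defaults).
#' @param batch_size Minibatch size (default 64).
#' @param max_epochs Upper bound on training epochs (default 20).
#' @param patience Early stopping: stop after this many consecutive epochs
#'   without holdout-loss improvement (default 5).
#' @param folds Cross-validation folds (default 5).
#' @param seed Master RNG seed for fold split, initialization, holdout split
#'   and batch order.
#' @param holdout_fraction Fraction of the training rows held out inside each
#'   fold to monitor early stopping (default 0.1).
#' @return A validated `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 64L,
                         max_epochs = 20L, patience = 5L, folds = 5L,
                         seed = 1L, holdout_fraction = 0.1) {
  if (learning_rate <= 0) ed_stop("learning_rate must be positive", "config")
  if (folds < 2L) ed_stop("folds must be at least 2", "config")
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    ed_stop("holdout_fraction must be in (0,1)", "config")
  }
  if (patience < 0L) ed_stop("patience must be non-negative", "config")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), folds = as.integer(folds),
                 seed = as.integer(seed),
                 holdout_fraction = holdout_fraction),
            class = "train_config")
}

#' Multi-label binary cross entropy
#'
#' Mean over all n x n_markers entries of
#' `-[p log q + (1-p) log(1-q)]`, with predictions clipped to
#' `[eps, 1-eps]` so the loss stays finite.  Equals `log(2)` at the
#' uninformative prediction 0.5 for any binary label matrix.
#'
#' @param pred Matrix of predicted probabilities in (0,1).
#' @param labels Binary matrix of the same shape.
#' @param eps Clipping constant (default 1e-7).
#' @return Non-negative scalar loss.
#' @export
multi_label_loss <- function(pred, labels, eps = 1e-7) {
  if (!all(dim(pred) == dim(labels))) {
    ed_stop("pred and labels must have identical dimensions", "dimension")
  }
  q <- pmin(pmax(pred, eps), 1 - eps)
  -mean(labels * log(q) + (1 - labels) * log(1 - q))
}

#' Analytic gradient of [multi_label_loss()] with respect to the predictions
#' @inheritParams multi_label_loss
#' @return Matrix of the same shape as `pred`.
#' @export
multi_label_loss_grad <- function(pred, labels, eps = 1e-7) {
  if (!all(dim(pred) == dim(labels))) {
    ed_stop("pred and labels must have identical dimensions", "dimension")
  }
  q <- pmin(pmax(pred, eps), 1 - eps)
  inside <- (pred > eps) & (pred < 1 - eps)
  (-labels / q + (1 - labels) / (1 - q)) * inside / length(pred)
}

#' Partition examples into near-equal random folds
#'
#' @param n Number of examples (must be at least `k`).
#' @param k Number of folds.
#' @param seed RNG seed; the same `(n, k, seed)` always gives the same
#'   assignment.
#' @return Integer vector of length `n` with fold ids in `[0, k)`; fold sizes
#'   differ by at most 1.
#' @export
make_folds <- function(n, k, seed = 1L) {
  if (n < k) ed_stop("need at least as many examples as folds", "config")
  set.seed(seed)
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ids <- rep.int(seq_len(k) - 1L, sizes)
  fold_of <- integer(n)
  fold_of[perm] <- ids
  fold_of
}

#' Chromosome-aware fold assignment
#'
#' Adjacent 200-bp windows share most of their 1000-bp input regions, so a
#' random window-level split can leak information between train and test
#' folds.  This optional splitter assigns whole chromosomes to folds
#' (balancing fold sizes greedily) to avoid that hazard.
#'
#' @param site_table A `site_table`.
#' @param k Number of folds; must not exceed the number of chromosomes.
#' @return Integer vector of fold ids in `[0, k)`, one per row.
#' @export
make_folds_by_chrom <- function(site_table, k) {
  chroms <- table(site_table$chrom)
  if (length(chroms) < k) {
    ed_stop("fewer chromosomes than folds; use make_folds()", "config")
  }
  fold_sizes <- numeric(k)
  fold_of_chrom <- setNames(integer(length(chroms)), names(chroms))
  for (ch in names(sort(chroms, decreasing = TRUE))) {
    f <- which.min(fold_sizes)
    fold_of_chrom[ch] <- f - 1L
    fold_sizes[f] <- fold_sizes[f] + chroms[[ch]]
  }
  unname(fold_of_chrom[site_table$chrom])
}

# One optimization step on a minibatch; returns updated model pieces.
train_step <- function(model, dataset, rows, adam_state, t, lr,
                       engine = "cpp") {
  cm <- rows_to_cmat(dataset, rows)
  fw <- if (engine == "cpp") {
    net_fwd_fast(model, cm$xseq, cm$xopn, cm$n, training = TRUE)
  } else {
    net_fwd(model, cm$xseq, cm$xopn, cm$n, training = TRUE)
  }
  model$params <- fw$params          # batchnorm running stats advanced
  probs <- sigmoid(fw$logits)
  labels <- dataset$labels[rows, , drop = FALSE]
  loss <- multi_label_loss(probs, labels)
  dlogits <- (probs - labels) / length(labels)
  grads <- if (engine == "cpp") {
    net_bwd_fast(model, dlogits, fw$caches, cm$n)
  } else {
    net_bwd(model, dlogits, fw$caches, cm$n)
  }
  up <- adam_step(model$params, grads, adam_state, t, lr)
  model$params <- up$params
  list(model = model, adam_state = up$state, loss = loss)
}

#' Train a model on given rows with Adam and early stopping
#'
#' A fraction of the training rows (`config$holdout_fraction`) is held out to
#' monitor the loss; training stops when the holdout loss has not improved
#' for `config$patience` consecutive epochs or at `config$max_epochs`, and
#' the parameters from the best holdout epoch are returned.
#'
#' @param model An `epideep_model` (freshly built or warm).
#' @param dataset An `encoded_dataset`.
#' @param train_rows Row indices to train on.
#' @param config A [train_config()].
#' @param verbose Emit one log line per epoch.
#' @return The trained model; `model$training_log` holds a tibble with one
#'   row per epoch (`epoch`, `train_loss`, `holdout_loss`, `learning_rate`).
#' @export
train_fold <- function(model, dataset, train_rows, config, verbose = FALSE) {
  if (length(train_rows) == 0L) ed_stop("train_rows is empty", "config")
  set.seed(config$seed)
  n_ho <- max(1L, round(config$holdout_fraction * length(train_rows)))
  ho <- sample(train_rows, n_ho)
  tr <- setdiff(train_rows, ho)
  if (length(tr) == 0L) ed_stop("no rows left after holdout split", "config")

  adam_state <- NULL
  t <- 0L
  best_loss <- Inf
  best_params <- model$params
  stall <- 0L
  history <- list()

  for (epoch in seq_len(config$max_epochs)) {
    order <- sample(tr)
    batches <- split(order, ceiling(seq_along(order) / config$batch_size))
    epoch_loss <- 0
    for (b in batches) {
      t <- t + 1L
      st <- train_step(model, dataset, b, adam_state, t,
                       config$learning_rate)
      model <- st$model
      adam_state <- st$adam_state
      if (!is.finite(st$loss)) {
        ed_stop(sprintf("non-finite training loss at epoch %d", epoch),
                "training")
      }
      epoch_loss <- epoch_loss + st$loss * length(b)
    }
    epoch_loss <- epoch_loss / length(order)
    ho_pred <- predict_dataset(model, dataset, ho)
    ho_loss <- multi_label_loss(ho_pred, dataset$labels[ho, , drop = FALSE])
    if (!is.finite(ho_loss)) {
      ed_stop(sprintf("non-finite holdout loss at epoch %d", epoch),
              "training")
    }
    history[[epoch]] <- tibble(epoch = epoch, train_loss = epoch_loss,
                               holdout_loss = ho_loss,
                               learning_rate = config$learning_rate)
    if (verbose) {
      message(sprintf("epoch %d  train %.4f  holdout %.4f", epoch, epoch_loss,
                      ho_loss))
    }
    if (ho_loss < best_loss) {
      best_loss <- ho_loss
      best_params <- model$params
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall > config$patience) break
    }
  }
  model$params <- best_params
  model$training_log <- dplyr::bind_rows(history)
  model
}

#' Run k-fold cross-validation over a site table
#'
#' All sites are partitioned into `config$folds` near-equal parts; each fold
#' trains a model on the remaining parts and predicts the held-out part, so
#' every example receives exactly one out-of-fold prediction.  The per-fold
#' models are retained for cross-epigenome collective scoring.
#'
#' @param site_table A `site_table`, or an `encoded_dataset` (in which case
#'   `genome` and `track` are ignored).
#' @param genome Genome handle (see [read_genome()]).
#' @param track DNase peak tibble.
#' @param spec A [network_spec()].
#' @param config A [train_config()].
#' @param fold_of Optional precomputed fold assignment (e.g. from
#'   [make_folds_by_chrom()]); defaults to [make_folds()].
#' @param verbose Emit per-epoch log lines.
#' @return An `epideep_cv`: list with `models` (one per fold), `oof`
#'   (n x n_markers out-of-fold probability matrix), `fold_of`, `labels`,
#'   `markers`, `epigenome_id`, `spec`, `config`.
#' @export
run_cv <- function(site_table, genome = NULL, track = NULL, spec, config,
                   fold_of = NULL, verbose = FALSE) {
  dataset <- if (inherits(site_table, "encoded_dataset")) {
    site_table
  } else {
    encode_dataset(genome, track, site_table, region_bp = spec$seq_len)
  }
  n <- nrow(dataset$codes)
  if (is.null(fold_of)) fold_of <- make_folds(n, config$folds, config$seed)
  oof <- matrix(NA_real_, nrow = n, ncol = spec$n_markers)
  colnames(oof) <- dataset$markers
  models <- vector("list", config$folds)
  for (f in seq_len(config$folds) - 1L) {
    test_rows <- which(fold_of == f)
    train_rows <- which(fold_of != f)
    fold_seed <- config$seed + 1009L * (f + 1L)
    model <- build_network(spec, seed = fold_seed)
    fold_config <- config
    fold_config$seed <- fold_seed
    if (verbose) message(sprintf("fold %d: training on %d rows", f,
                                 length(train_rows)))
    model <- train_fold(model, dataset, train_rows, fold_config,
                        verbose = verbose)
    models[[f + 1L]] <- model
    oof[test_rows, ] <- predict_dataset(model, dataset, test_rows)
  }
  structure(list(models = models, oof = oof, fold_of = fold_of,
                 labels = dataset$labels, markers = dataset$markers,
                 epigenome_id = dataset$epigenome_id, spec = spec,
                 config = config),
            class = "epideep_cv")
}
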