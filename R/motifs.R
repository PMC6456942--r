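#' Motif extraction configuration
#'
#' @param alpha Activation threshold coefficient in (0,1): a window is
#'   activated when its convolution activation reaches `alpha` times the
#'   sequence's extreme activation value (default 0.9).
#' @param kernel_len Kernel length (default 9).
#' @param min_activations Minimum number of activated windows for a kernel to
#'   yield a motif rather than a skip signal (default 10).
#' @return A validated `motif_config` list.
#' @export
motif_config <- function(alpha = 0.9, kernel_len = 9L, min_activations = 10L) {
  if (alpha <= 0 || alpha >= 1) ed_stop("alpha must be in (0,1)", "config")
  if (min_activations < 1L) ed_stop("min_activations must be >= 1", "config")
  structure(list(alpha = alpha, kernel_len = as.integer(kernel_len),
                 min_activations = as.integer(min_activations)),
            class = "motif_config")
}

# activations of one kernel (4 x k) over all length-k windows of a one-hot
# sequence (4 x L): a[j] = sum(W * X[, j:(j+k-1)])
kernel_activations <- function(kernel_weights, seq_onehot) {
  k <- ncol(kernel_weights)
  L <- ncol(seq_onehot)
  if (L < k) ed_stop(sprintf("sequence length %d < kernel length %d", L, k),
                     "length")
  W <- array(kernel_weights, dim = c(1L, 4L, k))
  acts <- cpp_conv1d_fwd(seq_onehot, W, 0, 1L, L)
  p <- (k - 1L) %/% 2L
  # centre positions of the same-padded output are the padding-free windows
  acts[1, (p + 1L):(L - p)]
}

#' Extreme activation value of a kernel over one sequence
#'
#' The maximum convolution activation of the kernel over all padding-free
#' length-k windows of the sequence.
#'
#' @param kernel_weights 4 x kernel_len weight matrix (rows A,C,G,T).
#' @param seq_onehot 4 x L one-hot sequence matrix, `L >= kernel_len`.
#' @return The maximum window activation (a scalar).
#' @export
kernel_eav <- function(kernel_weights, seq_onehot) {
  max(kernel_activations(kernel_weights, seq_onehot))
}

#' Extract a position frequency matrix from one kernel
#'
#' For every sequence, windows whose activation reaches `alpha` times that
#' sequence's extreme activation value (EAV) are collected; the PFM is the
#' element-wise mean of the collected one-hot windows.  Sequences whose EAV
#' is not positive contribute nothing (a non-positive maximum would make the
#' threshold admit arbitrarily weak windows).  Returns `NULL` (skip signal)
#' when fewer than `config$min_activations` windows activate in total.
#'
#' @param kernel_weights 4 x kernel_len weight matrix.
#' @param sequences List of one-hot sequence matrices (each 4 x L, L >=
#'   kernel_len).
#' @param config A [motif_config()].
#' @param kernel_index Index recorded on the result.
#' @return A `kernel_motif` (list with `kernel_index`, `pfm`,
#'   `n_activations`, `n_sequences_scanned`) or `NULL`.
#' @export
extract_pwm <- function(kernel_weights, sequences, config = motif_config(),
                        kernel_index = NA_integer_) {
  if (length(sequences) == 0L) ed_stop("no sequences supplied", "config")
  k <- config$kernel_len
  acc <- matrix(0, nrow = 4L, ncol = k)
  n_act <- 0L
  for (s in sequences) {
    acts <- kernel_activations(kernel_weights, s)
    eav <- max(acts)
    if (eav <= 0) next
    hits <- which(acts >= config$alpha * eav)
    for (j in hits) {
      acc <- acc + s[, j:(j + k - 1L), drop = FALSE]
    }
    n_act <- n_act + length(hits)
  }
  if (n_act < config$min_activations) return(NULL)
  pfm <- acc / n_act
  rownames(pfm) <- c("A", "C", "G", "T")
  structure(list(kernel_index = kernel_index, pfm = pfm,
                 n_activations = n_act,
                 n_sequences_scanned = length(sequences)),
            class = "kernel_motif")
}

#' Extract motifs from all first-layer DNA kernels of a model
#'
#' Applies the activation rule of [extract_pwm()] to every first-layer
#' kernel over a sample of input sequences; one forward convolution per
#' sequence scores all kernels at once.
#'
#' @param model An `epideep_model` with a DNA branch.
#' @param sequences List of one-hot matrices, or an `encoded_dataset` (then
#'   `rows` selects the sample).
#' @param config A [motif_config()].
#' @param rows Rows to scan when `sequences` is an `encoded_dataset`.
#' @return List of `kernel_motif` objects (kernels below the activation
#'   minimum are omitted).  Deterministic for a fixed sample.
#' @export
extract_all_motifs <- function(model, sequences, config = motif_config(),
                               rows = NULL) {
  kernels <- first_layer_kernels(model)
  if (inherits(sequences, "encoded_dataset")) {
    if (is.null(rows)) rows <- seq_len(nrow(sequences$codes))
    return(extract_all_motifs_batched(kernels, sequences, rows, config))
  }
  if (length(sequences) == 0L) ed_stop("no sequences supplied", "config")
  K <- length(kernels)
  k <- config$kernel_len
  Wcube <- array(0, dim = c(K, 4L, k))
  for (i in seq_len(K)) Wcube[i, , ] <- kernels[[i]]
  acc <- lapply(seq_len(K), function(i) matrix(0, 4L, k))
  n_act <- integer(K)
  p <- (k - 1L) %/% 2L
  for (s in sequences) {
    L <- ncol(s)
    acts <- cpp_conv1d_fwd(s, Wcube, numeric(K), 1L, L)[, (p + 1L):(L - p),
                                                        drop = FALSE]
    eav <- apply(acts, 1L, max)
    for (i in which(eav > 0)) {
      hits <- which(acts[i, ] >= config$alpha * eav[i])
      for (j in hits) acc[[i]] <- acc[[i]] + s[, j:(j + k - 1L), drop = FALSE]
      n_act[i] <- n_act[i] + length(hits)
    }
  }
  out <- list()
  for (i in seq_len(K)) {
    if (n_act[i] < config$min_activations) next
    pfm <- acc[[i]] / n_act[i]
    rownames(pfm) <- c("A", "C", "G", "T")
    out[[length(out) + 1L]] <- structure(
      list(kernel_index = i, pfm = pfm, n_activations = n_act[i],
           n_sequences_scanned = length(sequences)),
      class = "kernel_motif")
  }
  out
}

# Batched extraction over an encoded dataset: one convolution per chunk of
# sequences scores all kernels at once, and activated windows are
# accumulated by tabulating sequence codes.  Semantically identical to the
# per-sequence path (same EAV, threshold and averaging rules).
extract_all_motifs_batched <- function(kernels, ds, rows, config,
                                       chunk = 256L) {
  if (length(rows) == 0L) ed_stop("no sequences supplied", "config")
  K <- length(kernels)
  k <- config$kernel_len
  p <- (k - 1L) %/% 2L
  L <- ds$region_bp
  n_win <- L - k + 1L
  Wcube <- array(0, dim = c(K, 4L, k))
  for (i in seq_len(K)) Wcube[i, , ] <- kernels[[i]]
  acc <- lapply(seq_len(K), function(i) matrix(0, 4L, k))
  n_act <- integer(K)

  for (ck in split(rows, ceiling(seq_along(rows) / chunk))) {
    n <- length(ck)
    codes <- ds$codes[ck, , drop = FALSE]
    v <- as.vector(t(codes))
    xseq <- matrix(0, nrow = 4L, ncol = n * L)
    nz <- which(v > 0L)
    xseq[cbind(v[nz], nz)] <- 1
    acts <- cpp_conv1d_fwd(xseq, Wcube, numeric(K), n, L)
    for (i in seq_len(K)) {
      # padding-free windows: centre positions of the same-padded output
      a <- matrix(acts[i, ], nrow = L)[(p + 1L):(L - p), , drop = FALSE]
      eav <- a[1, ]
      for (r in 2:n_win) eav <- pmax(eav, a[r, ])
      ok <- eav > 0
      if (!any(ok)) next
      hits <- which(a >= rep(config$alpha * eav, each = n_win) &
                      rep(ok, each = n_win), arr.ind = TRUE)
      if (nrow(hits) == 0L) next
      for (off in seq_len(k)) {
        b <- codes[cbind(hits[, 2L], hits[, 1L] + off - 1L)]
        acc[[i]][, off] <- acc[[i]][, off] + tabulate(b, nbins = 4L)
      }
      n_act[i] <- n_act[i] + nrow(hits)
    }
  }
  out <- list()
  for (i in seq_len(K)) {
    if (n_act[i] < config$min_activations) next
    pfm <- acc[[i]] / n_act[i]
    rownames(pfm) <- c("A", "C", "G", "T")
    out[[length(out) + 1L]] <- structure(
      list(kernel_index = i, pfm = pfm, n_activations = n_act[i],
           n_sequences_scanned = length(rows)),
      class = "kernel_motif")
  }
  out
}

#' Summarise extracted motifs as a tibble
#'
#' @param motifs List of `kernel_motif` objects.
#' @return Tibble with `kernel_index`, `n_activations`,
#'   `n_sequences_scanned`, `information_content` (total bits, uniform
#'   background) and `consensus`.
#' @export
motif_summary <- function(motifs) {
  rows <- lapply(motifs, function(m) {
    pfm <- pmax(m$pfm, 1e-9)
    ic <- sum(pfm * log2(pfm / 0.25))
    tibble(kernel_index = m$kernel_index, n_activations = m$n_activations,
           n_sequences_scanned = m$n_sequences_scanned,
           information_content = ic,
           consensus = paste0(rownames(m$pfm)[apply(m$pfm, 2, which.max)],
                              collapse = ""))
  })
  dplyr::bind_rows(rows)
}

#' @export
print.kernel_motif <- function(x, ...) {
  cat(sprintf("<kernel_motif> kernel %s, %d activated windows over %d sequences\n",
              x$kernel_index, x$n_activations, x$n_sequences_scanned))
  print(round(x$pfm, 3))
  invisible(x)
}

#' Plot a motif PFM as a per-position stacked probability chart
#'
#' @param object A `kernel_motif`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kernel_motif
#' @export
autoplot.kernel_motif <- function(object, ...) {
  df <- as.data.frame(object$pfm)
  names(df) <- seq_len(ncol(object$pfm))
  df$base <- rownames(object$pfm)
  long <- tidyr::pivot_longer(df, -"base", names_to = "position",
                              values_to = "probability")
  long$position <- as.integer(long$position)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position,
                                     y = .data$probability,
                                     fill = .data$base)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::scale_x_continuous(breaks = seq_len(ncol(object$pfm))) +
    ggplot2::labs(x = "position", y = "probability",
                  title = sprintf("kernel %s (%d activations)",
                                  object$kernel_index,
                                  object$n_activations)) +
    ggplot2::theme_minimal()
}
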