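# Shared fixtures and independent oracles used across the test files.

tiny_markers <- function(k = 3) paste0("m", seq_len(k))

# a small random encoded dataset (no genome needed) for network/training tests
tiny_dataset <- function(n = 12, L = 32, n_markers = 3, seed = 1) {
  set.seed(seed)
  structure(list(
    codes = matrix(sample(0:4, n * L, replace = TRUE), nrow = n),
    openness = matrix(runif(n * L, 0, 5), nrow = n),
    labels = matrix(rbinom(n * n_markers, 1, 0.5), nrow = n),
    markers = tiny_markers(n_markers),
    region_bp = as.integer(L)),
    class = "encoded_dataset")
}

# init_gain = 1 keeps weights at ordinary He scale so finite-difference and
# float32 comparisons in the math tests stay well conditioned
tiny_spec <- function(mode = "standard", n_markers = 3) {
  network_spec(mode = mode, seq_len = 32, n_markers = n_markers,
               init_kernels = 5, kernel_len = 9, growth = 2,
               head_hidden = 6, init_gain = 1)
}

# a small genome as a named character vector
tiny_genome <- function() {
  c(chr1 = "ACGTACGTACGTACGTACGTACGTACGTACGT",
    chr2 = "TTTTGGGGCCCCAAAATTTTGGGGCCCCAAAA")
}

# brute-force window-calling oracle: per-base membership in the peak union
oracle_call_sites <- function(peaks, chrom_sizes, window_bp = 200,
                              step_bp = 200, min_overlap_bp = 100) {
  out <- list()
  for (chrom in sort(names(chrom_sizes))) {
    len <- chrom_sizes[[chrom]]
    covered <- logical(len)
    p <- peaks[peaks$chrom == chrom, , drop = FALSE]
    if (nrow(p) > 0) {
      for (i in seq_len(nrow(p))) {
        covered[(p$start[i] + 1):min(p$end[i], len)] <- TRUE
      }
    }
    starts <- seq(0, len - window_bp, by = step_bp)
    for (s in starts) {
      if (sum(covered[(s + 1):(s + window_bp)]) >= min_overlap_bp) {
        out[[length(out) + 1]] <- data.frame(chrom = chrom,
                                             start = as.integer(s),
                                             end = as.integer(s + window_bp))
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  tibble::as_tibble(do.call(rbind, out))
}

# exhaustive pairwise-concordance oracle for auROC (ties count 1/2)
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# direct precision/recall enumeration oracle for average precision
oracle_auprc <- function(scores, labels) {
  np <- sum(labels == 1)
  ts <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  ap <- 0
  for (t in ts) {
    sel <- scores >= t
    precision <- sum(labels[sel] == 1) / sum(sel)
    recall <- sum(labels[sel] == 1) / np
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# exhaustive window-scan oracle for the extreme activation value
oracle_eav <- function(kernel_weights, seq_onehot) {
  k <- ncol(kernel_weights)
  L <- ncol(seq_onehot)
  max(vapply(seq_len(L - k + 1), function(j) {
    sum(kernel_weights * seq_onehot[, j:(j + k - 1)])
  }, numeric(1)))
}

onehot <- function(seq) encode_sequence(seq)

random_onehot <- function(L) {
  m <- matrix(0, 4, L)
  idx <- sample(1:4, L, replace = TRUE)
  m[cbind(idx, seq_len(L))] <- 1
  m
}
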