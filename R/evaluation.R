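#' One-vs-rest labels for a marker
#'
#' Positives are the rows labelled for the marker; negatives are all other
#' rows of the site table — i.e. modification sites of the other markers that
#' are not sites of this one.  Negatives are never random genome windows;
#' this is the stringent negative semantics the evaluation uses throughout.
#'
#' @param site_table A `site_table`.
#' @param marker Marker name.
#' @return Integer 0/1 vector over all rows.
#' @export
one_vs_rest_labels <- function(site_table, marker) {
  markers <- attr(site_table, "markers")
  if (!marker %in% markers) {
    ed_stop(paste0("unknown marker: ", marker), "config")
  }
  as.integer(site_table[[marker]])
}

#' Area under the ROC curve
#'
#' Computed as the rank (concordance) statistic: the probability that a
#' random positive outranks a random negative, with ties counted 1/2.
#'
#' @param scores Numeric score vector.
#' @param labels Binary label vector of the same length.
#' @return auROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0 || nn == 0) {
    ed_stop("auROC undefined: both classes must be present", "metric")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve (average precision)
#'
#' Computed by the step summation `sum (R_t - R_{t-1}) * P_t` over the
#' distinct score thresholds in decreasing order (the average-precision
#' form, without interpolation).
#'
#' @inheritParams auroc
#' @return auPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  np <- sum(labels == 1)
  if (np == 0) ed_stop("auPRC undefined: no positives", "metric")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  tp <- cumsum(l == 1)
  k <- seq_along(s)
  # evaluate precision/recall only where the threshold actually drops
  at <- which(c(s[-1] != s[-length(s)], TRUE))
  precision <- tp[at] / k[at]
  recall <- tp[at] / np
  sum(diff(c(0, recall)) * precision)
}

#' Exact one-sided paired sign test
#'
#' For `n` paired comparisons with `wins` successes (ties removed before
#' calling, with `n` reduced accordingly), returns the exact binomial tail
#' probability `P(X >= wins)` for `X ~ Binomial(n, 1/2)` — the one-sided
#' paired-sample binomial exact test used to compare methods across
#' epigenomes.
#'
#' @param wins Number of pairs where the first method scored higher.
#' @param n Number of non-tied pairs.
#' @return One-sided tail probability.
#' @export
paired_sign_test <- function(wins, n) {
  if (n < 1) ed_stop("sign test undefined for n = 0", "metric")
  if (wins < 0 || wins > n) ed_stop("need 0 <= wins <= n", "metric")
  sum(choose(n, wins:n)) / 2^n
}

#' One-sided Wilcoxon rank-sum test ("x stochastically greater than y")
#'
#' For small samples (`min(m, n) <= 10` and `m + n <= 20`) the tail
#' probability is computed by exhaustive enumeration of all `choose(m+n, m)`
#' rank assignments (average ranks for ties): `P(W >= W_obs)`.  Otherwise a
#' normal approximation with tie-corrected variance and continuity correction
#' is used.
#'
#' @param x,y Non-empty numeric vectors.
#' @return One-sided tail probability for the alternative "x greater".
#' @export
wilcoxon_rank_sum_one_sided <- function(x, y) {
  m <- length(x)
  n <- length(y)
  if (m == 0 || n == 0) ed_stop("both samples must be non-empty", "metric")
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)])
  if (min(m, n) <= 10 && m + n <= 20) {
    combos <- utils::combn(m + n, m)
    w_all <- colSums(matrix(r[combos], nrow = m))
    return(mean(w_all >= w_obs - 1e-9))
  }
  u <- w_obs - m * (m + 1) / 2
  mu <- m * n / 2
  tie_counts <- table(pooled)
  tie_term <- sum(tie_counts^3 - tie_counts) / ((m + n) * (m + n - 1))
  sigma2 <- m * n / 12 * ((m + n + 1) - tie_term)
  z <- (u - mu - 0.5) / sqrt(sigma2)
  pnorm(z, lower.tail = FALSE)
}

#' Per-marker one-vs-rest metrics for a cross-validation result
#'
#' @param cv An `epideep_cv` from [run_cv()], or a list with `oof` score
#'   matrix and `labels` matrix (columns = markers).
#' @param epigenome_id Optional id recorded in the output.
#' @return Tibble with `epigenome`, `marker`, `n_pos`, `n_neg`, `auroc`,
#'   `auprc`, `defined`.  Markers with a degenerate one-vs-rest class
#'   (no positives or no negatives) are flagged `defined = FALSE` with `NA`
#'   metrics.
#' @export
cv_metrics <- function(cv, epigenome_id = NULL) {
  markers <- colnames(cv$labels)
  if (is.null(markers)) markers <- colnames(cv$oof)
  epi <- epigenome_id %||% cv$epigenome_id %||% NA_character_
  rows <- lapply(seq_along(markers), function(j) {
    lab <- cv$labels[, j]
    np <- sum(lab == 1)
    nn <- sum(lab == 0)
    ok <- np > 0 && nn > 0
    tibble(epigenome = epi, marker = markers[j], n_pos = np, n_neg = nn,
           auroc = if (ok) auroc(cv$oof[, j], lab) else NA_real_,
           auprc = if (ok) auprc(cv$oof[, j], lab) else NA_real_,
           defined = ok)
  })
  dplyr::bind_rows(rows)
}

#' Compare two methods' per-epigenome metrics with the exact sign test
#'
#' Joins the two metric tables on (epigenome, marker), counts per marker how
#' often method A beats method B (exact ties dropped, n reduced), and reports
#' the one-sided exact sign-test tail probability per marker.
#'
#' @param metrics_a,metrics_b Tibbles as returned by [cv_metrics()].
#' @param metric Which column to compare (default `"auroc"`).
#' @return Tibble with `marker`, `wins`, `n`, `p_value`.
#' @export
compare_methods <- function(metrics_a, metrics_b, metric = "auroc") {
  joined <- dplyr::inner_join(
    metrics_a[, c("epigenome", "marker", metric)],
    metrics_b[, c("epigenome", "marker", metric)],
    by = c("epigenome", "marker"), suffix = c("_a", "_b"))
  a <- joined[[paste0(metric, "_a")]]
  b <- joined[[paste0(metric, "_b")]]
  joined <- joined[!is.na(a) & !is.na(b) & a != b, ]
  out <- joined |>
    dplyr::group_by(.data$marker) |>
    dplyr::summarise(
      wins = sum(.data[[paste0(metric, "_a")]] >
                   .data[[paste0(metric, "_b")]]),
      n = dplyr::n(), .groups = "drop")
  out$p_value <- mapply(paired_sign_test, out$wins, out$n)
  out
}

#' Collective cross-epigenome prediction
#'
#' Predicts a novel epigenome by averaging: for each known epigenome, the
#' mean probability over its cross-validation fold models; then the
#' unweighted mean over the known epigenomes.  The input batch carries the
#' region's DNA sequence together with the novel epigenome's own chromatin
#' accessibility track.
#'
#' @param ensembles List with one element per known epigenome: either an
#'   `epideep_cv` or a list of `epideep_model` fold models.
#' @param batch `encoded_batch` (or cmat list) built from the novel
#'   epigenome's openness data.
#' @return n x n_markers matrix of averaged probabilities.
#' @export
collective_predict <- function(ensembles, batch) {
  if (length(ensembles) == 0L) ed_stop("no known epigenomes supplied", "config")
  cm <- if (inherits(batch, "encoded_batch")) batch_to_cmat(batch) else batch
  per_epi <- lapply(ensembles, function(e) {
    models <- if (inherits(e, "epideep_cv")) e$models else e
    if (length(models) == 0L) ed_stop("empty model ensemble", "config")
    preds <- lapply(models, function(m) predict(m, cm))
    Reduce(`+`, preds) / length(preds)
  })
  Reduce(`+`, per_epi) / length(per_epi)
}

#' Write a per-marker metrics report as TSV
#' @param metrics Tibble from [cv_metrics()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.table(metrics, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
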