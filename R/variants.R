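#' Score variants by predicted change in marker probability
#'
#' For each SNP, the 1000-bp sequence centred at the variant position is
#' predicted twice — with the reference and with the alternate base — and the
#' functional implication score is `delta_p = |p_alt - p_ref|`.  The same
#' openness vector is used for both alleles: the substitution edits the
#' sequence, not the accessibility assay.
#'
#' @param scorer An `epideep_model`, a list of models (fold ensemble,
#'   averaged), or an `epideep_cv` (its fold models are averaged — the inner
#'   level of collective scoring).
#' @param genome Genome handle; the base at each variant position must equal
#'   the stated `ref` allele.
#' @param track DNase peak tibble for the scored epigenome.
#' @param variants Tibble with `chrom`, `pos` (0-based), `ref`, `alt`.
#' @param marker Marker name(s) to report; default all model outputs.
#' @param markers Marker order of the model outputs (default: the 7 standard
#'   histone markers).
#' @param region_bp Window length (default 1000; the SNP sits at offset
#'   `region_bp/2`, 0-based, of the window).
#' @return Tibble with one row per variant x marker: `chrom`, `pos`, `ref`,
#'   `alt`, `marker`, `p_ref`, `p_alt`, `delta_p`.
#' @export
score_variants <- function(scorer, genome, track, variants, marker = NULL,
                           markers = default_markers(), region_bp = 1000L) {
  models <- scorer_models(scorer)
  nv <- nrow(variants)
  if (nv == 0L) ed_stop("no variants supplied", "config")
  half <- region_bp %/% 2L
  L <- region_bp
  xref <- matrix(0, nrow = 4L, ncol = nv * L)
  xalt <- matrix(0, nrow = 4L, ncol = nv * L)
  xopn <- matrix(0, nrow = 1L, ncol = nv * L)
  for (i in seq_len(nv)) {
    v <- variants[i, ]
    start <- v$pos - half
    seq <- fetch_sequence(genome, v$chrom, start, start + L)
    at <- half + 1L
    gbase <- substr(seq, at, at)
    if (gbase != toupper(v$ref)) {
      ed_stop(sprintf("variant %s:%d: genome base is %s, not ref %s",
                      v$chrom, v$pos, gbase, v$ref), "ref_mismatch")
    }
    cols <- (i - 1L) * L + seq_len(L)
    codes <- seq_codes(seq)
    nz <- which(codes > 0L)
    xref[cbind(codes[nz], cols[nz])] <- 1
    alt_codes <- codes
    alt_codes[at] <- match(toupper(v$alt), c("A", "C", "G", "T"))
    nz <- which(alt_codes > 0L)
    xalt[cbind(alt_codes[nz], cols[nz])] <- 1
    xopn[1L, cols] <- encode_openness(track, list(chrom = v$chrom,
                                                  start = start,
                                                  end = start + L))
  }
  ens_predict <- function(xseq) {
    preds <- lapply(models, function(m) {
      predict(m, list(xseq = xseq, xopn = xopn, n = nv))
    })
    Reduce(`+`, preds) / length(preds)
  }
  p_ref <- ens_predict(xref)
  p_alt <- ens_predict(xalt)
  colnames(p_ref) <- colnames(p_alt) <- markers[seq_len(ncol(p_ref))]
  use <- marker %||% colnames(p_ref)
  if (!all(use %in% colnames(p_ref))) {
    ed_stop("requested marker not among the model outputs", "config")
  }
  out <- lapply(use, function(m) {
    pr <- unname(p_ref[, m])
    pa <- unname(p_alt[, m])
    tibble(chrom = variants$chrom, pos = variants$pos, ref = variants$ref,
           alt = variants$alt, marker = m, p_ref = pr, p_alt = pa,
           delta_p = abs(pa - pr))
  })
  dplyr::bind_rows(out)
}

scorer_models <- function(scorer) {
  if (inherits(scorer, "epideep_model")) return(list(scorer))
  if (inherits(scorer, "epideep_cv")) return(scorer$models)
  if (is.list(scorer) && length(scorer) > 0L &&
        all(vapply(scorer, inherits, logical(1), "epideep_model"))) {
    return(scorer)
  }
  ed_stop("scorer must be a model, a list of models, or a CV result", "config")
}

#' Build a distance-matched control variant set
#'
#' For each positive SNP, selects the not-yet-used candidate on the same
#' chromosome whose distance to the positive is closest to
#' `target_distance_bp` and within `tolerance_bp` of it.  Matching is without
#' replacement, in positive order; positives with no admissible candidate are
#' dropped from both sets so the two sets stay equal-sized.
#'
#' @param positives,candidates Variant tibbles (`chrom`, `pos`, `ref`,
#'   `alt`); candidates must be disjoint from positives.
#' @param target_distance_bp Desired positive-to-control distance (e.g. 500,
#'   1000, 1500, 2000, 2500).
#' @param tolerance_bp Admissible deviation from the target (default 250).
#' @return List with `positives` and `controls`, equal-length tibbles in
#'   surviving-positive order.
#' @export
build_control_set <- function(positives, candidates, target_distance_bp,
                              tolerance_bp = 250L) {
  if (nrow(candidates) == 0L) ed_stop("empty candidate list", "config")
  used <- logical(nrow(candidates))
  keep_pos <- integer(0)
  keep_ctrl <- integer(0)
  for (i in seq_len(nrow(positives))) {
    ok <- which(!used & candidates$chrom == positives$chrom[i])
    if (length(ok) == 0L) next
    d <- abs(abs(candidates$pos[ok] - positives$pos[i]) - target_distance_bp)
    j <- ok[which.min(d)]
    if (min(d) > tolerance_bp) next
    used[j] <- TRUE
    keep_pos <- c(keep_pos, i)
    keep_ctrl <- c(keep_ctrl, j)
  }
  list(positives = positives[keep_pos, , drop = FALSE],
       controls = candidates[keep_ctrl, , drop = FALSE])
}

#' Compare functional implication scores of two variant sets
#'
#' Tests whether the positive set's scores are stochastically greater than
#' the control set's with the one-sided Wilcoxon rank-sum test
#' ([wilcoxon_rank_sum_one_sided()]).
#'
#' @param pos_scores,neg_scores Numeric score vectors (e.g. `delta_p`).
#' @return An `epideep_score_comparison`: list with `p_value`, `median_pos`,
#'   `median_neg`, `n_pos`, `n_neg`.
#' @export
compare_scores <- function(pos_scores, neg_scores) {
  p <- wilcoxon_rank_sum_one_sided(pos_scores, neg_scores)
  structure(list(p_value = p, median_pos = median(pos_scores),
                 median_neg = median(neg_scores), n_pos = length(pos_scores),
                 n_neg = length(neg_scores)),
            class = "epideep_score_comparison")
}

#' @export
print.epideep_score_comparison <- function(x, ...) {
  cat(sprintf(
    "score comparison: median %.4g (n=%d) vs %.4g (n=%d); one-sided rank-sum p = %.4g\n",
    x$median_pos, x$n_pos, x$median_neg, x$n_neg, x$p_value))
  invisible(x)
}

#' @method tidy epideep_score_comparison
#' @export
tidy.epideep_score_comparison <- function(x, ...) {
  tibble(median_pos = x$median_pos, median_neg = x$median_neg,
         n_pos = x$n_pos, n_neg = x$n_neg, p_value = x$p_value)
}

#' The seven histone markers modelled by default
#' @return Character vector of marker names.
#' @export
default_markers <- function() {
  c("H3K4me1", "H3K4me3", "H3K27me3", "H3K36me3", "H3K9me3", "H3K9ac",
    "H3K27ac")
}
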