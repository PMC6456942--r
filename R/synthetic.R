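#' Built-in planted motif PFMs for the synthetic generator
#'
#' One 9-column position frequency matrix per marker, each an
#' information-rich motif around a fixed distinct consensus: the consensus
#' base carries probability 0.85 (0.97 at the centre column, making the
#' centre the unambiguous maximum-information position for variant
#' placement), the other bases share the remainder.
#'
#' @param markers Marker names (default the 7 standard markers).
#' @return Named list of 4 x 9 column-stochastic matrices (rows A,C,G,T).
#' @export
default_motif_pfms <- function(markers = default_markers()) {
  consensus <- c("TGACTCAGC", "CACGTGTAC", "AGGTCATTG", "CCGGAAGTG",
                 "AGATAAGCG", "ATGCAAATC", "TTGACGTCA")
  stopifnot(length(markers) <= length(consensus))
  bases <- c("A", "C", "G", "T")
  out <- lapply(seq_along(markers), function(i) {
    cs <- strsplit(consensus[i], "")[[1]]
    pfm <- matrix(0, nrow = 4L, ncol = length(cs),
                  dimnames = list(bases, NULL))
    for (j in seq_along(cs)) {
      p <- if (j == (length(cs) + 1L) %/% 2L) 0.97 else 0.85
      pfm[, j] <- (1 - p) / 3
      pfm[cs[j], j] <- p
    }
    pfm
  })
  setNames(out, markers)
}

#' Configuration of the synthetic fixture generator
#'
#' The generator emulates the statistical structure the predictor assumes:
#' marker-specific sequence signatures planted at modification sites, and
#' chromatin accessibility elevated at sites (identically for all markers, so
#' accessibility alone cannot distinguish among markers).  Background is
#' i.i.d. sequence at a human-like GC fraction.
#'
#' @param seed Master seed; each generation step derives its own stream.
#' @param n_chroms,chrom_len_bp Genome shape (default 4 x 1 Mb).
#' @param markers Marker names (7).
#' @param motif_pfms Per-marker planted PFMs (default
#'   [default_motif_pfms()]).
#' @param sites_per_marker Planted sites per marker (default 2000).
#' @param peak_len_bp Emitted peak length (default 200, the window size, so
#'   called sites reproduce the planted truth exactly).
#' @param background_gc Background GC fraction (default 0.41).
#' @param dnase_fold_at_sites DNase fold enrichment over true sites
#'   (default 5).
#' @param dnase_fold_background Fold enrichment of optional background peaks
#'   (default 0 = none).
#' @param motif_insertion_prob Probability a planted site actually receives a
#'   motif instance (default 1).
#' @param window_bp Scanning-grid window (default 200).
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L, n_chroms = 4L, chrom_len_bp = 1000000L,
                             markers = default_markers(),
                             motif_pfms = default_motif_pfms(markers),
                             sites_per_marker = 2000L, peak_len_bp = 200L,
                             background_gc = 0.41, dnase_fold_at_sites = 5,
                             dnase_fold_background = 0,
                             motif_insertion_prob = 1, window_bp = 200L) {
  if (peak_len_bp < window_bp) {
    ed_stop("peak_len_bp must be at least the window size", "config")
  }
  if (background_gc < 0 || background_gc > 1) {
    ed_stop("background_gc must be in [0,1]", "config")
  }
  if (motif_insertion_prob <= 0 || motif_insertion_prob > 1) {
    ed_stop("motif_insertion_prob must be in (0,1]", "config")
  }
  stopifnot(length(motif_pfms) == length(markers))
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_len_bp = as.integer(chrom_len_bp), markers = markers,
                 motif_pfms = motif_pfms,
                 sites_per_marker = as.integer(sites_per_marker),
                 peak_len_bp = as.integer(peak_len_bp),
                 background_gc = background_gc,
                 dnase_fold_at_sites = dnase_fold_at_sites,
                 dnase_fold_background = dnase_fold_background,
                 motif_insertion_prob = motif_insertion_prob,
                 window_bp = as.integer(window_bp)),
            class = "synthetic_config")
}

#' Generate the background genome
#'
#' @param config A [synthetic_config()].
#' @return Named character vector of chromosome sequences (`chr1`, ...),
#'   i.i.d. bases at the configured GC fraction; deterministic for a fixed
#'   seed.
#' @export
generate_genome <- function(config) {
  set.seed(config$seed)
  gc <- config$background_gc
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  out <- vapply(seq_len(config$n_chroms), function(i) {
    paste0(sample(names(probs), config$chrom_len_bp, replace = TRUE,
                  prob = probs), collapse = "")
  }, character(1))
  setNames(out, paste0("chr", seq_len(config$n_chroms)))
}

#' Plant marker-specific motif sites into a genome
#'
#' Chooses disjoint grid-aligned windows for each marker, writes (with
#' probability `motif_insertion_prob`) a sample from the marker's PFM into
#' the centre of each window, and emits one peak per window.  Because marker
#' loci are disjoint and peaks equal the window, calling sites on the emitted
#' peaks recovers exactly the truth table.
#'
#' @param config A [synthetic_config()].
#' @param genome Named character vector from [generate_genome()].
#' @return List with `genome` (edited sequences), `truth` (tibble: `chrom`,
#'   `start`, `end`, `marker`, `motif`, `motif_start`) and `peaks` (named
#'   list of per-marker peak tibbles).
#' @export
plant_sites <- function(config, genome) {
  set.seed(config$seed + 1L)
  w <- config$window_bp
  k <- ncol(config$motif_pfms[[1]])
  n_need <- length(config$markers) * config$sites_per_marker
  grid <- dplyr::bind_rows(lapply(names(genome), function(ch) {
    n_win <- nchar(genome[[ch]]) %/% w
    tibble(chrom = ch, start = (seq_len(n_win) - 1L) * w)
  }))
  if (nrow(grid) < n_need) {
    ed_stop(sprintf("genome has %d grid windows but %d sites are requested",
                    nrow(grid), n_need), "capacity")
  }
  picked <- grid[sample.int(nrow(grid), n_need), ]
  picked$marker <- rep(config$markers, each = config$sites_per_marker)
  picked$motif <- runif(n_need) <= config$motif_insertion_prob
  offset <- (w - k) %/% 2L
  picked$motif_start <- ifelse(picked$motif, picked$start + offset,
                               NA_integer_)

  chars <- lapply(genome, function(s) strsplit(s, "")[[1]])
  bases <- c("A", "C", "G", "T")
  for (i in which(picked$motif)) {
    pfm <- config$motif_pfms[[picked$marker[i]]]
    inst <- vapply(seq_len(k), function(j) {
      sample(bases, 1L, prob = pfm[, j])
    }, character(1))
    at <- picked$motif_start[i] + seq_len(k)  # 1-based positions
    chars[[picked$chrom[i]]][at] <- inst
  }
  genome_out <- vapply(chars, paste0, character(1), collapse = "")

  truth <- tibble(chrom = picked$chrom, start = picked$start,
                  end = picked$start + w, marker = picked$marker,
                  motif = picked$motif, motif_start = picked$motif_start)
  truth <- dplyr::arrange(truth, .data$chrom, .data$start)
  pad <- (config$peak_len_bp - w) %/% 2L
  peaks <- lapply(config$markers, function(m) {
    tr <- truth[truth$marker == m, ]
    tibble(chrom = tr$chrom, start = pmax(tr$start - pad, 0L),
           end = tr$end + pad, signal_value = 1.0)
  })
  list(genome = genome_out, truth = truth,
       peaks = setNames(peaks, config$markers))
}

#' Generate the DNase accessibility track for a planted genome
#'
#' Emits one peak with fold enrichment `dnase_fold_at_sites` over every true
#' site (identically for all markers), plus optional background peaks at
#' `dnase_fold_background` on site-free grid windows.
#'
#' @param config A [synthetic_config()].
#' @param truth Truth tibble from [plant_sites()].
#' @return DNase peak tibble.
#' @export
generate_dnase <- function(config, truth) {
  set.seed(config$seed + 2L)
  peaks <- tibble(chrom = truth$chrom, start = truth$start, end = truth$end,
                  signal_value = config$dnase_fold_at_sites)
  if (config$dnase_fold_background > 0) {
    w <- config$window_bp
    grid <- dplyr::bind_rows(lapply(unique(truth$chrom), function(ch) {
      n_win <- config$chrom_len_bp %/% w
      tibble(chrom = ch, start = (seq_len(n_win) - 1L) * w)
    }))
    free <- dplyr::anti_join(grid, truth[, c("chrom", "start")],
                             by = c("chrom", "start"))
    n_bg <- min(nrow(free), nrow(truth))
    bg <- free[sample.int(nrow(free), n_bg), ]
    peaks <- dplyr::bind_rows(peaks, tibble(chrom = bg$chrom,
                                            start = bg$start,
                                            end = bg$start + w,
                                            signal_value =
                                              config$dnase_fold_background))
  }
  dplyr::arrange(peaks, .data$chrom, .data$start)
}

#' Generate motif-disrupting variants and distance-matched controls
#'
#' Positives substitute the base at a planted motif's maximum-information
#' column (the centre) with the least likely base under that column of the
#' PFM; controls substitute a background base about `distance_bp` away from
#' the paired positive, outside any planted window.  All ref alleles match
#' the emitted genome.
#'
#' @param config A [synthetic_config()].
#' @param truth Truth tibble from [plant_sites()].
#' @param genome Edited genome from [plant_sites()].
#' @param n_pos,n_neg Numbers of positives and controls (`n_neg <= n_pos`;
#'   control i is anchored to positive i).
#' @param distance_bp Target control distance (default 500).
#' @return List with `positives` and `controls` variant tibbles (the
#'   positives carry a `marker` column).
#' @export
generate_variant_pairs <- function(config, truth, genome, n_pos = 50L,
                                   n_neg = n_pos, distance_bp = 500L) {
  set.seed(config$seed + 3L)
  if (n_neg > n_pos) ed_stop("n_neg cannot exceed n_pos", "config")
  motif_rows <- which(truth$motif)
  if (length(motif_rows) < n_pos) {
    ed_stop(sprintf("only %d motif-bearing sites available for %d positives",
                    length(motif_rows), n_pos), "capacity")
  }
  rows <- sample(motif_rows)   # shuffled pool; scanned until enough pairs
  bases <- c("A", "C", "G", "T")
  base_at <- function(ch, pos) substr(genome[[ch]], pos + 1L, pos + 1L)

  # index of planted windows for the off-site check
  by_chrom <- split(truth, truth$chrom)
  starts_by_chrom <- lapply(by_chrom, function(tr) sort(tr$start))
  off_site <- function(ch, pos) {
    st <- starts_by_chrom[[ch]]
    if (is.null(st)) return(TRUE)
    idx <- findInterval(pos, st)
    if (idx == 0L) return(TRUE)
    !(pos >= st[idx] && pos < st[idx] + config$window_bp)
  }
  chrom_len <- setNames(nchar(genome), names(genome))

  positives <- list()
  controls <- list()
  for (i in rows) {
    if (length(positives) == n_pos) break
    pfm <- config$motif_pfms[[truth$marker[i]]]
    ic <- colSums(pfm * log2(pmax(pfm, 1e-12) / 0.25))
    col <- which.max(ic)
    pos <- truth$motif_start[i] + col - 1L
    ref <- base_at(truth$chrom[i], pos)
    others <- setdiff(bases, ref)
    alt <- others[which.min(pfm[others, col])]
    # pair the positive with a background base about distance_bp away;
    # a site with no off-site partner on either side is skipped entirely
    ctrl <- NULL
    for (cand in c(pos + distance_bp, pos - distance_bp)) {
      if (cand < 0L || cand >= chrom_len[[truth$chrom[i]]]) next
      if (!off_site(truth$chrom[i], cand)) next
      cref <- base_at(truth$chrom[i], cand)
      ctrl <- tibble(chrom = truth$chrom[i], pos = cand, ref = cref,
                     alt = sample(setdiff(bases, cref), 1L))
      break
    }
    if (is.null(ctrl)) next
    positives[[length(positives) + 1L]] <-
      tibble(chrom = truth$chrom[i], pos = pos, ref = ref, alt = alt,
             marker = truth$marker[i])
    controls[[length(controls) + 1L]] <- ctrl
  }
  if (length(positives) < n_pos) {
    ed_stop("could not place enough distance-matched controls", "capacity")
  }
  pos_tbl <- dplyr::bind_rows(positives)
  ctrl_tbl <- dplyr::bind_rows(controls)
  list(positives = pos_tbl[seq_len(n_pos), , drop = FALSE],
       controls = ctrl_tbl[seq_len(n_neg), , drop = FALSE])
}

#' Simulate a complete synthetic epigenome fixture directory
#'
#' Orchestrates genome generation, motif planting, DNase-track and variant
#' generation, and writes the exact formats the real pipeline consumes:
#' `genome.fa`, `peaks/<marker>.narrowPeak` (7 files), `dnase.narrowPeak`,
#' `truth.tsv`, `variants_positive.tsv`, `variants_control.tsv` and a JSON
#' manifest.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory.
#' @param n_variants Positive/control variant pairs to emit (default 50).
#' @param variant_distance_bp Control distance (default 500).
#' @return Invisibly, a list with the in-memory objects (`genome`, `truth`,
#'   `peaks`, `dnase`, `variants`) and `paths`.
#' @export
simulate_epigenome <- function(config, dir, n_variants = 50L,
                               variant_distance_bp = 500L) {
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE, recursive = TRUE)
  genome0 <- generate_genome(config)
  ps <- plant_sites(config, genome0)
  dnase <- generate_dnase(config, ps$truth)
  variants <- generate_variant_pairs(config, ps$truth, ps$genome,
                                     n_pos = n_variants,
                                     distance_bp = variant_distance_bp)
  paths <- list(genome = file.path(dir, "genome.fa"),
                dnase = file.path(dir, "dnase.narrowPeak"),
                truth = file.path(dir, "truth.tsv"),
                variants_positive = file.path(dir, "variants_positive.tsv"),
                variants_control = file.path(dir, "variants_control.tsv"),
                manifest = file.path(dir, "manifest.json"))
  paths$peaks <- setNames(
    file.path(dir, "peaks", paste0(config$markers, ".narrowPeak")),
    config$markers)

  dss <- Biostrings::DNAStringSet(ps$genome)
  Biostrings::writeXStringSet(dss, paths$genome)
  for (m in config$markers) write_narrowpeak(ps$peaks[[m]], paths$peaks[[m]])
  write_narrowpeak(dnase, paths$dnase)
  utils::write.table(ps$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_variants(variants$positives, paths$variants_positive)
  write_variants(variants$controls, paths$variants_control)
  manifest <- config
  manifest$motif_pfms <- lapply(manifest$motif_pfms, function(p) {
    unname(apply(p, 2, function(col) {
      paste(sprintf("%.4f", col), collapse = ",")
    }))
  })
  jsonlite::write_json(unclass(manifest), paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(genome = ps$genome, truth = ps$truth, peaks = ps$peaks,
                 dnase = dnase, variants = variants, paths = paths))
}
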