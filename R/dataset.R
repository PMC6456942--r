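#' Call modification sites by scanning a genome grid against peaks
#'
#' Scans each chromosome with non-overlapping windows of `window_bp`
#' (step `step_bp`, anchored at coordinate 0) and calls a window a
#' modification site when its total base overlap with the union of the peaks
#' reaches `min_overlap_bp`.  The defaults implement the 200-bp window /
#' 100-bp overlap rule used to define histone modification sites.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, ...).
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param window_bp,step_bp,min_overlap_bp Grid geometry; see Details.
#' @return Tibble of called windows (`chrom`, `start`, `end`), sorted by
#'   (chrom, start), without duplicates.
#' @export
call_sites <- function(peaks, chrom_sizes, window_bp = 200L, step_bp = 200L,
                       min_overlap_bp = 100L) {
  if (window_bp <= 0L || step_bp <= 0L) {
    ed_stop("window_bp and step_bp must be positive", "config")
  }
  if (min_overlap_bp > window_bp) {
    ed_stop("min_overlap_bp cannot exceed window_bp", "config")
  }
  if (nrow(peaks) > 0L && !all(peaks$chrom %in% names(chrom_sizes))) {
    missing <- setdiff(unique(peaks$chrom), names(chrom_sizes))
    ed_stop(paste0("peaks on chromosomes absent from chrom_sizes: ",
                   paste(missing, collapse = ", ")), "lookup")
  }
  out <- list()
  for (chrom in sort(names(chrom_sizes))) {
    len <- chrom_sizes[[chrom]]
    n_win <- if (len >= window_bp) (len - window_bp) %/% step_bp + 1L else 0L
    if (n_win == 0L) next
    p <- peaks[peaks$chrom == chrom, , drop = FALSE]
    if (nrow(p) == 0L) next
    ir <- IRanges::reduce(IRanges::IRanges(start = p$start + 1L, end = p$end))
    cov <- IRanges::coverage(ir, width = max(len, max(p$end)))
    starts0 <- (seq_len(n_win) - 1L) * step_bp
    v <- IRanges::Views(cov, start = starts0 + 1L, end = starts0 + window_bp)
    ov <- IRanges::viewSums(v)
    keep <- which(ov >= min_overlap_bp)
    if (length(keep) > 0L) {
      out[[chrom]] <- tibble(chrom = chrom, start = starts0[keep],
                             end = starts0[keep] + window_bp)
    }
  }
  if (length(out) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  dplyr::bind_rows(out)
}

#' Assemble a multi-label site table from per-marker site lists
#'
#' The table is the union of all markers' sites; each window carries a binary
#' label per marker, so a window shared by several markers is multi-labelled
#' and every row has at least one positive label.  The one-vs-rest negative
#' set for a marker is exactly the rows where its label is 0.
#'
#' @param per_marker_sites Named list mapping marker name to a window tibble
#'   (`chrom`, `start`, `end`), as returned by [call_sites()].
#' @param markers Ordered character vector of the 7 marker names.
#' @param epigenome_id Identifier stored on the table.
#' @return A `site_table`: tibble with `chrom`, `start`, `end` and one 0/1
#'   column per marker; attributes `markers` and `epigenome_id`.
#' @export
build_site_table <- function(per_marker_sites, markers, epigenome_id = "syn") {
  stray <- setdiff(names(per_marker_sites), markers)
  if (length(stray) > 0L) {
    ed_stop(paste0("site list for unknown marker(s): ",
                   paste(stray, collapse = ", ")), "config")
  }
  nonempty <- Filter(function(x) nrow(x) > 0L, per_marker_sites)
  if (length(nonempty) == 0L) {
    ed_stop("no sites for any marker", "config")
  }
  all_w <- dplyr::distinct(
    dplyr::bind_rows(lapply(nonempty, function(x) x[c("chrom", "start", "end")])))
  all_w <- dplyr::arrange(all_w, .data$chrom, .data$start)
  key <- paste(all_w$chrom, all_w$start)
  labels <- matrix(0L, nrow = nrow(all_w), ncol = length(markers),
                   dimnames = list(NULL, markers))
  for (m in names(per_marker_sites)) {
    w <- per_marker_sites[[m]]
    if (nrow(w) == 0L) next
    labels[match(paste(w$chrom, w$start), key), m] <- 1L
  }
  out <- dplyr::bind_cols(all_w, as_tibble(as.data.frame(labels)))
  attr(out, "markers") <- markers
  attr(out, "epigenome_id") <- epigenome_id
  class(out) <- c("site_table", class(out))
  out
}

#' Extract the n x 7 binary label matrix of a site table
#' @param site_table A `site_table` from [build_site_table()].
#' @return Integer matrix, one column per marker.
#' @export
site_labels <- function(site_table) {
  markers <- attr(site_table, "markers")
  as.matrix(as.data.frame(site_table)[, markers, drop = FALSE])
}

#' Does an epigenome retain enough sites for every marker?
#'
#' Epigenomes with fewer than `threshold` modification sites for any marker
#' are discarded from the study; a count exactly at the threshold passes
#' (the rule is a strict "< threshold" discard).
#'
#' @param site_counts Named integer vector of per-marker site counts.
#' @param markers Marker names that must all be present.
#' @param threshold Minimum per-marker site count (default 50,000).
#' @return `TRUE` iff every marker's count is at least `threshold`.
#' @export
epigenome_passes_filter <- function(site_counts, markers = names(site_counts),
                                    threshold = 50000L) {
  missing <- setdiff(markers, names(site_counts))
  if (length(missing) > 0L) {
    ed_stop(paste0("missing site counts for marker(s): ",
                   paste(missing, collapse = ", ")), "config")
  }
  all(site_counts[markers] >= threshold)
}

#' Extend a window to a fixed-length region with the same midpoint
#'
#' A 200-bp site is extended upstream and downstream to the 1000-bp region
#' that is fed to the network.  The result may extend below 0 or past the
#' chromosome end; downstream encoders pad such positions.
#'
#' @param window One-row tibble or list with `chrom`, `start`, `end`.
#' @param region_bp Target region length (default 1000).
#' @return List with `chrom`, `start`, `end` of the centred region.
#' @export
center_region <- function(window, region_bp = 1000L) {
  w <- window$end - window$start
  if (w > region_bp) ed_stop("window longer than region_bp", "config")
  if ((region_bp - w) %% 2L != 0L) {
    ed_stop("region_bp - window length must be even", "config")
  }
  ext <- (region_bp - w) %/% 2L
  list(chrom = window$chrom, start = window$start - ext,
       end = window$end + ext)
}

#' One-hot encode a nucleotide string
#'
#' @param seq String over A, C, G, T, N (any case).  `N` encodes as an
#'   all-zero column, preserving the binary-matrix property; any other symbol
#'   is an error.
#' @return 4 x nchar(seq) 0/1 matrix with rows A, C, G, T.
#' @export
encode_sequence <- function(seq) {
  codes <- seq_codes(seq)
  L <- length(codes)
  out <- matrix(0, nrow = 4L, ncol = L, dimnames = list(c("A", "C", "G", "T")))
  nz <- which(codes > 0L)
  out[cbind(codes[nz], nz)] <- 1
  out
}

# internal: map a nucleotide string to integer codes A=1 C=2 G=3 T=4 N=0
seq_codes <- function(seq) {
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("C")] <- 2L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("g")] <- 3L
  lut[utf8ToInt("T")] <- 4L; lut[utf8ToInt("t")] <- 4L
  lut[utf8ToInt("N")] <- 0L; lut[utf8ToInt("n")] <- 0L
  raw <- utf8ToInt(seq)
  codes <- lut[raw]
  if (anyNA(codes)) {
    ed_stop(paste0("cannot encode symbol '", intToUtf8(raw[which(is.na(codes))[1]]),
                   "' (alphabet is A/C/G/T/N)"), "encoding")
  }
  codes
}

#' Per-base openness scores of a region from a DNase peak track
#'
#' Positions inside a peak receive the peak's fold-enrichment
#' `signal_value`; positions covered by several overlapping peaks receive the
#' maximum; everything else (including positions beyond chromosome bounds) is
#' zero.
#'
#' @param track Peak tibble for one epigenome's DNase-seq assay.
#' @param region List/row with `chrom`, `start`, `end` (0-based half-open).
#' @param log1p_transform Apply `log1p` to the scores (default `FALSE`: raw
#'   fold enrichment, as assigned by the standard peak pipeline).
#' @return Numeric vector of length `end - start`.
#' @export
encode_openness <- function(track, region, log1p_transform = FALSE) {
  L <- region$end - region$start
  if (L <= 0L) ed_stop("region length must be positive", "interval")
  out <- numeric(L)
  if (nrow(track) > 0L) {
    p <- track[track$chrom == region$chrom & track$end > region$start &
                 track$start < region$end, , drop = FALSE]
    if (nrow(p) > 0L) {
      for (i in seq_len(nrow(p))) {
        a <- max(p$start[i], region$start) - region$start + 1L
        b <- min(p$end[i], region$end) - region$start
        out[a:b] <- pmax(out[a:b], p$signal_value[i])
      }
    }
  }
  if (log1p_transform) out <- log1p(out)
  out
}

#' Encode site-table rows into network-ready arrays
#'
#' Composes [center_region()], [fetch_sequence()], [encode_sequence()] and
#' [encode_openness()] for the requested rows.
#'
#' @param genome Genome handle (see [read_genome()]).
#' @param track DNase peak tibble.
#' @param site_table A `site_table`.
#' @param rows Integer row indices to encode (default: all rows).
#' @param region_bp Region length fed to the network (default 1000).
#' @param log1p_openness Passed to [encode_openness()].
#' @return An `encoded_batch`: list with `seq` (n x 4 x region_bp 0/1 array),
#'   `openness` (n x 1 x region_bp array) and `labels` (n x 7 matrix).
#' @export
build_batch <- function(genome, track, site_table, rows = seq_len(nrow(site_table)),
                        region_bp = 1000L, log1p_openness = FALSE) {
  stopifnot(all(rows >= 1L), all(rows <= nrow(site_table)))
  n <- length(rows)
  seq_arr <- array(0, dim = c(n, 4L, region_bp))
  opn_arr <- array(0, dim = c(n, 1L, region_bp))
  for (i in seq_len(n)) {
    w <- site_table[rows[i], , drop = FALSE]
    reg <- center_region(w, region_bp)
    s <- fetch_sequence(genome, reg$chrom, reg$start, reg$end)
    seq_arr[i, , ] <- encode_sequence(s)
    opn_arr[i, 1L, ] <- encode_openness(track, reg, log1p_openness)
  }
  labels <- site_labels(site_table)[rows, , drop = FALSE]
  structure(list(seq = seq_arr, openness = opn_arr, labels = labels),
            class = "encoded_batch")
}

#' Pre-encode a whole site table into a compact in-memory dataset
#'
#' Stores sequences as integer codes and openness as a dense matrix so
#' training can materialize one-hot minibatches cheaply.
#'
#' @inheritParams build_batch
#' @return An `encoded_dataset`: list with `codes` (n x region_bp integer
#'   matrix, A=1..T=4, N=0), `openness` (n x region_bp), `labels` (n x 7),
#'   `markers`, `epigenome_id`, `region_bp`.
#' @export
encode_dataset <- function(genome, track, site_table, region_bp = 1000L,
                           log1p_openness = FALSE) {
  n <- nrow(site_table)
  # keep chromosomes as plain strings: substr is much faster than XString
  # slicing in a tight loop
  chrs <- if (inherits(genome, "DNAStringSet")) {
    setNames(as.character(genome), names(genome))
  } else {
    genome
  }
  codes <- matrix(0L, nrow = n, ncol = region_bp)
  opn <- matrix(0, nrow = n, ncol = region_bp)
  regions <- lapply(seq_len(n), function(i) {
    center_region(site_table[i, , drop = FALSE], region_bp)
  })
  for (i in seq_len(n)) {
    r <- regions[[i]]
    codes[i, ] <- seq_codes(fetch_sequence(chrs, r$chrom, r$start, r$end))
  }
  # one overlap pass for openness instead of per-row scans
  if (nrow(track) > 0L) {
    reg_chrom <- vapply(regions, `[[`, character(1), "chrom")
    reg_start <- vapply(regions, `[[`, numeric(1), "start")
    for (chrom in unique(reg_chrom)) {
      p <- track[track$chrom == chrom, , drop = FALSE]
      if (nrow(p) == 0L) next
      ri <- which(reg_chrom == chrom)
      q <- IRanges::IRanges(start = reg_start[ri] + 1L, width = region_bp)
      s <- IRanges::IRanges(start = p$start + 1L, end = p$end)
      hits <- IRanges::findOverlaps(q, s)
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      for (h in seq_along(qh)) {
        i <- ri[qh[h]]
        a <- max(p$start[sh[h]] - reg_start[i], 0) + 1L
        b <- min(p$end[sh[h]] - reg_start[i], region_bp)
        opn[i, a:b] <- pmax(opn[i, a:b], p$signal_value[sh[h]])
      }
    }
  }
  if (log1p_openness) opn <- log1p(opn)
  structure(list(codes = codes, openness = opn, labels = site_labels(site_table),
                 markers = attr(site_table, "markers"),
                 epigenome_id = attr(site_table, "epigenome_id"),
                 region_bp = region_bp),
            class = "encoded_dataset")
}

#' Materialize one-hot arrays for selected rows of an encoded dataset
#'
#' @param dataset An `encoded_dataset` from [encode_dataset()].
#' @param rows Row indices.
#' @return An `encoded_batch` (same contract as [build_batch()]).
#' @export
dataset_batch <- function(dataset, rows) {
  n <- length(rows)
  L <- dataset$region_bp
  seq_arr <- array(0, dim = c(n, 4L, L))
  for (i in seq_len(n)) {
    codes <- dataset$codes[rows[i], ]
    nz <- which(codes > 0L)
    seq_arr[cbind(i, codes[nz], nz)] <- 1
  }
  opn_arr <- array(dataset$openness[rows, , drop = FALSE], dim = c(n, 1L, L))
  structure(list(seq = seq_arr, openness = opn_arr,
                 labels = dataset$labels[rows, , drop = FALSE]),
            class = "encoded_batch")
}

#' Write an encoded dataset (plus manifest) to a directory
#'
#' The directory holds the site table as a BED-like TSV with one label column
#' per marker, the encoded arrays, and a JSON manifest recording the genome
#' path, marker order and encoding flags.
#'
#' @param dataset An `encoded_dataset`.
#' @param site_table The `site_table` it was encoded from.
#' @param dir Output directory (created if needed).
#' @param genome_path,flags Provenance recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, site_table, dir, genome_path = NA_character_,
                          flags = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(site_table), file.path(dir, "sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  saveRDS(dataset, file.path(dir, "encoded.rds"))
  manifest <- list(epigenome_id = dataset$epigenome_id,
                   markers = dataset$markers,
                   n_sites = nrow(dataset$codes),
                   region_bp = dataset$region_bp,
                   genome_path = genome_path,
                   flags = flags,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#' @param dir Dataset directory.
#' @return List with `dataset` (`encoded_dataset`), `sites` (tibble) and
#'   `manifest` (list).
#' @export
read_dataset <- function(dir) {
  dataset <- readRDS(file.path(dir, "encoded.rds"))
  sites <- as_tibble(utils::read.table(file.path(dir, "sites.tsv"),
                                       header = TRUE, sep = "\t"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  attr(sites, "markers") <- manifest$markers
  attr(sites, "epigenome_id") <- manifest$epigenome_id
  class(sites) <- c("site_table", class(sites))
  list(dataset = dataset, sites = sites, manifest = manifest)
}
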