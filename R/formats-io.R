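#' Read a BED3 / ENCODE narrowPeak file into a peak tibble
#'
#' Coordinates follow the BED convention throughout the package: 0-based,
#' half-open `[start, end)`.  Ten-column input is treated as ENCODE
#' narrowPeak, with the fold-enrichment signal in column 7; three-column BED
#' gets `signal_value = 1` by convention so minimal fixtures stay minimal.
#'
#' @param path Path to a tab-separated BED3 or 10-column narrowPeak file.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `signal_value`, `p_value`, `q_value`, `summit` — one row per
#'   peak, in file order.
#' @export
read_narrowpeak <- function(path) {
  if (!file.exists(path)) ed_stop(paste0("no such peak file: ", path), "io")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      name = character(), score = double(), strand = character(),
      signal_value = double(), p_value = double(), q_value = double(),
      summit = integer()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  bad <- which(ncol < 3L)
  if (length(bad) > 0L) {
    ed_stop(sprintf("line %d: expected >= 3 tab-separated columns", bad[1]),
            "parse")
  }
  get_col <- function(j) vapply(fields, function(f) {
    if (length(f) >= j) f[[j]] else NA_character_
  }, character(1))

  chrom <- get_col(1)
  start <- suppressWarnings(as.integer(get_col(2)))
  end <- suppressWarnings(as.integer(get_col(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    ed_stop(sprintf("line %d: non-integer coordinates", bad[1]), "parse")
  }
  bad <- which(start >= end | start < 0L)
  if (length(bad) > 0L) {
    ed_stop(sprintf("line %d: invalid interval (need 0 <= start < end)",
                    bad[1]), "parse")
  }
  signal <- rep(1.0, length(lines))
  has10 <- ncol >= 7L
  if (any(has10)) {
    sv <- suppressWarnings(as.double(get_col(7)))
    bad <- which(has10 & (is.na(sv) | sv < 0))
    if (length(bad) > 0L) {
      ed_stop(sprintf("line %d: signal value must be a non-negative number",
                      bad[1]), "parse")
    }
    signal[has10] <- sv[has10]
  }
  tibble(
    chrom = chrom, start = start, end = end,
    name = ifelse(ncol >= 4L, get_col(4), NA_character_),
    score = suppressWarnings(as.double(ifelse(ncol >= 5L, get_col(5), NA))),
    strand = ifelse(ncol >= 6L, get_col(6), NA_character_),
    signal_value = signal,
    p_value = suppressWarnings(as.double(ifelse(ncol >= 8L, get_col(8), NA))),
    q_value = suppressWarnings(as.double(ifelse(ncol >= 9L, get_col(9), NA))),
    summit = suppressWarnings(as.integer(ifelse(ncol >= 10L, get_col(10), NA)))
  )
}

#' Write a peak tibble as a 10-column narrowPeak file
#'
#' Round-trips exactly with [read_narrowpeak()]: chrom/start/end/signal_value
#' are preserved; missing optional columns are written as narrowPeak
#' placeholders (`.` name/strand, `0` score, `-1` p/q/summit).
#'
#' @param peaks Peak tibble (at least `chrom`, `start`, `end`; optionally
#'   `signal_value` and the other narrowPeak columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  n <- nrow(peaks)
  grab <- function(col, default) {
    if (col %in% names(peaks)) {
      v <- peaks[[col]]
      ifelse(is.na(v), default, v)
    } else {
      rep(default, n)
    }
  }
  lines <- paste(
    peaks$chrom, format(peaks$start, scientific = FALSE, trim = TRUE),
    format(peaks$end, scientific = FALSE, trim = TRUE),
    grab("name", "."), grab("score", 0), grab("strand", "."),
    grab("signal_value", 1), grab("p_value", -1), grab("q_value", -1),
    grab("summit", -1),
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Load a genome from a FASTA file
#'
#' @param path FASTA path (plain text).
#' @return A [Biostrings::DNAStringSet] keyed by the first whitespace-
#'   delimited token of each record header.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) ed_stop(paste0("no such FASTA: ", path), "io")
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- vapply(strsplit(names(g), "\\s+"), `[[`, character(1), 1)
  g
}

#' Fetch the sequence of a genomic interval, padding out-of-range positions
#'
#' Positions below 0 or at/after the chromosome end are returned as `N`, so
#' windows extended past chromosome boundaries are always well defined and
#' `nchar(result) == end - start` holds for every interval.
#'
#' @param genome A `DNAStringSet` (see [read_genome()]) or a named character
#'   vector of chromosome sequences.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @return Uppercased nucleotide string of length `end - start`.
#' @export
fetch_sequence <- function(genome, chrom, start, end) {
  if (start >= end) ed_stop("need start < end", "interval")
  if (inherits(genome, "DNAStringSet")) {
    if (!chrom %in% names(genome)) {
      ed_stop(paste0("unknown chromosome: ", chrom), "lookup")
    }
    len <- Biostrings::width(genome)[match(chrom, names(genome))]
    lo <- max(start, 0L)
    hi <- min(end, len)
    core <- if (lo < hi) {
      as.character(Biostrings::subseq(genome[[chrom]], lo + 1L, hi))
    } else {
      ""
    }
  } else {
    if (!chrom %in% names(genome)) {
      ed_stop(paste0("unknown chromosome: ", chrom), "lookup")
    }
    len <- nchar(genome[[chrom]])
    lo <- max(start, 0L)
    hi <- min(end, len)
    core <- if (lo < hi) substr(genome[[chrom]], lo + 1L, hi) else ""
  }
  pad_left <- lo - start
  pad_right <- end - max(hi, start)
  if (pad_right < 0) pad_right <- 0
  out <- paste0(strrep("N", pad_left), toupper(core), strrep("N", pad_right))
  # degenerate case: interval entirely beyond the chromosome
  if (nchar(out) != end - start) out <- strrep("N", end - start)
  out
}

#' Write kernel motifs in MEME minimal format
#'
#' Produces the interchange format consumed by TomTom-style motif comparison
#' tools: a version line, the ACGT alphabet, a background frequency line, and
#' one `MOTIF` block with a letter-probability matrix per kernel.
#'
#' @param motifs List of `kernel_motif` objects (see [extract_pwm()]), or an
#'   empty list for a header-only file.
#' @param path Output path.
#' @param background Background frequencies for A, C, G, T (must sum to 1).
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path, background = rep(0.25, 4)) {
  stopifnot(length(background) == 4, abs(sum(background) - 1) < 1e-6)
  for (m in motifs) {
    sums <- colSums(m$pfm)
    if (any(abs(sums - 1) > 1e-6)) {
      ed_stop(sprintf("motif %s: PFM column %d sums to %.6f, not 1",
                      m$kernel_index, which(abs(sums - 1) > 1e-6)[1],
                      sums[which(abs(sums - 1) > 1e-6)[1]]), "validation")
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.6f C %.6f G %.6f T %.6f", background[1], background[2],
            background[3], background[4]), ""
  ), con)
  for (m in motifs) {
    w <- ncol(m$pfm)
    writeLines(sprintf("MOTIF kernel_%d", m$kernel_index), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0", w,
      max(m$n_activations, 1L)), con)
    for (j in seq_len(w)) {
      writeLines(sprintf("%.6f %.6f %.6f %.6f", m$pfm[1, j], m$pfm[2, j],
                         m$pfm[3, j], m$pfm[4, j]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read a MEME minimal-format motif file
#'
#' @param path MEME file written by [write_meme()] or compatible tools.
#' @return List of `kernel_motif`-like lists with `kernel_index` (parsed from
#'   `kernel_<i>` names when present, otherwise sequential), `pfm` (4 x w
#'   matrix, rows A,C,G,T) and `n_activations` (from `nsites`).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  idx <- grep("^MOTIF ", lines)
  out <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    name <- sub("^MOTIF\\s+", "", lines[idx[i]])
    hdr_at <- idx[i] + 1L
    hdr <- lines[hdr_at]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
    nsites <- if (grepl("nsites=", hdr)) {
      as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", hdr))
    } else {
      NA_integer_
    }
    rows <- lines[(hdr_at + 1L):(hdr_at + w)]
    pfm <- t(vapply(strsplit(trimws(rows), "\\s+"),
                    function(f) as.double(f[1:4]), double(4)))
    pfm <- t(pfm)  # 4 x w, rows A,C,G,T
    rownames(pfm) <- c("A", "C", "G", "T")
    ki <- if (grepl("^kernel_\\d+$", name)) {
      as.integer(sub("kernel_", "", name))
    } else {
      i
    }
    out[[i]] <- list(kernel_index = ki, pfm = pfm, n_activations = nsites)
  }
  out
}

#' Read a variant TSV (`chrom pos ref alt`, 0-based positions)
#'
#' @param path Tab-separated file with header `chrom`, `pos`, `ref`, `alt`.
#' @return Tibble with those columns; `pos` is the 0-based coordinate of the
#'   substituted base.
#' @export
read_variants <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer", "character",
                                         "character"))
  v <- as_tibble(df)
  v$ref <- toupper(v$ref)
  v$alt <- toupper(v$alt)
  bad <- which(!is_nt(v$ref) | !is_nt(v$alt) | v$ref == v$alt |
                 nchar(v$ref) != 1L | nchar(v$alt) != 1L)
  if (length(bad) > 0L) {
    ed_stop(sprintf(
      "variant %d (%s:%d): alleles must be single distinct A/C/G/T bases",
      bad[1], v$chrom[bad[1]], v$pos[bad[1]]), "parse")
  }
  v
}

#' Write a variant tibble as TSV
#'
#' @param variants Tibble with at least `chrom`, `pos`, `ref`, `alt`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
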