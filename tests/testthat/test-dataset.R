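test_that("call_sites implements the 200-bp window / 100-bp overlap rule", {
  sizes <- c(chr1 = 10000)
  p1 <- tibble::tibble(chrom = "chr1", start = 0L, end = 400L,
                       signal_value = 1)
  w <- call_sites(p1, sizes)
  expect_equal(w$start, c(0L, 200L))

  p2 <- tibble::tibble(chrom = "chr1", start = 150L, end = 260L,
                       signal_value = 1)
  expect_equal(nrow(call_sites(p2, sizes)), 0L)

  # union semantics: two 50-bp peaks both inside window [0,200)
  p3 <- tibble::tibble(chrom = "chr1", start = c(150L, 100L),
                       end = c(200L, 150L), signal_value = 1)
  expect_equal(call_sites(p3, sizes)$start, 0L)

  expect_error(call_sites(p1, sizes, window_bp = 0), class = "epideep_config")
  expect_error(call_sites(p1, sizes, min_overlap_bp = 300),
               class = "epideep_config")
  expect_error(call_sites(p1, c(chr9 = 100)), class = "epideep_lookup")
})

test_that("call_sites matches the per-base brute-force oracle on random peak sets", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(1:12, 1)
    sizes <- c(chr1 = 10000, chr2 = 6000)
    chrom <- sample(names(sizes), n, TRUE)
    start <- vapply(chrom, function(ch) sample(0:(sizes[[ch]] - 10), 1),
                    numeric(1))
    peaks <- tibble::tibble(chrom = chrom, start = as.integer(start),
                            end = as.integer(start + sample(10:800, n, TRUE)),
                            signal_value = 1)
    peaks$end <- pmin(peaks$end, sizes[peaks$chrom])
    got <- call_sites(peaks, sizes)
    want <- oracle_call_sites(peaks, sizes)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("site tables take the union with multi-marker labels", {
  w1 <- tibble::tibble(chrom = "chr1", start = 0L, end = 200L)
  markers <- tiny_markers(7)
  st <- build_site_table(list(m1 = w1, m2 = w1), markers, "E1")
  expect_equal(nrow(st), 1L)
  expect_equal(unname(site_labels(st)[1, ]), c(1L, 1L, 0L, 0L, 0L, 0L, 0L))

  w_a <- tibble::tibble(chrom = "chr1", start = c(0L, 200L, 400L),
                        end = c(200L, 400L, 600L))
  w_b <- tibble::tibble(chrom = "chr2", start = c(0L, 200L),
                        end = c(200L, 400L))
  st2 <- build_site_table(list(m1 = w_a, m3 = w_b), markers, "E1")
  expect_equal(nrow(st2), 5L)
  expect_true(all(rowSums(site_labels(st2)) == 1))

  st3 <- build_site_table(setNames(rep(list(w1), 7), markers), markers, "E1")
  expect_equal(unname(site_labels(st3)[1, ]), rep(1L, 7))

  expect_error(build_site_table(list(zz = w1), markers, "E1"),
               class = "epideep_config")
})

test_that("label matrix conserves per-marker site counts", {
  set.seed(5)
  markers <- tiny_markers(7)
  grid <- tibble::tibble(chrom = "chr1", start = seq(0L, 9800L, by = 200L))
  grid$end <- grid$start + 200L
  sites <- lapply(markers, function(m) grid[sample(nrow(grid), 8), ])
  names(sites) <- markers
  st <- build_site_table(sites, markers, "E1")
  expect_equal(sum(vapply(sites, nrow, integer(1))), sum(site_labels(st)))
})

test_that("the per-marker site-count filter uses a strict less-than rule", {
  counts <- setNames(rep(60000, 7), tiny_markers(7))
  expect_true(epigenome_passes_filter(counts))
  counts["m3"] <- 49999
  expect_false(epigenome_passes_filter(counts))
  counts["m3"] <- 50000
  expect_true(epigenome_passes_filter(counts))
  expect_error(epigenome_passes_filter(counts[-1], markers = names(counts)),
               class = "epideep_config")
})

test_that("center_region keeps the midpoint and may extend past boundaries", {
  r <- center_region(list(chrom = "chr1", start = 1000L, end = 1200L))
  expect_equal(c(r$start, r$end), c(600L, 1600L))
  r2 <- center_region(list(chrom = "chr1", start = 0L, end = 200L))
  expect_equal(c(r2$start, r2$end), c(-400L, 600L))
  expect_error(center_region(list(chrom = "chr1", start = 0L, end = 200L),
                             region_bp = 999L), class = "epideep_config")
})

test_that("one-hot encoding follows the A,C,G,T row order with zero columns for N", {
  expect_equal(unname(encode_sequence("ACGT")), diag(4))
  expect_equal(unname(encode_sequence("N")), matrix(0, 4, 1))
  expect_error(encode_sequence("ACGX"), "X")

  set.seed(2)
  for (rep in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "T", "N"), 50, TRUE), collapse = "")
    m <- encode_sequence(seq)
    sums <- colSums(m)
    expect_true(all(sums %in% c(0, 1)))
    expect_equal(sum(sums == 0),
                 lengths(regmatches(seq, gregexpr("N", seq))))
  }
})

test_that("openness encoding assigns fold enrichment with per-base maximum", {
  region <- list(chrom = "chr1", start = 0L, end = 1000L)
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), signal_value = double())
  expect_equal(encode_openness(empty, region), rep(0, 1000))

  full <- tibble::tibble(chrom = "chr1", start = -10L, end = 2000L,
                         signal_value = 5.2)
  expect_equal(encode_openness(full, region), rep(5.2, 1000))

  two <- tibble::tibble(chrom = "chr1", start = c(0L, 100L),
                        end = c(500L, 300L), signal_value = c(2, 7))
  o <- encode_openness(two, region)
  expect_equal(o[150], 7)
  expect_equal(o[50], 2)
  expect_equal(o[600], 0)

  # monotonicity: adding a peak never decreases any position's score
  set.seed(8)
  track <- tibble::tibble(chrom = "chr1", start = c(10L, 400L),
                          end = c(200L, 800L), signal_value = c(3, 1))
  base <- encode_openness(track, region)
  for (rep in 1:10) {
    s <- sample(0:900, 1)
    extra <- rbind(track, tibble::tibble(chrom = "chr1", start = s,
                                         end = s + sample(10:300, 1),
                                         signal_value = runif(1, 0, 10)))
    expect_true(all(encode_openness(extra, region) >= base))
  }
})

test_that("encoded batches compose fetching, centering and encoding", {
  set.seed(31)
  g <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 3000, TRUE),
                      collapse = ""))
  track <- tibble::tibble(chrom = "chr1", start = 400L, end = 700L,
                          signal_value = 4)
  st <- build_site_table(
    list(m1 = tibble::tibble(chrom = "chr1", start = c(0L, 600L),
                             end = c(200L, 800L))),
    tiny_markers(3), "E1")
  b <- build_batch(g, track, st)
  expect_s3_class(b, "encoded_batch")
  expect_equal(dim(b$seq), c(2, 4, 1000))
  expect_equal(dim(b$openness), c(2, 1, 1000))
  expect_equal(dim(b$labels), c(2, 3))

  # window at chromosome start: left 400 columns are N padding (all zero)
  expect_true(all(b$seq[1, , 1:400] == 0))
  expect_true(all(colSums(b$seq[1, , 401:1000]) == 1))

  # determinism: the same row twice gives identical encodings
  b2 <- build_batch(g, track, st, rows = c(2, 2))
  expect_identical(b2$seq[1, , ], b2$seq[2, , ])

  # openness of row 2 (region 200..1200) covers the peak at 400..700
  expect_equal(b$openness[2, 1, 201], 4)
  expect_equal(b$openness[2, 1, 800], 0)

  # the compact dataset encoding agrees with build_batch
  ds <- encode_dataset(g, track, st)
  db <- dataset_batch(ds, 1:2)
  expect_equal(db$seq, b$seq)
  expect_equal(db$openness, b$openness)
  expect_equal(db$labels, b$labels)
})

test_that("dataset directories round-trip through write_dataset/read_dataset", {
  set.seed(4)
  g <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 2000, TRUE),
                      collapse = ""))
  st <- build_site_table(
    list(m1 = tibble::tibble(chrom = "chr1", start = 200L, end = 400L)),
    tiny_markers(3), "E9")
  ds <- encode_dataset(g, tibble::tibble(chrom = character(),
                                         start = integer(), end = integer(),
                                         signal_value = double()), st)
  dir <- withr::local_tempdir()
  write_dataset(ds, st, dir, genome_path = "genome.fa")
  back <- read_dataset(dir)
  expect_equal(back$dataset$codes, ds$codes)
  expect_equal(back$dataset$labels, ds$labels)
  expect_equal(back$manifest$epigenome_id, "E9")
  expect_equal(attr(back$sites, "markers"), tiny_markers(3))
})
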