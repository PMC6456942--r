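test_that("one-vs-rest labels treat other markers' sites as negatives", {
  w <- function(s) tibble::tibble(chrom = "chr1", start = s, end = s + 200L)
  st <- build_site_table(list(m1 = w(0L), m2 = w(c(0L, 200L))),
                         tiny_markers(3), "E1")
  expect_equal(one_vs_rest_labels(st, "m1"), c(1L, 0L))
  expect_equal(one_vs_rest_labels(st, "m2"), c(1L, 1L))
  expect_equal(one_vs_rest_labels(st, "m3"), c(0L, 0L))
  expect_error(one_vs_rest_labels(st, "zz"), class = "epideep_config")
})

test_that("auROC equals the rank/concordance statistic with half-credit ties", {
  expect_equal(auroc(c(0.9, 0.1), c(1, 0)), 1.0)
  expect_equal(auroc(c(0.1, 0.9), c(1, 0)), 0.0)
  expect_equal(auroc(rep(0.5, 4), c(1, 1, 0, 0)), 0.5)
  expect_error(auroc(c(0.5, 0.6), c(1, 1)), class = "epideep_metric")

  set.seed(21)
  for (rep in 1:40) {
    n <- sample(5:200, 1)
    scores <- sample(round(runif(n), 2))  # rounded -> plenty of ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) %in% c(0, n)) next
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels))
    # complement symmetry for tie-free scores
    sc2 <- runif(n)
    expect_equal(auroc(sc2, labels) + auroc(-sc2, labels), 1.0)
  }
})

test_that("auPRC is the average-precision step summation", {
  expect_equal(auprc(c(0.3, 0.9), c(0, 1)), 1.0)
  expect_equal(auprc(c(0.9, 0.8, 0.7), c(1, 0, 1)), 5 / 6)
  expect_equal(auprc(c(10:2, 1), c(rep(0, 9), 1)), 0.1)
  expect_error(auprc(c(0.1, 0.2), c(0, 0)), class = "epideep_metric")

  set.seed(22)
  for (rep in 1:40) {
    n <- sample(5:200, 1)
    scores <- sample(round(runif(n), 2))
    labels <- rbinom(n, 1, 0.3)
    if (sum(labels) == 0) next
    expect_equal(auprc(scores, labels), oracle_auprc(scores, labels))
  }
})

test_that("the exact sign test reproduces binomial tail probabilities", {
  expect_equal(paired_sign_test(15, 15), 2^-15)
  expect_equal(paired_sign_test(8, 15), 0.5)
  expect_equal(paired_sign_test(0, 15), 1.0)
  expect_error(paired_sign_test(16, 15), class = "epideep_metric")
  expect_error(paired_sign_test(1, 0), class = "epideep_metric")

  # tail consistency: P(X >= k) + P(X <= k-1) = 1
  for (k in 1:15) {
    expect_equal(paired_sign_test(k, 15) +
                   sum(choose(15, 0:(k - 1))) / 2^15, 1.0)
  }
})

test_that("one-sided rank-sum test matches exact enumeration and wilcox.test", {
  expect_equal(wilcoxon_rank_sum_one_sided(c(5, 6, 7), c(1, 2, 3)), 1 / 20)
  # extreme opposite ordering: every permutation is at least as extreme
  expect_equal(wilcoxon_rank_sum_one_sided(c(1, 2, 3), c(5, 6, 7)), 1.0)
  expect_equal(wilcoxon_rank_sum_one_sided(c(0.9), c(0.1)), 0.5)
  # identical multisets: with average ranks, 14 of the 20 assignments have a
  # rank sum at least as large as the observed one
  tied <- wilcoxon_rank_sum_one_sided(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tied, 14 / 20)
  expect_error(wilcoxon_rank_sum_one_sided(numeric(0), 1),
               class = "epideep_metric")

  # small tie-free samples agree exactly with the standard implementation
  set.seed(23)
  for (rep in 1:20) {
    x <- runif(sample(2:8, 1))
    y <- runif(sample(2:8, 1))
    expect_equal(wilcoxon_rank_sum_one_sided(x, y),
                 wilcox.test(x, y, alternative = "greater",
                             exact = TRUE)$p.value)
  }
  # large samples use the tie-corrected normal approximation
  for (rep in 1:10) {
    x <- round(rnorm(30, 0.3), 1)
    y <- round(rnorm(25), 1)
    expect_equal(wilcoxon_rank_sum_one_sided(x, y),
                 suppressWarnings(
                   wilcox.test(x, y, alternative = "greater",
                               exact = FALSE, correct = TRUE)$p.value),
                 tolerance = 1e-8)
  }
})

test_that("collective scoring averages fold models then epigenomes", {
  ds <- tiny_dataset(n = 4, seed = 30)
  cm <- epideep:::rows_to_cmat(ds, 1:4)
  batch <- dataset_batch(ds, 1:4)

  const_model <- function(bias) {
    m <- build_network(tiny_spec(), seed = 1)
    m$params$head$fc2$W[] <- 0
    m$params$head$fc2$b[] <- bias
    m
  }
  logit <- function(p) log(p / (1 - p))

  e1 <- list(const_model(logit(0.8)), const_model(logit(0.8)))
  expect_equal(unname(collective_predict(list(e1), batch)),
               matrix(0.8, 4, 3), tolerance = 1e-6)

  e2 <- list(const_model(logit(0.2)))
  two <- collective_predict(list(e1, e2), batch)
  expect_equal(unname(two), matrix(0.5, 4, 3), tolerance = 1e-6)
  expect_equal(collective_predict(list(e2, e1), batch), two)

  # bounded by the contributing models' outputs
  set.seed(31)
  real <- list(list(build_network(tiny_spec(), 2)),
               list(build_network(tiny_spec(), 3)))
  preds <- lapply(real, function(e) predict(e[[1]], cm))
  cp <- collective_predict(real, cm)
  expect_true(all(cp <= pmax(preds[[1]], preds[[2]]) + 1e-12))
  expect_true(all(cp >= pmin(preds[[1]], preds[[2]]) - 1e-12))

  expect_error(collective_predict(list(), batch), class = "epideep_config")
})

test_that("method comparison counts wins and applies the exact sign test", {
  epis <- paste0("E", 1:15)
  a <- tidyr::expand_grid(epigenome = epis, marker = c("m1", "m2"))
  a$auroc <- 0.9
  b <- a
  b$auroc <- 0.8
  b$auroc[b$marker == "m2"] <- c(rep(0.95, 7), rep(0.8, 8))
  rep <- compare_methods(a, b)
  expect_equal(rep$wins[rep$marker == "m1"], 15L)
  expect_equal(rep$p_value[rep$marker == "m1"], 2^-15)
  expect_equal(rep$wins[rep$marker == "m2"], 8L)
  expect_equal(rep$p_value[rep$marker == "m2"], 0.5)

  # exact ties are dropped with n reduced
  b2 <- a
  b2$auroc[1:2] <- 0.9
  rep2 <- compare_methods(a, b2)
  expect_true(all(rep2$n < 15))
})

test_that("metric reports are tidy tibbles", {
  fake <- list(oof = matrix(runif(20), 10, 2,
                            dimnames = list(NULL, c("m1", "m2"))),
               labels = cbind(m1 = rep(c(1L, 0L), 5), m2 = rep(c(0L, 1L), 5)),
               epigenome_id = "E7")
  m <- cv_metrics(fake)
  expect_s3_class(m, "tbl_df")
  expect_equal(m$epigenome, c("E7", "E7"))
  expect_equal(m$n_pos, c(5L, 5L))
  f <- withr::local_tempfile()
  write_metrics(m, f)
  expect_equal(nrow(utils::read.table(f, header = TRUE, sep = "\t")), 2L)
})
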