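truth_set <- function(starts, ends, chrom = "chr1") {
  tibble::tibble(chrom = chrom, ref_start = as.integer(starts),
                 ref_end = as.integer(ends))
}

test_that("insertion matching honours the 50-bp tolerance", {
  truth <- truth_set(1000, 2000)
  expect_equal(match_insertions(truth, truth_set(1030, 1980)),
               tibble::tibble(tp = 1L, fp = 0L, fn = 0L))
  expect_equal(match_insertions(truth, truth_set(1060, 2000)),
               tibble::tibble(tp = 0L, fp = 1L, fn = 1L))
  expect_equal(match_insertions(truth, truth_set(1000, 2000, chrom = "chr2")),
               tibble::tibble(tp = 0L, fp = 1L, fn = 1L))
  perfect <- truth_set(c(100, 5000), c(400, 5600))
  expect_equal(match_insertions(perfect, perfect),
               tibble::tibble(tp = 2L, fp = 0L, fn = 0L))
})

test_that("matching is one-to-one and order-invariant", {
  set.seed(71)
  truth <- truth_set(c(1000, 1010, 8000), c(1500, 1510, 8900))
  calls <- truth_set(c(1005, 8010), c(1505, 8895))
  base <- match_insertions(truth, calls)
  expect_equal(base, tibble::tibble(tp = 2L, fp = 0L, fn = 1L))
  for (i in 1:5) {
    expect_equal(match_insertions(truth[sample(3), ], calls[sample(2), ]),
                 base)
  }
})

test_that("the size floor drops sub-threshold truths and excuses their calls", {
  truth <- truth_set(c(1000, 5000), c(1030, 6000))  # 30 bp and 1000 bp
  calls <- truth_set(c(1002, 5004), c(1031, 5996))
  raw <- match_insertions(truth, calls, min_size = 0)
  expect_equal(raw$tp, 2L)
  flt <- match_insertions(truth, calls, min_size = 50)
  expect_equal(flt, tibble::tibble(tp = 1L, fp = 0L, fn = 0L))
  # an unmatched small call is not penalised either
  flt2 <- match_insertions(truth_set(5000, 6000), truth_set(c(5004, 900), c(5996, 930)),
                           min_size = 50)
  expect_equal(flt2, tibble::tibble(tp = 1L, fp = 0L, fn = 0L))
})

test_that("precision/recall/F1 follow their formulas with NA for 0/0", {
  expect_equal(prf(3, 1, 0)[c("precision", "recall", "f1")],
               tibble::tibble(precision = 0.75, recall = 1, f1 = 6 / 7))
  z <- prf(0, 0, 5)
  expect_true(is.na(z$precision))
  expect_equal(z$recall, 0)
  expect_equal(prf(4, 4, 4)[c("precision", "recall", "f1")],
               tibble::tibble(precision = 0.5, recall = 0.5, f1 = 0.5))
  all_zero <- prf(0, 0, 0)
  expect_true(all(is.na(c(all_zero$precision, all_zero$recall, all_zero$f1))))
})

test_that("f1 is the harmonic mean of precision and recall when both defined", {
  set.seed(72)
  for (i in 1:50) {
    x <- prf(sample(0:20, 1), sample(0:20, 1), sample(0:20, 1))
    if (!is.na(x$precision) && !is.na(x$recall) &&
        (x$precision + x$recall) > 0) {
      expect_equal(x$f1,
                   2 * x$precision * x$recall / (x$precision + x$recall),
                   tolerance = 1e-12)
    }
    expect_true(all(dplyr::between(
      c(x$precision, x$recall, x$f1)[!is.na(c(x$precision, x$recall, x$f1))],
      0, 1)))
  }
})

test_that("spurious calls never raise precision; dropped correct calls never raise recall", {
  set.seed(73)
  truth <- truth_set(seq(1000, 9000, by = 2000), seq(1500, 9500, by = 2000))
  calls <- truth
  base <- prf(match_insertions(truth, calls)$tp,
              match_insertions(truth, calls)$fp,
              match_insertions(truth, calls)$fn)
  spurious <- dplyr::bind_rows(calls, truth_set(20000, 20500))
  with_sp <- match_insertions(truth, spurious)
  expect_lte(prf(with_sp$tp, with_sp$fp, with_sp$fn)$precision,
             base$precision)
  dropped <- match_insertions(truth, calls[-2, ])
  expect_lte(prf(dropped$tp, dropped$fp, dropped$fn)$recall, base$recall)
})

test_that("read-level benchmarking pools counts and reports count agreement", {
  set.seed(74)
  ins <- tibble::tibble(chrom = "chr1", ref_start = c(1000L, 4000L),
                        ref_end = c(1800L, 4900L), strand = c("+", "-"),
                        size = c(800L, 900L))
  id_good <- encode_truth_id("event0001", ins, 1L)
  id_miss <- encode_truth_id("event0001", ins, 2L)
  segs <- dplyr::bind_rows(
    make_chain(id_good, c(300L, 800L, 900L, 300L),
               chroms = c("sub1", "chr1", "chr1", "sub2"),
               ref_starts = c(0L, 1000L, 4000L, 0L)),
    make_chain(id_miss, c(300L, 800L, 300L),
               chroms = c("sub1", "chr1", "sub2"),
               ref_starts = c(0L, 1000L, 0L))
  )
  bm <- benchmark_insertions(annotate_events(segs))
  s <- bm$summary[bm$summary$scope == "size_filtered", ]
  expect_equal(c(s$tp, s$fp, s$fn), c(3L, 0L, 1L))
  expect_equal(s$recall, 0.75)
  expect_equal(s$precision, 1)
  expect_equal(bm$agreement$rate, 0.5)
  td <- tidy(bm)
  expect_equal(nrow(td), 2L)
  g <- glance(bm)
  expect_equal(g$f1, 2 * 3 / (2 * 3 + 0 + 1))
})

test_that("cluster benchmarking scores identity, splits and merges as expected", {
  truth <- dplyr::bind_rows(
    tibble::tibble(read_id = sprintf("event0001|n=0||read%d", 1:4),
                   cluster_true = "event0001"),
    tibble::tibble(read_id = sprintf("event0002|n=0||read%d", 1:4),
                   cluster_true = "event0002"))

  identical_cl <- tibble::tibble(
    read_id = truth$read_id,
    cluster_id = rep(1:2, each = 4), n_members = 4L,
    is_representative = FALSE)
  bi <- benchmark_clusters(identical_cl)
  expect_equal(bi$summary[c("precision", "recall", "f1")],
               tibble::tibble(precision = 1, recall = 1, f1 = 1))

  split_cl <- identical_cl
  split_cl$cluster_id <- c(1L, 1L, 3L, 3L, 2L, 2L, 2L, 2L)
  bs <- benchmark_clusters(split_cl)
  ev1 <- bs$per_cluster[bs$per_cluster$event_id == "event0001", ]
  expect_equal(ev1$tp, 2L)
  expect_equal(ev1$fn, 2L)  # recall 0.5 for the split cluster
  expect_equal(ev1$fp, 0L)

  merged_cl <- identical_cl
  merged_cl$cluster_id <- 1L
  bmg <- benchmark_clusters(merged_cl)
  expect_true(all(bmg$per_cluster$fp > 0L | bmg$per_cluster$tp == 0L))
  expect_lt(bmg$summary$precision, 1)
  expect_equal(bmg$summary$recall, 0.5)  # one event pairs, one left out
})

test_that("expected-vs-observed tables degrade under systematic perturbation", {
  set.seed(75)
  ins <- tibble::tibble(chrom = "chr1", ref_start = 1000L, ref_end = 2000L,
                        strand = "+", size = 1000L)
  ids <- vapply(1:10, function(i) encode_truth_id(sprintf("event%04d", i), ins, 1L), "")
  good <- purrr::map_dfr(ids, ~ make_chain(.x, c(300L, 1000L, 300L),
                                           chroms = c("s1", "chr1", "s2"),
                                           ref_starts = c(0L, 1000L, 0L)))
  bm_good <- benchmark_insertions(annotate_events(good))
  expect_equal(bm_good$agreement$rate, 1)
  tab <- expected_vs_observed(bm_good)
  expect_equal(tab$n_true, rep(1L, 10))
  expect_equal(tab$n_called, rep(1L, 10))

  # inject an extra spurious insertion into every read
  bad <- purrr::map_dfr(ids, ~ make_chain(.x, c(300L, 1000L, 400L, 300L),
                                          chroms = c("s1", "chr1", "chr2", "s2"),
                                          ref_starts = c(0L, 1000L, 5000L, 0L)))
  bm_bad <- benchmark_insertions(annotate_events(bad))
  expect_equal(bm_bad$agreement$rate, 0)
  expect_lt(bm_bad$summary$precision[1], 1)
})

test_that("insertion-free truth events stay clean in a noiseless pipeline", {
  id0 <- encode_truth_id("event0001",
                         tibble::tibble(chrom = character(),
                                        ref_start = integer(),
                                        ref_end = integer(),
                                        strand = character(),
                                        size = integer()), 1L)
  segs <- make_chain(id0, c(400L, 400L), chroms = c("s1", "s2"))
  bm <- benchmark_insertions(annotate_events(segs))
  expect_equal(bm$summary$tp[1], 0L)
  expect_equal(bm$summary$fp[1], 0L)
  expect_equal(bm$summary$fn[1], 0L)
  expect_equal(bm$agreement$rate, 1)
})
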