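# identical complex events at distinct loci, for graph tests
clique_segments <- function(n, prefix = "r", ref_offset = 0L) {
  purrr::map_dfr(seq_len(n), function(i) {
    make_chain(sprintf("%s%03d", prefix, i), c(400L, 300L, 250L, 400L),
               chroms = c("chr1", "chr2", "chr1", "chr2"),
               ref_starts = c(0L, 5000L, 9000L, 14000L) + ref_offset)
  })
}

test_that("only reads with three or more alignments are clusterable", {
  segs <- dplyr::bind_rows(
    make_chain("two", c(300L, 300L)),
    make_chain("three", c(300L, 200L, 300L)),
    make_chain("many", rep(150L, 17))
  )
  cl <- select_clusterable(annotate_events(segs))
  expect_false("two" %in% cl$read_id)
  expect_equal(sum(cl$read_id == "three"), 1L)
  expect_equal(sum(cl$read_id == "many"), 15L)  # flanks removed
})

test_that("candidate retrieval requires 80% reciprocal overlap", {
  base <- annotate_events(dplyr::bind_rows(
    make_chain("a", c(300L, 1000L, 300L), ref_starts = c(0L, 0L, 8000L)),
    make_chain("b", c(300L, 1000L, 300L), ref_starts = c(0L, 500L, 8000L)),
    make_chain("c", c(300L, 900L, 300L), ref_starts = c(0L, 100L, 8000L))
  ))
  ins <- select_clusterable(base) %>%
    dplyr::group_by(read_id) %>%
    dplyr::mutate(.idx = dplyr::row_number()) %>%
    dplyr::ungroup()
  hits <- telofuse:::.insertion_hits(ins, fusion_config())
  pair_ab <- hits[hits$read_a == "a" & hits$read_b == "b", ]
  pair_ac <- hits[hits$read_a == "a" & hits$read_b == "c", ]
  expect_equal(nrow(pair_ab), 0L)  # reciprocal overlap 0.5
  expect_equal(nrow(pair_ac), 1L)  # reciprocal overlap 0.89
})

test_that("the pair prefilter applies the 25% count and 4% length rules", {
  expect_true(prefilter_pair(4, 5, 10000, 10000))   # 20% count diff
  expect_false(prefilter_pair(4, 6, 10000, 10000))  # 33% count diff
  expect_false(prefilter_pair(4, 4, 10000, 10500))  # 4.8% length diff
  expect_true(prefilter_pair(4, 4, 10000, 10400))   # 4.0% exactly
})

test_that("insertion-set Jaccard follows set arithmetic with overlap equivalence", {
  set3 <- tibble::tibble(chrom = "chr1",
                         ref_start = c(0L, 5000L, 9000L),
                         ref_end = c(400L, 5400L, 9400L))
  expect_equal(insertion_jaccard(set3, set3), 1)
  other <- dplyr::mutate(set3, ref_start = ref_start + 20000L,
                         ref_end = ref_end + 20000L)
  expect_equal(insertion_jaccard(set3[1:2, ], other[1:2, ]), 0)
  # share exactly two equivalent members: J = 2 / (3 + 3 - 2)
  mix <- dplyr::bind_rows(set3[1:2, ], other[1, ])
  expect_equal(insertion_jaccard(set3, mix), 0.5)
  expect_equal(insertion_jaccard(mix, set3), 0.5)  # symmetric
  expect_equal(insertion_jaccard(set3[0, ], set3[0, ]), 0)
})

test_that("jaccard stays in [0,1] and J(A,A)=1 on random sets", {
  set.seed(51)
  for (i in 1:30) {
    n <- sample(1:6, 1)
    a <- tibble::tibble(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                        ref_start = sample.int(30000L, n))
    a$ref_end <- a$ref_start + sample(100:900, n, replace = TRUE)
    m <- sample(1:6, 1)
    b <- tibble::tibble(chrom = sample(c("chr1", "chr2"), m, replace = TRUE),
                        ref_start = sample.int(30000L, m))
    b$ref_end <- b$ref_start + sample(100:900, m, replace = TRUE)
    j <- insertion_jaccard(a, b)
    expect_gte(j, 0); expect_lte(j, 1)
    expect_equal(insertion_jaccard(b, a), j)
    expect_equal(insertion_jaccard(a, a), 1)
  }
})

test_that("edge thresholds follow the set-size table", {
  expect_equal(edge_threshold(1), 1)
  expect_equal(edge_threshold(2), 1)
  expect_equal(edge_threshold(3), 0.66)
  expect_equal(edge_threshold(5), 0.66)
  expect_equal(edge_threshold(6), 0.5)
  expect_equal(edge_threshold(9), 0.5)
  expect_error(edge_threshold(0), ">= 1")
})

test_that("identical events form one cluster; distinct groups stay apart", {
  cl5 <- cluster_events(annotate_events(clique_segments(5)))
  expect_equal(length(unique(cl5$cluster_id)), 1L)
  expect_equal(unique(cl5$n_members), 5L)

  two_groups <- annotate_events(dplyr::bind_rows(
    clique_segments(4, prefix = "g1_"),
    clique_segments(4, prefix = "g2_", ref_offset = 2500L)))
  cl <- cluster_events(two_groups)
  expect_equal(length(unique(cl$cluster_id)), 2L)
  by_group <- split(cl$cluster_id, substr(cl$read_id, 1, 2))
  expect_equal(length(unique(by_group$g1)), 1L)
  expect_equal(length(unique(by_group$g2)), 1L)
})

test_that("a 30-read clique survives the 10-edge cap through transitivity", {
  cl <- cluster_events(annotate_events(clique_segments(30)))
  expect_equal(length(unique(cl$cluster_id)), 1L)
  expect_equal(unique(cl$n_members), 30L)
  edges <- attr(cl, "edges")
  # every kept edge is among the top-cap edges of at least one endpoint
  cap <- fusion_config()$max_edges_per_node
  rank_in <- function(node, other) {
    inc <- edges[edges$read_a == node | edges$read_b == node, ]
    partners <- ifelse(inc$read_a == node, inc$read_b, inc$read_a)
    ord <- order(-inc$jaccard, partners)
    which(partners[ord] == other)[1]
  }
  for (r in seq_len(nrow(edges))) {
    expect_true(rank_in(edges$read_a[r], edges$read_b[r]) <= cap ||
                  rank_in(edges$read_b[r], edges$read_a[r]) <= cap)
  }
})

test_that("the edge cap never changes components when groups have <= cap+1 members", {
  set.seed(52)
  segs <- purrr::map_dfr(1:4, function(g) {
    clique_segments(sample(2:11, 1), prefix = sprintf("g%d_", g),
                    ref_offset = g * 2200L)
  })
  ann <- annotate_events(segs)
  capped <- cluster_events(ann)
  uncapped <- cluster_events(ann, fusion_config(max_edges_per_node = 1000))
  part <- function(cl) {
    unname(lapply(split(cl$read_id, cl$cluster_id), sort))
  }
  expect_setequal(part(capped), part(uncapped))
})

test_that("cluster assignment partitions the clusterable reads", {
  set.seed(53)
  segs <- dplyr::bind_rows(
    clique_segments(6, prefix = "a"),
    clique_segments(3, prefix = "b", ref_offset = 2500L),
    make_chain("lone", c(300L, 250L, 300L),
               ref_starts = c(0L, 17000L, 8000L))
  )
  ann <- annotate_events(segs)
  cl <- cluster_events(ann)
  clusterable <- unique(select_clusterable(ann)$read_id)
  expect_setequal(cl$read_id, clusterable)
  expect_equal(anyDuplicated(cl$read_id), 0L)
  # the lone read is a singleton with its own cluster id
  lone <- cl[cl$read_id == "lone", ]
  expect_equal(lone$n_members, 1L)
})

test_that("representatives maximise score per aligned base with read-id tie-break", {
  segs <- dplyr::bind_rows(
    make_chain("hi", c(300L, 200L, 300L)),
    make_chain("lo", c(300L, 200L, 300L))
  )
  segs$score[segs$read_id == "hi"] <- segs$aligned_bases[segs$read_id == "hi"] * 1.8
  segs$score[segs$read_id == "lo"] <- segs$aligned_bases[segs$read_id == "lo"] * 1.6
  expect_equal(pick_representative(c("hi", "lo"), segs), "hi")
  tied <- dplyr::mutate(segs, score = aligned_bases * 2)
  expect_equal(pick_representative(c("hi", "lo"), tied), "hi")  # lexicographic
  expect_equal(pick_representative("lo", segs), "lo")

  ann <- annotate_events(segs)
  cl <- cluster_events(ann)
  expect_equal(cl$read_id[cl$is_representative], "hi")
})

test_that("cluster BED outputs split all reads and singletons", {
  set.seed(54)
  segs <- dplyr::bind_rows(
    clique_segments(3, prefix = "grp"),
    make_chain("solo", c(300L, 250L, 300L),
               ref_starts = c(0L, 17000L, 8000L))
  )
  ann <- annotate_events(segs)
  cl <- cluster_events(ann)
  all_bed <- tempfile(fileext = ".bed")
  single_bed <- tempfile(fileext = ".bed")
  write_cluster_beds(ann, cl, all_bed, single_bed)
  allb <- read_alignment_bed(all_bed)
  sing <- read_alignment_bed(single_bed)
  expect_setequal(unique(allb$read_id), c(sprintf("grp%03d", 1:3), "solo"))
  expect_equal(unique(sing$read_id), "solo")
  expect_true(all(!is.na(allb$cluster_id)))
})
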