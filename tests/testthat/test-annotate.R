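test_that("events are classed by insertion count: none, simple, complex", {
  segs <- dplyr::bind_rows(
    make_chain("two", c(500L, 500L)),
    make_chain("four", c(500L, 200L, 200L, 500L)),
    make_chain("five", c(500L, 200L, 200L, 200L, 500L))
  )
  ev <- event_table(annotate_events(segs))
  expect_equal(ev$complexity_class[ev$read_id == "two"], "no_insertion")
  expect_equal(ev$n_insertions[ev$read_id == "two"], 0L)
  expect_equal(ev$complexity_class[ev$read_id == "four"], "simple")
  expect_equal(ev$n_insertions[ev$read_id == "four"], 2L)
  expect_equal(ev$complexity_class[ev$read_id == "five"], "complex")
  expect_equal(ev$n_insertions[ev$read_id == "five"], 3L)
})

test_that("complexity thresholds are exactly {0}, {1,2}, {>=3}", {
  got <- complexity_class(0:20)
  expect_equal(got[1], "no_insertion")
  expect_equal(got[2:3], c("simple", "simple"))
  expect_equal(got[4:21], rep("complex", 18))
})

test_that("flank/insertion roles follow query order", {
  ann <- annotate_events(make_chain("r", c(400L, 100L, 300L)))
  expect_equal(ann$role, c("flank", "insertion", "flank"))
  single <- annotate_events(make_segment("s", 0, 500))
  expect_equal(single$role, "unassigned")
  expect_false(single$is_fusion)
})

test_that("junctions are typed from adjacent query intervals", {
  expect_equal(classify_junction(100, 97), tibble::tibble(kind = "microhomology", size = 3L))
  expect_equal(classify_junction(100, 100), tibble::tibble(kind = "blunt", size = 0L))
  expect_equal(classify_junction(100, 112), tibble::tibble(kind = "insertion_gap", size = 12L))
})

test_that("junction kinds partition every consecutive pair", {
  set.seed(41)
  for (i in 1:40) {
    n <- sample(2:8, 1)
    offsets <- sample(c(-15:15), n - 1, replace = TRUE)
    ann <- annotate_events(make_chain("r", rep(200L, n), offsets = offsets))
    jn <- ann$junction_kind[!is.na(ann$junction_kind)]
    expect_equal(length(jn), n - 1L)
    expect_true(all(jn %in% c("microhomology", "blunt", "insertion_gap")))
    # sizes match the constructed offsets
    expect_equal(ann$junction_size[!is.na(ann$junction_size)], abs(offsets))
    expect_equal(jn == "blunt", offsets == 0)
    expect_equal(jn == "microhomology", offsets > 0)
  }
})

test_that("origin classification is a catalogue lookup that fails on unknown contigs", {
  catalogue <- tibble::tibble(
    chrom = c("chr8", "TALEN_L1", "chrM"),
    origin = c("chromosomal", "external_plasmid", "mitochondrial"))
  segs <- dplyr::bind_rows(
    make_segment("r", 0, 100, chrom = "chr8"),
    make_segment("r", 100, 200, chrom = "TALEN_L1"),
    make_segment("r", 200, 300, chrom = "chrM"))
  out <- classify_origins(segs, catalogue)
  expect_equal(out$origin, c("chromosomal", "external_plasmid", "mitochondrial"))
  expect_error(
    classify_origins(make_segment("r", 0, 100, chrom = "weird"), catalogue),
    "weird")
})

test_that("hotspots group insertions within 10 kb and flag overlapping members", {
  two <- tibble::tibble(chrom = "chr5",
                        ref_start = c(1000L, 6000L),
                        ref_end = c(1200L, 6300L))
  h <- detect_hotspots(two)
  expect_equal(nrow(h), 1L)
  expect_equal(h$n_members, 2L)
  expect_false(h$overlapping)

  three <- tibble::tibble(chrom = "chr17",
                          ref_start = rep(10000L, 3),
                          ref_end = rep(10500L, 3))
  h3 <- detect_hotspots(three)
  expect_equal(h3$n_members, 3L)
  expect_true(h3$overlapping)

  apart <- tibble::tibble(chrom = "chr1",
                          ref_start = c(0L, 15200L),
                          ref_end = c(200L, 15400L))
  expect_equal(nrow(detect_hotspots(apart)), 0L)
})

test_that("hotspot grouping is order-invariant and assigns each insertion at most once", {
  set.seed(42)
  ins <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
    ref_start = sample.int(60000L, 40))
  ins$ref_end <- ins$ref_start + sample(50:2000, 40, replace = TRUE)
  base <- detect_hotspots(ins)
  for (i in 1:5) {
    perm_idx <- sample(nrow(ins))
    perm <- detect_hotspots(ins[perm_idx, ])
    expect_equal(perm[c("chrom", "span_start", "span_end", "n_members",
                        "overlapping")],
                 base[c("chrom", "span_start", "span_end", "n_members",
                        "overlapping")])
  }
  members <- unlist(base$members)
  expect_equal(anyDuplicated(members), 0L)
})

test_that("foldbacks require the same locus in opposite orientations", {
  fb <- annotate_events(dplyr::bind_rows(
    make_segment("r", 0, 500, chrom = "chr8", ref_start = 100, ref_end = 600,
                 strand = "+"),
    make_segment("r", 500, 1000, chrom = "chr8", ref_start = 120,
                 ref_end = 620, strand = "-")))
  hits <- detect_foldbacks(fb)
  expect_equal(nrow(hits), 1L)
  expect_gte(hits$reciprocal_overlap, 0.8)

  same_strand <- annotate_events(dplyr::bind_rows(
    make_segment("r", 0, 500, chrom = "chr8", ref_start = 100, ref_end = 600),
    make_segment("r", 500, 1000, chrom = "chr8", ref_start = 120,
                 ref_end = 620)))
  expect_equal(nrow(detect_foldbacks(same_strand)), 0L)

  diff_chrom <- annotate_events(dplyr::bind_rows(
    make_segment("r", 0, 500, chrom = "chr1", ref_start = 100, ref_end = 600,
                 strand = "+"),
    make_segment("r", 500, 1000, chrom = "chr2", ref_start = 100,
                 ref_end = 600, strand = "-")))
  expect_equal(nrow(detect_foldbacks(diff_chrom)), 0L)
})

test_that("summary tables recover a known class mixture exactly", {
  segs <- dplyr::bind_rows(
    purrr::map_dfr(1:10, ~ make_chain(paste0("none", .x), c(400L, 400L))),
    purrr::map_dfr(1:6, ~ make_chain(paste0("simple", .x),
                                     c(400L, 150L, 400L))),
    purrr::map_dfr(1:4, ~ make_chain(paste0("cx", .x),
                                     c(400L, 150L, 150L, 150L, 400L)))
  )
  summ <- summarise_events(annotate_events(segs))
  cx <- summ$complexity
  expect_equal(cx$proportion[cx$complexity_class == "no_insertion"], 0.5)
  expect_equal(cx$proportion[cx$complexity_class == "simple"], 0.3)
  expect_equal(cx$proportion[cx$complexity_class == "complex"], 0.2)
  counts <- summ$alignment_counts
  expect_equal(counts$n_reads[counts$n_alignments == 2], 10L)
  expect_equal(counts$n_reads[counts$n_alignments == 5], 4L)
})

test_that("a degenerate two-alignment corpus is 100% insertion-free", {
  segs <- purrr::map_dfr(1:10, ~ make_chain(paste0("r", .x), c(300L, 300L)))
  summ <- summarise_events(annotate_events(segs))
  expect_equal(summ$complexity$proportion, 1)
  expect_equal(summ$complexity$complexity_class, "no_insertion")
})

test_that("junction medians equal a sort-based median oracle", {
  set.seed(43)
  offsets <- sample(1:9, 11, replace = TRUE)  # all microhomology
  segs <- make_chain("r", rep(120L, 12), offsets = offsets)
  summ <- summarise_events(annotate_events(segs))
  med_oracle <- sort(offsets)[(length(offsets) + 1) %/% 2]
  expect_equal(attr(summ$junctions, "microhomology_median"), med_oracle)
  jt <- summ$junctions
  expect_equal(jt$proportion[jt$junction_kind == "microhomology"], 1)
})
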