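#' Complexity class from insertion count
#'
#' Fusion molecules are classed by the number of inserted segments between
#' the two sub-telomeric flanks: none, simple (1 or 2) or complex (3 or
#' more).
#'
#' @param n_insertions Integer vector.
#' @return Character vector: `no_insertion`, `simple`, or `complex`.
#' @export
complexity_class <- function(n_insertions) {
  dplyr::case_when(
    n_insertions == 0L ~ "no_insertion",
    n_insertions <= 2L ~ "simple",
    TRUE ~ "complex"
  )
}

#' Type the junction between two consecutive alignments
#'
#' Junction typing is a relation between adjacent query intervals of one
#' read: an overlap of `k > 0` bases is microhomology of size `k` (the two
#' joined ends share sequence that aligns to both loci); contiguity is a
#' blunt junction; a gap is unaligned sequence at the join (an untemplated
#' or unmappable insertion), typed `insertion_gap` with the gap size.
#'
#' @param left_query_end,right_query_start Query coordinates (0-based
#'   half-open) of the two adjacent segments; vectorised.
#' @return A tibble with columns `kind` and `size`.
#' @examples
#' classify_junction(100, 97)   # microhomology of 3
#' classify_junction(100, 100)  # blunt
#' classify_junction(100, 112)  # insertion_gap of 12
#' @export
classify_junction <- function(left_query_end, right_query_start) {
  k <- left_query_end - right_query_start
  tibble::tibble(
    kind = dplyr::case_when(
      k > 0 ~ "microhomology",
      k == 0 ~ "blunt",
      TRUE ~ "insertion_gap"
    ),
    size = abs(as.integer(k))
  )
}

#' Annotate selected alignments into fusion events
#'
#' Orders each read's chosen segments along the query, marks the first and
#' last as sub-telomeric flanks and the interior as insertions, types every
#' junction between consecutive segments, and attaches per-read event
#' attributes (alignment count, insertion count, complexity class). Reads
#' with a single alignment are not fusions; they are retained with role
#' `unassigned` and `is_fusion = FALSE` so they can be reported separately.
#'
#' @param segments Selected segment tibble ([select_alignments()]).
#' @return The segment tibble with added columns `segment_index`, `role`,
#'   `junction_kind`, `junction_size` (junction to the next segment; `NA` on
#'   each read's last segment), `n_alignments`, `n_insertions`,
#'   `complexity_class`, `is_fusion`.
#' @export
annotate_events <- function(segments) {
  if (!nrow(segments)) {
    out <- segments
    out$segment_index <- integer()
    out$role <- character()
    out$junction_kind <- character()
    out$junction_size <- integer()
    out$n_alignments <- integer()
    out$n_insertions <- integer()
    out$complexity_class <- character()
    out$is_fusion <- logical()
    return(out)
  }
  segments %>%
    dplyr::group_by(.data$read_id) %>%
    dplyr::arrange(.data$query_start, .by_group = TRUE) %>%
    dplyr::mutate(
      segment_index = dplyr::row_number(),
      n_alignments = dplyr::n(),
      role = dplyr::case_when(
        .data$n_alignments == 1L ~ "unassigned",
        .data$segment_index %in% c(1L, .data$n_alignments) ~ "flank",
        TRUE ~ "insertion"
      ),
      junction_kind = dplyr::if_else(
        .data$segment_index < .data$n_alignments,
        classify_junction(.data$query_end,
                          dplyr::lead(.data$query_start))$kind,
        NA_character_
      ),
      junction_size = dplyr::if_else(
        .data$segment_index < .data$n_alignments,
        classify_junction(.data$query_end,
                          dplyr::lead(.data$query_start))$size,
        NA_integer_
      ),
      n_insertions = pmax(.data$n_alignments - 2L, 0L),
      complexity_class = complexity_class(.data$n_insertions),
      is_fusion = .data$n_alignments >= 2L
    ) %>%
    dplyr::ungroup()
}

#' Per-read event table
#'
#' Collapses an annotated segment tibble to one row per read.
#'
#' @param annotated Output of [annotate_events()].
#' @return A tibble: `read_id`, `n_alignments`, `n_insertions`,
#'   `complexity_class`, `is_fusion`, `query_span` (bp from first segment
#'   start to last segment end).
#' @export
event_table <- function(annotated) {
  annotated %>%
    dplyr::group_by(.data$read_id) %>%
    dplyr::summarise(
      n_alignments = dplyr::first(.data$n_alignments),
      n_insertions = dplyr::first(.data$n_insertions),
      complexity_class = dplyr::first(.data$complexity_class),
      is_fusion = dplyr::first(.data$is_fusion),
      query_span = max(.data$query_end) - min(.data$query_start),
      .groups = "drop"
    )
}

#' Classify the origin of each segment
#'
#' Joins segments against a reference catalogue tagging every contig as
#' `chromosomal`, `external_plasmid`, `external_ecoli` or `mitochondrial`.
#'
#' @param segments A segment tibble.
#' @param catalogue A tibble with columns `chrom` and `origin`.
#' @return `segments` with an `origin` column.
#' @export
classify_origins <- function(segments, catalogue) {
  out <- dplyr::left_join(segments, catalogue, by = "chrom")
  if (anyNA(out$origin)) {
    missing <- unique(out$chrom[is.na(out$origin)])
    stop("reference name(s) missing from catalogue: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out
}

#' Detect insertion hotspots within an event
#'
#' Groups the insertions of one fusion molecule by single-linkage on the
#' reference: two insertions on the same chromosome belong to the same
#' hotspot when the gap between their reference intervals is at most
#' `window` bp. Only groups with two or more members are hotspots; a
#' hotspot is flagged `overlapping` when at least two members' intervals
#' share at least one base, the signature of repeated replication of the
#' locus.
#'
#' @param insertions Tibble of one event's insertions (`chrom`,
#'   `ref_start`, `ref_end`).
#' @param window Linkage distance (bp).
#' @return A tibble: `hotspot_id`, `chrom`, `span_start`, `span_end`,
#'   `n_members`, `overlapping`, `members` (list-column of row indices into
#'   `insertions`).
#' @export
detect_hotspots <- function(insertions, window = 10000) {
  if (!nrow(insertions)) {
    return(tibble::tibble(hotspot_id = integer(), chrom = character(),
                          span_start = integer(), span_end = integer(),
                          n_members = integer(), overlapping = logical(),
                          members = list()))
  }
  ins <- dplyr::mutate(insertions, .row = dplyr::row_number())
  out <- list()
  for (cm in unique(ins$chrom)) {
    sub <- dplyr::arrange(dplyr::filter(ins, .data$chrom == cm),
                          .data$ref_start, .data$ref_end)
    run_max_end <- cummax(sub$ref_end)
    new_grp <- c(TRUE, sub$ref_start[-1] - run_max_end[-nrow(sub)] > window)
    grp <- cumsum(new_grp)
    for (g in unique(grp)) {
      m <- sub[grp == g, ]
      if (nrow(m) < 2L) next
      pairs <- utils::combn(nrow(m), 2L)
      ovl <- any(pmin(m$ref_end[pairs[1, ]], m$ref_end[pairs[2, ]]) -
                   pmax(m$ref_start[pairs[1, ]], m$ref_start[pairs[2, ]]) >= 1L)
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = cm, span_start = min(m$ref_start), span_end = max(m$ref_end),
        n_members = nrow(m), overlapping = ovl, members = list(m$.row))
    }
  }
  if (!length(out)) return(detect_hotspots(insertions[0, ]))
  dplyr::bind_rows(out) %>%
    dplyr::arrange(.data$chrom, .data$span_start) %>%
    dplyr::mutate(hotspot_id = dplyr::row_number(), .before = 1)
}

# reciprocal overlap of two interval sets (vectorised over pairs)
.reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  pmin(ov / (e1 - s1), ov / (e2 - s2))
}

#' Detect foldback segment pairs within events
#'
#' A foldback is a pair of segments of one molecule mapping to (nearly) the
#' same reference interval in opposite orientations -- the signature of
#' intra-strand fold-back-primed synthesis. Pairs require reciprocal
#' overlap of at least `config$foldback_overlap` on the same chromosome and
#' opposite strands.
#'
#' @param annotated Annotated segment tibble for one or more reads.
#' @param config A [fusion_config()].
#' @return A tibble: `read_id`, `segment_index_1`, `segment_index_2`,
#'   `chrom`, `reciprocal_overlap`.
#' @export
detect_foldbacks <- function(annotated, config = fusion_config()) {
  empty <- tibble::tibble(read_id = character(), segment_index_1 = integer(),
                          segment_index_2 = integer(), chrom = character(),
                          reciprocal_overlap = numeric())
  if (!nrow(annotated)) return(empty)
  pairs <- annotated %>%
    dplyr::inner_join(annotated, by = c("read_id", "chrom"),
                      suffix = c("_1", "_2"),
                      relationship = "many-to-many") %>%
    dplyr::filter(.data$segment_index_1 < .data$segment_index_2,
                  .data$strand_1 != .data$strand_2) %>%
    dplyr::mutate(reciprocal_overlap = .reciprocal_overlap(
      .data$ref_start_1, .data$ref_end_1,
      .data$ref_start_2, .data$ref_end_2)) %>%
    dplyr::filter(.data$reciprocal_overlap >= config$foldback_overlap)
  if (!nrow(pairs)) return(empty)
  dplyr::select(pairs, "read_id", "segment_index_1", "segment_index_2",
                "chrom", "reciprocal_overlap")
}

#' Summary analytics over annotated events
#'
#' The per-dataset tables behind the standard figures: the distribution of
#' alignments per molecule, complexity-class proportions, the junction
#' spectrum with the microhomology median, flank and insertion size
#' distributions, and (when a catalogue is supplied) per-contig origin
#' counts and the external-DNA fraction of insertions.
#'
#' @param annotated Annotated segment tibble ([annotate_events()]).
#' @param catalogue Optional origin catalogue (see [classify_origins()]).
#' @return A list of tibbles with class `"fusion_summary"`:
#'   `alignment_counts`, `complexity`, `junctions`, `sizes`, and (with a
#'   catalogue) `origins`, `external_fraction`.
#' @export
summarise_events <- function(annotated, catalogue = NULL) {
  ev <- event_table(annotated)
  fused <- dplyr::filter(ev, .data$is_fusion)
  alignment_counts <- dplyr::count(fused, .data$n_alignments, name = "n_reads")
  complexity <- fused %>%
    dplyr::count(.data$complexity_class, name = "n_reads") %>%
    dplyr::mutate(proportion = .data$n_reads / sum(.data$n_reads))
  jn <- dplyr::filter(annotated, !is.na(.data$junction_kind))
  junctions <- jn %>%
    dplyr::count(.data$junction_kind, name = "n_junctions") %>%
    dplyr::mutate(proportion = .data$n_junctions / sum(.data$n_junctions))
  mh <- dplyr::filter(jn, .data$junction_kind == "microhomology")
  attr(junctions, "microhomology_median") <-
    if (nrow(mh)) median(mh$junction_size) else NA_real_
  sizes <- annotated %>%
    dplyr::filter(.data$role %in% c("flank", "insertion")) %>%
    dplyr::group_by(.data$role) %>%
    dplyr::summarise(
      n = dplyr::n(),
      median_size = median(.data$ref_end - .data$ref_start),
      min_size = min(.data$ref_end - .data$ref_start),
      max_size = max(.data$ref_end - .data$ref_start),
      .groups = "drop"
    )
  out <- list(alignment_counts = alignment_counts, complexity = complexity,
              junctions = junctions, sizes = sizes)
  if (!is.null(catalogue)) {
    tagged <- classify_origins(annotated, catalogue)
    out$origins <- tagged %>%
      dplyr::filter(.data$role %in% c("flank", "insertion")) %>%
      dplyr::count(.data$role, .data$chrom, .data$origin, name = "n_segments")
    ins <- dplyr::filter(tagged, .data$role == "insertion")
    out$external_fraction <- tibble::tibble(
      n_insertions = nrow(ins),
      external = sum(startsWith(ins$origin, "external_")),
      fraction_external = ifelse(nrow(ins) > 0,
                                 sum(startsWith(ins$origin, "external_")) /
                                   nrow(ins), NA_real_)
    )
  }
  structure(out, class = c("fusion_summary", "list"))
}

#' @export
print.fusion_summary <- function(x, ...) {
  cat("<fusion_summary>\n")
  for (nm in names(x)) {
    cat("$", nm, "\n", sep = "")
    print(x[[nm]])
    cat("\n")
  }
  invisible(x)
}
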