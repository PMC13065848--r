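#' Select reads eligible for clustering
#'
#' Clustering operates on complex fusions only -- reads with three or more
#' alignments -- and on each read's insertion set (interior segments): the
#' first and last alignments are the PCR-targeted sub-telomeres and carry
#' no information about event identity.
#'
#' @param annotated Annotated segment tibble ([annotate_events()]).
#' @return The insertion segments of clusterable reads, with `query_span`
#'   (the read's aligned query extent) attached.
#' @export
select_clusterable <- function(annotated) {
  spans <- event_table(annotated)
  annotated %>%
    dplyr::filter(.data$n_alignments >= 3L, .data$role == "insertion") %>%
    dplyr::left_join(dplyr::select(spans, "read_id", "query_span"),
                     by = "read_id")
}

#' Jaccard edge threshold by insertion-set size
#'
#' The clustering graph uses a dynamic Jaccard threshold: small insertion
#' sets must match exactly (threshold 1 for sizes 1-2), intermediate sets
#' at 0.66 (sizes 3-5), and large sets at 0.5 (size 6 and above), trading
#' precision for sensitivity as set size grows.
#'
#' @param set_size Insertion-set size (the smaller of the two compared
#'   reads' set sizes); vectorised.
#' @param config A [fusion_config()].
#' @return Numeric vector of thresholds.
#' @export
edge_threshold <- function(set_size, config = fusion_config()) {
  if (any(set_size < 1L)) stop("set_size must be >= 1", call. = FALSE)
  ifelse(set_size <= 6L, config$jaccard_thresholds[pmin(set_size, 6L)],
         config$jaccard_threshold_large)
}

#' Pair prefilter on insertion count and query length
#'
#' Two reads are only compared when their insertion counts differ by at
#' most 25% and their query lengths by at most 4% (relative to the larger
#' of each pair).
#'
#' @param n_a,n_b Insertion counts; vectorised.
#' @param len_a,len_b Query lengths.
#' @param config A [fusion_config()].
#' @return Logical vector: `TRUE` when the pair should be compared.
#' @export
prefilter_pair <- function(n_a, n_b, len_a, len_b, config = fusion_config()) {
  count_ok <- abs(n_a - n_b) / pmax(n_a, n_b) <= config$insertion_count_rel_diff
  len_ok <- abs(len_a - len_b) / pmax(len_a, len_b) <= config$query_len_rel_diff
  count_ok & len_ok
}

# Greedy one-to-one matching of two insertion sets: candidate pairs are
# same-chromosome with reciprocal overlap >= overlap_fraction, taken in
# decreasing overlap order. Returns the number of matched pairs.
.match_insertion_sets <- function(a, b, overlap_fraction) {
  pairs <- dplyr::inner_join(
    dplyr::mutate(a, .i = dplyr::row_number()),
    dplyr::mutate(b, .j = dplyr::row_number()),
    by = "chrom", suffix = c("_a", "_b"), relationship = "many-to-many")
  if (!nrow(pairs)) return(0L)
  pairs$ro <- .reciprocal_overlap(pairs$ref_start_a, pairs$ref_end_a,
                                  pairs$ref_start_b, pairs$ref_end_b)
  pairs <- pairs[pairs$ro >= overlap_fraction, ]
  if (!nrow(pairs)) return(0L)
  pairs <- pairs[order(-pairs$ro, pairs$.i, pairs$.j), ]
  used_i <- logical(nrow(a)); used_j <- logical(nrow(b))
  matched <- 0L
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$.i[r]; j <- pairs$.j[r]
    if (!used_i[i] && !used_j[j]) {
      used_i[i] <- TRUE; used_j[j] <- TRUE
      matched <- matched + 1L
    }
  }
  matched
}

#' Jaccard similarity of two reads' insertion sets
#'
#' `|A intersect B| / |A union B|`, where two insertions are equivalent
#' when they lie on the same chromosome with reciprocal overlap of at
#' least `config$overlap_fraction`; the intersection is a greedy
#' highest-overlap one-to-one pairing, so the index is symmetric and equals
#' 1 on identical non-empty sets. Two empty sets score 0 by definition.
#'
#' @param insertions_a,insertions_b Insertion tibbles (`chrom`,
#'   `ref_start`, `ref_end`).
#' @param config A [fusion_config()].
#' @return Similarity in `[0, 1]`.
#' @export
insertion_jaccard <- function(insertions_a, insertions_b,
                              config = fusion_config()) {
  na <- nrow(insertions_a); nb <- nrow(insertions_b)
  if (na + nb == 0L) return(0)
  m <- .match_insertion_sets(insertions_a, insertions_b,
                             config$overlap_fraction)
  m / (na + nb - m)
}

# Equivalent-insertion hits between reads: pairs of insertions (of two
# different reads) on the same chromosome with reciprocal overlap >=
# overlap_fraction, found through a per-chromosome interval index over all
# clusterable insertions. `ins` must carry `.idx` (insertion index within
# its read). Returns one row per hit with both read ids in canonical order.
.insertion_hits <- function(ins, config) {
  hits <- list()
  for (cm in unique(ins$chrom)) {
    sub <- ins[ins$chrom == cm, ]
    ir <- IRanges::IRanges(start = sub$ref_start + 1L, end = sub$ref_end)
    ov <- IRanges::findOverlaps(ir, ir)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    keep <- qh < sh
    qh <- qh[keep]; sh <- sh[keep]
    if (!length(qh)) next
    ro <- .reciprocal_overlap(sub$ref_start[qh], sub$ref_end[qh],
                              sub$ref_start[sh], sub$ref_end[sh])
    ok <- ro >= config$overlap_fraction &
      sub$read_id[qh] != sub$read_id[sh]
    if (!any(ok)) next
    qh <- qh[ok]; sh <- sh[ok]; ro <- ro[ok]
    swap <- sub$read_id[qh] > sub$read_id[sh]
    a <- ifelse(swap, sh, qh); b <- ifelse(swap, qh, sh)
    hits[[cm]] <- tibble::tibble(
      read_a = sub$read_id[a], read_b = sub$read_id[b],
      ia = sub$.idx[a], ib = sub$.idx[b], ro = ro)
  }
  if (!length(hits)) {
    return(tibble::tibble(read_a = character(), read_b = character(),
                          ia = integer(), ib = integer(), ro = numeric()))
  }
  dplyr::bind_rows(hits)
}

# Sparse-graph edge cap: each node contributes its `cap` highest-Jaccard
# edges (ties by partner index); the kept set is the union over nodes, so a
# clique larger than the cap stays connected through shared partners, while
# every kept edge is among the top-`cap` of at least one endpoint.
.cap_edges <- function(ed, cap) {
  long <- dplyr::bind_rows(
    dplyr::transmute(ed, node = .data$a, other = .data$b,
                     jaccard = .data$jaccard),
    dplyr::transmute(ed, node = .data$b, other = .data$a,
                     jaccard = .data$jaccard))
  long %>%
    dplyr::group_by(.data$node) %>%
    dplyr::arrange(dplyr::desc(.data$jaccard), .data$other,
                   .by_group = TRUE) %>%
    dplyr::slice_head(n = cap) %>%
    dplyr::ungroup() %>%
    dplyr::transmute(a = pmin(.data$node, .data$other),
                     b = pmax(.data$node, .data$other),
                     jaccard = .data$jaccard) %>%
    dplyr::distinct(.data$a, .data$b, .keep_all = TRUE)
}

#' Cluster complex-fusion reads into unique events
#'
#' Graph-based clustering of clusterable reads: candidate pairs are
#' retrieved through a per-chromosome interval index (at least one shared
#' insertion with 80% reciprocal overlap), prefiltered on insertion count
#' and query length, and scored by insertion-set Jaccard similarity. Pairs
#' reaching the set-size-dependent threshold ([edge_threshold()], indexed
#' by the smaller set) become graph edges; the graph is kept sparse by
#' admitting edges in decreasing Jaccard order only while both endpoints
#' have fewer than `config$max_edges_per_node` edges. Clusters are the
#' connected components; reads without edges are singletons with their own
#' cluster ids. Each cluster's representative is the member with the
#' highest total alignment score per aligned base (ties to the
#' lexicographically smallest read id).
#'
#' @param annotated Annotated segment tibble ([annotate_events()]).
#' @param config A [fusion_config()].
#' @return A tibble: `read_id`, `cluster_id`, `n_members`,
#'   `is_representative`, one row per clusterable read. Non-clusterable
#'   reads (fewer than three alignments) are absent.
#' @export
cluster_events <- function(annotated, config = fusion_config()) {
  ins <- select_clusterable(annotated)
  empty <- tibble::tibble(read_id = character(), cluster_id = integer(),
                          n_members = integer(), is_representative = logical())
  if (!nrow(ins)) return(empty)
  reads <- sort(unique(ins$read_id))
  ins <- ins %>%
    dplyr::group_by(.data$read_id) %>%
    dplyr::mutate(.idx = dplyr::row_number()) %>%
    dplyr::ungroup()
  meta <- ins %>%
    dplyr::group_by(.data$read_id) %>%
    dplyr::summarise(n_ins = dplyr::n(),
                     query_span = dplyr::first(.data$query_span),
                     .groups = "drop")
  meta <- meta[match(reads, meta$read_id), ]

  hits <- .insertion_hits(ins, config)
  pairs <- dplyr::distinct(hits[c("read_a", "read_b")])
  ia <- ib <- integer(0)
  if (nrow(pairs)) {
    ia <- match(pairs$read_a, reads); ib <- match(pairs$read_b, reads)
    keep <- prefilter_pair(meta$n_ins[ia], meta$n_ins[ib],
                           meta$query_span[ia], meta$query_span[ib], config)
    pairs <- pairs[keep, ]; ia <- ia[keep]; ib <- ib[keep]
  }
  edges <- NULL
  if (nrow(pairs)) {
    pairs$pair_id <- seq_len(nrow(pairs))
    h <- dplyr::inner_join(hits, pairs, by = c("read_a", "read_b"))
    h <- h[order(h$pair_id, -h$ro, h$ia, h$ib), ]
    matched <- cpp_greedy_match_counts(h$pair_id, h$ia, h$ib, nrow(pairs))
    na <- meta$n_ins[ia]; nb <- meta$n_ins[ib]
    jac <- matched / (na + nb - matched)
    thr <- edge_threshold(pmin(na, nb), config)
    ok <- jac >= thr
    if (any(ok)) {
      ed <- tibble::tibble(a = ia[ok], b = ib[ok], jaccard = jac[ok])
      edges <- .cap_edges(ed, config$max_edges_per_node)
    }
  }
  g <- igraph::make_empty_graph(n = length(reads), directed = FALSE)
  if (!is.null(edges) && nrow(edges)) {
    g <- igraph::add_edges(g, rbind(edges$a, edges$b))
  }
  comp <- igraph::components(g)$membership
  out <- tibble::tibble(read_id = reads, cluster_id = as.integer(comp)) %>%
    dplyr::group_by(.data$cluster_id) %>%
    dplyr::mutate(n_members = dplyr::n()) %>%
    dplyr::ungroup()

  score_rate <- annotated %>%
    dplyr::group_by(.data$read_id) %>%
    dplyr::summarise(rate = sum(.data$score) / sum(.data$aligned_bases),
                     .groups = "drop")
  # representative: highest score per aligned base, ties by read id
  out <- dplyr::left_join(out, score_rate, by = "read_id") %>%
    dplyr::group_by(.data$cluster_id) %>%
    dplyr::mutate(is_representative = .data$read_id ==
                    .data$read_id[order(-.data$rate, .data$read_id)][1]) %>%
    dplyr::ungroup() %>%
    dplyr::select(-"rate") %>%
    dplyr::arrange(.data$cluster_id, .data$read_id)
  attr(out, "edges") <- if (is.null(edges)) {
    tibble::tibble(read_a = character(), read_b = character(),
                   jaccard = numeric())
  } else {
    tibble::tibble(read_a = reads[edges$a], read_b = reads[edges$b],
                   jaccard = edges$jaccard)
  }
  out
}

#' Pick the representative read of one cluster
#'
#' The member maximising total alignment score over total aligned bases;
#' exact ties resolve to the lexicographically smallest read id.
#'
#' @param member_read_ids Character vector of the cluster's reads.
#' @param segments Segment tibble holding those reads' alignments.
#' @return A read id.
#' @export
pick_representative <- function(member_read_ids, segments) {
  stopifnot(length(member_read_ids) >= 1L)
  rates <- segments %>%
    dplyr::filter(.data$read_id %in% member_read_ids) %>%
    dplyr::group_by(.data$read_id) %>%
    dplyr::summarise(rate = sum(.data$score) / sum(.data$aligned_bases),
                     .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$rate), .data$read_id)
  rates$read_id[1]
}

#' Write the cluster-stage BED outputs
#'
#' Two files: all clustered reads with their cluster annotations, and the
#' singleton reads (clusters of size one) alone.
#'
#' @param annotated Annotated segment tibble.
#' @param clusters Output of [cluster_events()].
#' @param path,singleton_path Output paths.
#' @return `path`, invisibly.
#' @export
write_cluster_beds <- function(annotated, clusters, path, singleton_path) {
  write_cluster_bed(annotated, clusters, path)
  singles <- dplyr::filter(clusters, .data$n_members == 1L)
  write_cluster_bed(
    dplyr::semi_join(annotated, singles, by = "read_id"), singles,
    singleton_path)
  invisible(path)
}
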