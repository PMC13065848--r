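#' Precision, recall and F1 from benchmark counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 TP / (2 TP + FP + FN)`. A ratio with a zero denominator is
#' undefined and reported as `NA`, not 0.
#'
#' @param tp,fp,fn Non-negative counts; vectorised.
#' @return A tibble with columns `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`.
#' @examples
#' prf(3, 1, 0) # precision 0.75, recall 1, f1 6/7
#' @export
prf <- function(tp, fp, fn) {
  stopifnot(all(tp >= 0), all(fp >= 0), all(fn >= 0))
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    precision = ifelse(tp + fp > 0, tp / (tp + fp), NA_real_),
    recall = ifelse(tp + fn > 0, tp / (tp + fn), NA_real_),
    f1 = ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), NA_real_)
  )
}

#' Match called insertions of one read against its ground truth
#'
#' Greedy one-to-one matching: a call matches a truth insertion when both
#' lie on the same chromosome and the start and end positions each agree
#' within `tolerance` bp; candidate matches are taken in increasing order
#' of positional discrepancy. Matched calls are true positives, unmatched
#' calls false positives, unmatched truths false negatives. With a
#' positive `min_size` the scoring is restricted to truth insertions of at
#' least `min_size` bp and to unmatched calls of at least `min_size` bp;
#' calls matched to a sub-threshold truth are excused entirely (neither TP
#' nor FP), so the size floor never converts a correct short call into an
#' error.
#'
#' @param truth_insertions,called_insertions Insertion tibbles (`chrom`,
#'   `ref_start`, `ref_end`).
#' @param tolerance Positional tolerance (bp) on start and end.
#' @param min_size Minimum truth/call size (bp) scored; 0 scores all.
#' @param require_strand Also require strand agreement for a match
#'   (`FALSE` by default; positions alone define a true positive).
#' @return A one-row tibble of `tp`, `fp`, `fn`.
#' @export
match_insertions <- function(truth_insertions, called_insertions,
                             tolerance = 50, min_size = 0,
                             require_strand = FALSE) {
  tr <- dplyr::mutate(truth_insertions, .i = dplyr::row_number())
  ca <- dplyr::mutate(called_insertions, .j = dplyr::row_number())
  by <- if (require_strand) c("chrom", "strand") else "chrom"
  pairs <- dplyr::inner_join(tr, ca, by = by, suffix = c("_t", "_c"),
                             relationship = "many-to-many")
  matched_i <- integer(); matched_j <- integer()
  if (nrow(pairs)) {
    pairs$ds <- abs(pairs$ref_start_t - pairs$ref_start_c)
    pairs$de <- abs(pairs$ref_end_t - pairs$ref_end_c)
    pairs <- pairs[pairs$ds <= tolerance & pairs$de <= tolerance, ]
    if (nrow(pairs)) {
      pairs <- pairs[order(pmax(pairs$ds, pairs$de), pairs$.i, pairs$.j), ]
      used_i <- logical(nrow(tr)); used_j <- logical(nrow(ca))
      for (r in seq_len(nrow(pairs))) {
        i <- pairs$.i[r]; j <- pairs$.j[r]
        if (!used_i[i] && !used_j[j]) {
          used_i[i] <- TRUE; used_j[j] <- TRUE
          matched_i <- c(matched_i, i); matched_j <- c(matched_j, j)
        }
      }
    }
  }
  t_size <- tr$ref_end - tr$ref_start
  c_size <- ca$ref_end - ca$ref_start
  t_in <- t_size >= min_size
  c_in <- c_size >= min_size
  tp <- sum(t_in[matched_i])
  fn <- sum(t_in) - tp
  unmatched_j <- setdiff(seq_len(nrow(ca)), matched_j)
  fp <- sum(c_in[unmatched_j])
  tibble::tibble(tp = tp, fp = fp, fn = fn)
}

#' Benchmark called insertions against simulation ground truth
#'
#' Decodes the ground truth from truth-encoded read identifiers
#' ([decode_truth_ids()]), matches each read's called insertions against
#' its truth ([match_insertions()]), and pools the counts. Headline
#' metrics use the configured size floor (`config$benchmark_min_size`);
#' unfiltered metrics over all insertions are reported alongside.
#'
#' @param annotated Annotated segment tibble of the pipeline's output for
#'   truth-encoded reads.
#' @param config A [fusion_config()].
#' @param truth Optional decoded truth table (from [decode_truth_ids()]);
#'   decoded from `annotated`'s read ids when omitted. Reads absent from
#'   `annotated` (e.g. dropped by QC) still contribute their truth
#'   insertions as false negatives when supplied here.
#' @return An object of class `"fusion_benchmark"`: list with `per_read`
#'   (tibble of read-level counts), `summary` (pooled micro-averaged
#'   [prf()], filtered and unfiltered), `macro` (mean of per-read P/R/F1),
#'   `agreement` (expected-vs-observed insertion-count table and rate).
#' @export
benchmark_insertions <- function(annotated, config = fusion_config(),
                                 truth = NULL) {
  if (is.null(truth)) {
    truth <- decode_truth_ids(unique(annotated$read_id))
  }
  calls <- annotated %>%
    dplyr::filter(.data$role == "insertion") %>%
    dplyr::select("read_id", "chrom", "ref_start", "ref_end", "strand")
  call_sets <- split(calls[c("chrom", "ref_start", "ref_end", "strand")],
                     calls$read_id)
  empty_ins <- tibble::tibble(chrom = character(), ref_start = integer(),
                              ref_end = integer(), strand = character())
  per_read <- purrr::map2_dfr(truth$read_id, truth$insertions,
                              function(id, tr_ins) {
    ca <- call_sets[[id]] %||% empty_ins
    flt <- match_insertions(tr_ins, ca, tolerance = config$benchmark_tolerance,
                            min_size = config$benchmark_min_size)
    raw <- match_insertions(tr_ins, ca, tolerance = config$benchmark_tolerance,
                            min_size = 0)
    tibble::tibble(read_id = id,
                   n_true = nrow(tr_ins), n_called = nrow(ca),
                   tp = flt$tp, fp = flt$fp, fn = flt$fn,
                   tp_raw = raw$tp, fp_raw = raw$fp, fn_raw = raw$fn)
  })
  summary <- dplyr::bind_rows(
    dplyr::mutate(prf(sum(per_read$tp), sum(per_read$fp), sum(per_read$fn)),
                  scope = "size_filtered", .before = 1),
    dplyr::mutate(prf(sum(per_read$tp_raw), sum(per_read$fp_raw),
                      sum(per_read$fn_raw)),
                  scope = "all_insertions", .before = 1)
  )
  macro <- per_read %>%
    dplyr::mutate(prf(.data$tp, .data$fp, .data$fn)[c("precision", "recall",
                                                      "f1")]) %>%
    dplyr::summarise(precision = mean(.data$precision, na.rm = TRUE),
                     recall = mean(.data$recall, na.rm = TRUE),
                     f1 = mean(.data$f1, na.rm = TRUE))
  agreement <- list(
    table = dplyr::select(per_read, "read_id", "n_true", "n_called",
                          "tp", "fp", "fn"),
    rate = mean(per_read$fp == 0L & per_read$fn == 0L)
  )
  structure(list(per_read = per_read, summary = summary, macro = macro,
                 agreement = agreement, config = config),
            class = "fusion_benchmark")
}

#' @export
print.fusion_benchmark <- function(x, ...) {
  cat("<fusion_benchmark> ", nrow(x$per_read), " reads\n", sep = "")
  print(x$summary)
  cat("insertion-count agreement rate: ",
      format(x$agreement$rate, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @rdname benchmark_insertions
#' @param x A `fusion_benchmark` object.
#' @param ... Unused.
#' @export
tidy.fusion_benchmark <- function(x, ...) {
  dplyr::mutate(x$per_read,
                prf(x$per_read$tp, x$per_read$fp,
                    x$per_read$fn)[c("precision", "recall", "f1")])
}

#' @rdname benchmark_insertions
#' @export
glance.fusion_benchmark <- function(x, ...) {
  flt <- x$summary[x$summary$scope == "size_filtered", ]
  tibble::tibble(n_reads = nrow(x$per_read),
                 tp = flt$tp, fp = flt$fp, fn = flt$fn,
                 precision = flt$precision, recall = flt$recall, f1 = flt$f1,
                 agreement_rate = x$agreement$rate)
}

#' Expected versus observed insertion counts per read
#'
#' @param benchmark A [benchmark_insertions()] result.
#' @return A tibble `read_id`, `n_true`, `n_called` plus the overall
#'   agreement rate as attribute `"agreement_rate"`.
#' @export
expected_vs_observed <- function(benchmark) {
  out <- benchmark$agreement$table
  attr(out, "agreement_rate") <- benchmark$agreement$rate
  out
}

#' Benchmark clustering against ground truth
#'
#' Truth clusters are the groups of reads sharing a simulated event; they
#' are restricted to reads present in the called clustering (reads the
#' pipeline deemed clusterable). Each truth cluster is paired with the
#' called cluster of maximal intersection (greedy, in decreasing
#' intersection order, each called cluster used at most once); per truth
#' cluster `TP` is the intersection size, `FN` the truth members missing
#' from it, and `FP` the called members foreign to it. Counts are pooled
#' into micro-averaged precision/recall/F1.
#'
#' @param clusters Called clusters ([cluster_events()]).
#' @param truth Optional decoded truth ([decode_truth_ids()]); decoded
#'   from the clustered read ids when omitted.
#' @return An object of class `"fusion_cluster_benchmark"`: `per_cluster`
#'   tibble (`event_id`, `cluster_id`, `n_true`, `n_called`, `tp`, `fp`,
#'   `fn`), pooled `summary` ([prf()]), and `sizes` (expected vs observed
#'   cluster sizes).
#' @export
benchmark_clusters <- function(clusters, truth = NULL) {
  if (is.null(truth)) truth <- decode_truth_ids(clusters$read_id)
  truth <- dplyr::filter(truth, .data$read_id %in% clusters$read_id)
  true_groups <- split(truth$read_id, truth$event_id)
  called_groups <- split(clusters$read_id, clusters$cluster_id)
  inter <- purrr::imap_dfr(true_groups, function(members, ev) {
    purrr::imap_dfr(called_groups, function(cmembers, cid) {
      tibble::tibble(event_id = ev, cluster_id = cid,
                     intersection = length(intersect(members, cmembers)))
    })
  })
  inter <- inter[inter$intersection > 0L, ]
  inter <- inter[order(-inter$intersection, inter$event_id,
                       inter$cluster_id), ]
  used_cluster <- character(); rows <- list()
  paired_events <- character()
  for (r in seq_len(nrow(inter))) {
    ev <- inter$event_id[r]; cid <- inter$cluster_id[r]
    if (ev %in% paired_events || cid %in% used_cluster) next
    paired_events <- c(paired_events, ev)
    used_cluster <- c(used_cluster, cid)
    members <- true_groups[[ev]]; cmembers <- called_groups[[cid]]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      event_id = ev, cluster_id = as.integer(cid),
      n_true = length(members), n_called = length(cmembers),
      tp = length(intersect(members, cmembers)),
      fn = length(setdiff(members, cmembers)),
      fp = length(setdiff(cmembers, members)))
  }
  unpaired <- setdiff(names(true_groups), paired_events)
  for (ev in unpaired) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      event_id = ev, cluster_id = NA_integer_,
      n_true = length(true_groups[[ev]]), n_called = 0L,
      tp = 0L, fn = length(true_groups[[ev]]), fp = 0L)
  }
  per_cluster <- dplyr::bind_rows(rows) %>% dplyr::arrange(.data$event_id)
  summary <- prf(sum(per_cluster$tp), sum(per_cluster$fp),
                 sum(per_cluster$fn))
  sizes <- dplyr::select(per_cluster, "event_id", "n_true", "n_called")
  structure(list(per_cluster = per_cluster, summary = summary, sizes = sizes),
            class = "fusion_cluster_benchmark")
}

#' @export
print.fusion_cluster_benchmark <- function(x, ...) {
  cat("<fusion_cluster_benchmark> ", nrow(x$per_cluster),
      " truth clusters\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname benchmark_clusters
#' @param x A `fusion_cluster_benchmark` object.
#' @param ... Unused.
#' @export
tidy.fusion_cluster_benchmark <- function(x, ...) {
  dplyr::mutate(x$per_cluster,
                prf(x$per_cluster$tp, x$per_cluster$fp,
                    x$per_cluster$fn)[c("precision", "recall", "f1")])
}

#' @rdname benchmark_clusters
#' @export
glance.fusion_cluster_benchmark <- function(x, ...) {
  tibble::tibble(n_clusters = nrow(x$per_cluster), x$summary)
}
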