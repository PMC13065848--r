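#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline in a single flat list, so
#' that all stages read from one place. Defaults are the pipeline's standard
#' operating values.
#'
#' @param min_block_len Minimum length (bp) of a low-complexity block before
#'   it is considered evidence of a sequencing artefact.
#' @param telomere_kmer_fraction Blocks whose overlapping 6-mer composition
#'   exceeds this fraction of telomere-motif rotations are exempt from the
#'   artefact filter (keeps genuine telomere repeat arrays).
#' @param repetitiveness_cutoff Reads with a qualifying block whose
#'   repetitiveness score exceeds this value are discarded.
#' @param repetitiveness_k k-mer size used by [repetitiveness_score()].
#' @param score_fraction Fraction of the maximum alignment score a primer
#'   alignment target must reach to label a read end.
#' @param end_window Length (bp) of the terminal windows searched for primers;
#'   the interior (read minus both windows) is searched for concatemers.
#' @param telomere_motifs Character vector of telomere repeat units; all
#'   rotations of each (and nothing else) count towards the telomere k-mer
#'   fraction.
#' @param match,mismatch,gap_open,gap_extend Local-alignment scoring used for
#'   primer identification and concatemer detection (mirrors the recommended
#'   mapper scoring).
#' @param overlap_fraction Reciprocal-overlap fraction two reference intervals
#'   must share to be considered equivalent (candidate retrieval, Jaccard set
#'   membership, foldback detection).
#' @param insertion_count_rel_diff Pairs of reads whose insertion counts
#'   differ by more than this relative fraction are not compared.
#' @param query_len_rel_diff Pairs of reads whose query lengths differ by more
#'   than this relative fraction are not compared.
#' @param jaccard_thresholds Jaccard edge thresholds indexed by insertion-set
#'   size 1..6.
#' @param jaccard_threshold_large Threshold for set sizes above 6.
#' @param max_edges_per_node Sparse-graph cap on the number of edges per read.
#' @param hotspot_window Window (bp) for single-linkage insertion hotspot
#'   grouping.
#' @param foldback_overlap Reciprocal overlap required to flag a foldback
#'   segment pair.
#' @param seed_k Seed length of the built-in k-mer mapper.
#' @param seed_max_hits Seeds whose k-mer occurs more than this many times in
#'   the reference are ignored (repeat filtering).
#' @param benchmark_tolerance Positional tolerance (bp) on insertion start and
#'   end for a benchmark true positive.
#' @param benchmark_min_size Headline benchmark metrics consider only truth
#'   insertions (and unmatched calls) at least this long; set to 0 to score
#'   every insertion.
#' @param rng_seed Optional integer seed recorded in run manifests.
#'
#' @return A named list with class `"fusion_config"`.
#' @examples
#' cfg <- fusion_config()
#' cfg$jaccard_thresholds
#' @export
fusion_config <- function(min_block_len = 150,
                          telomere_kmer_fraction = 0.30,
                          repetitiveness_cutoff = 0.3,
                          repetitiveness_k = 8,
                          score_fraction = 0.4,
                          end_window = 150,
                          telomere_motifs = c("TTAGGG", "CCCTAA"),
                          match = 2,
                          mismatch = -3,
                          gap_open = 5,
                          gap_extend = 2,
                          overlap_fraction = 0.80,
                          insertion_count_rel_diff = 0.25,
                          query_len_rel_diff = 0.04,
                          jaccard_thresholds = c(1, 1, 0.66, 0.66, 0.66, 0.5),
                          jaccard_threshold_large = 0.5,
                          max_edges_per_node = 10,
                          hotspot_window = 10000,
                          foldback_overlap = 0.80,
                          seed_k = 11,
                          seed_max_hits = 24,
                          benchmark_tolerance = 50,
                          benchmark_min_size = 50,
                          rng_seed = NULL) {
  cfg <- list(
    min_block_len = min_block_len,
    telomere_kmer_fraction = telomere_kmer_fraction,
    repetitiveness_cutoff = repetitiveness_cutoff,
    repetitiveness_k = repetitiveness_k,
    score_fraction = score_fraction,
    end_window = end_window,
    telomere_motifs = telomere_motifs,
    match = match,
    mismatch = mismatch,
    gap_open = gap_open,
    gap_extend = gap_extend,
    overlap_fraction = overlap_fraction,
    insertion_count_rel_diff = insertion_count_rel_diff,
    query_len_rel_diff = query_len_rel_diff,
    jaccard_thresholds = jaccard_thresholds,
    jaccard_threshold_large = jaccard_threshold_large,
    max_edges_per_node = max_edges_per_node,
    hotspot_window = hotspot_window,
    foldback_overlap = foldback_overlap,
    seed_k = seed_k,
    seed_max_hits = seed_max_hits,
    benchmark_tolerance = benchmark_tolerance,
    benchmark_min_size = benchmark_min_size,
    rng_seed = rng_seed
  )
  fracs <- c("telomere_kmer_fraction", "repetitiveness_cutoff",
             "score_fraction", "overlap_fraction",
             "insertion_count_rel_diff", "query_len_rel_diff",
             "foldback_overlap")
  for (f in fracs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop("`", f, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  if (length(cfg$jaccard_thresholds) != 6L) {
    stop("`jaccard_thresholds` must have 6 entries (set sizes 1..6)",
         call. = FALSE)
  }
  if (any(cfg$jaccard_thresholds < 0 | cfg$jaccard_thresholds > 1)) {
    stop("`jaccard_thresholds` must lie in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "fusion_config")
}

#' @export
print.fusion_config <- function(x, ...) {
  cat("<fusion_config>\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-26s %s\n", nm,
                if (is.null(val)) "NULL" else paste(val, collapse = ", ")))
  }
  invisible(x)
}

#' Read / write a pipeline configuration file
#'
#' Flat `key = value` text format; vector values are comma-separated.
#' Unknown keys are rejected so that typos fail loudly.
#'
#' @param path File path.
#' @return `read_fusion_config()` returns a [fusion_config()] object.
#' @export
read_fusion_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1], call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  defaults <- fusion_config()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  args <- list()
  for (i in seq_along(keys)) {
    parts <- trimws(strsplit(vals[i], ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    args[[keys[i]]] <- if (anyNA(num)) parts else num
  }
  do.call(fusion_config, args)
}

#' @rdname read_fusion_config
#' @param config A [fusion_config()] object.
#' @export
write_fusion_config <- function(config, path) {
  stopifnot(inherits(config, "fusion_config"))
  keep <- !vapply(config, is.null, logical(1))
  lines <- vapply(names(config)[keep], function(nm) {
    paste0(nm, " = ", paste(config[[nm]], collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
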