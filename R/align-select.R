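#' Map reads with the built-in seed-and-chain mapper
#'
#' A deliberately simple k-mer mapper for hermetic testing and the built-in
#' end-to-end path: exact k-mer seeds (k = 11 by default, repeat-filtered),
#' per-strand diagonal chaining with indel-tolerant chain merging, and
#' x-drop ungapped extension of segment boundaries. It reports *all*
#' candidate segments per read, the contract the pipeline expects from an
#' external mapper run in report-all-candidates mode (see
#' [mapper_command()] for the recommended real-mapper invocation).
#'
#' @param reads A read tibble; the retained (trimmed) sequence of each
#'   QC-passed read is mapped.
#' @param reference A [simulate_reference()] bundle, or a named character
#'   vector of contig sequences, or a FASTA path.
#' @param config A [fusion_config()] (seed length and repeat cap).
#' @param max_gap Maximum query/reference gap (bp) bridged within one
#'   candidate segment.
#' @param diag_tol Maximum indel drift (bp) between merged seed chains.
#' @param min_seeds Minimum seeds per candidate segment.
#' @param min_aligned Minimum (approximate) aligned bases per candidate.
#' @return A candidate segment tibble (see [read_candidate_alignments()]).
#' @export
map_reads <- function(reads, reference, config = fusion_config(),
                      max_gap = 150, diag_tol = 50, min_seeds = 2,
                      min_aligned = 25) {
  seqs <- .reference_sequences(reference)
  keep <- reads$qc_status == "pass"
  tb <- cpp_map_reads(reads$read_id[keep], read_sequences(reads)[keep],
                      names(seqs), unname(seqs),
                      as.integer(config$seed_k),
                      as.integer(config$seed_max_hits),
                      as.integer(max_gap), as.integer(diag_tol),
                      as.integer(min_seeds), as.integer(min_aligned),
                      8L, as.integer(config$match))
  tibble::as_tibble(tb)
}

.reference_sequences <- function(reference) {
  if (inherits(reference, "fusion_reference")) return(reference$sequences)
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    x <- Biostrings::readDNAStringSet(reference)
    return(setNames(as.character(x), sub("\\s.*$", "", names(x))))
  }
  if (is.character(reference) && !is.null(names(reference))) return(reference)
  stop("`reference` must be a fusion_reference, a named character vector, ",
       "or a FASTA path", call. = FALSE)
}

#' Recommended external mapper invocation
#'
#' The pipeline consumes any SAM/BAM that reports all candidate alignments
#' per read. For real data the recommended mapper is bwa mem with
#' sensitivity-increasing settings; this helper prints the exact invocation.
#'
#' @param reference Path to the reference FASTA (indexed with `bwa index`).
#' @param fastq Path to the input reads.
#' @return The command line, invisibly; it is also printed.
#' @export
mapper_command <- function(reference = "reference.fa", fastq = "reads.fq.gz") {
  cmd <- paste("bwa mem",
               "-c 1000 -A2 -B3 -O5 -E2 -T0 -L0 -D 0.25 -r 1.25 -d 200 -k 11 -a",
               reference, fastq)
  message(cmd)
  invisible(cmd)
}

#' Choose an optimal spanning set of alignments for one read
#'
#' From all candidate alignments of a read, selects the subset maximising
#' total alignment score minus an overlap penalty of `overlap_penalty` per
#' query base shared by consecutive chosen segments. Chosen segments are
#' strictly ordered on the query (increasing start and end); consecutive
#' segments may overlap by up to half the shorter segment -- overlap at
#' junctions is the microhomology signal and must be allowed, but is
#' discouraged at the per-base match rate -- and coverage gaps are free
#' (they surface downstream as insertion/gap junctions). The optimum is
#' found by dynamic programming and ties break deterministically (lower
#' query start, then higher score, then chromosome, reference start and
#' strand).
#'
#' @param candidates Candidate segment tibble for a single read.
#' @param config A [fusion_config()]; `config$match` is the per-base
#'   overlap penalty.
#' @return The chosen segments, ordered by `query_start`.
#' @examples
#' cand <- tibble::tibble(read_id = "r", query_start = c(0L, 100L),
#'                        query_end = c(100L, 200L), chrom = "chr1",
#'                        ref_start = c(0L, 500L), ref_end = c(100L, 600L),
#'                        strand = "+", score = c(200, 200),
#'                        aligned_bases = c(100L, 100L))
#' choose_spanning_set(cand)
#' @export
choose_spanning_set <- function(candidates, config = fusion_config()) {
  if (!nrow(candidates)) {
    stop("no candidate alignments supplied", call. = FALSE)
  }
  if ("read_id" %in% names(candidates) &&
      length(unique(candidates$read_id)) > 1L) {
    stop("choose_spanning_set() works on one read; see select_alignments()",
         call. = FALSE)
  }
  ord <- order(candidates$query_start, -candidates$score, candidates$chrom,
               candidates$ref_start, candidates$strand)
  cand <- candidates[ord, ]
  sel <- cpp_choose_spanning(cand$query_start, cand$query_end, cand$score,
                             overlap_penalty = config$match)
  cand[sel, ]
}

#' Select spanning alignments for every read
#'
#' Applies [choose_spanning_set()] per read across a candidate table.
#'
#' @param candidates Candidate segment tibble (any number of reads).
#' @param config A [fusion_config()].
#' @return Segment tibble of the chosen alignments, ordered by
#'   (`read_id`, `query_start`).
#' @export
select_alignments <- function(candidates, config = fusion_config()) {
  if (!nrow(candidates)) return(candidates)
  candidates %>%
    dplyr::group_by(.data$read_id) %>%
    dplyr::group_modify(~ choose_spanning_set(.x, config)) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$read_id, .data$query_start)
}
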