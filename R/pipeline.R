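#' Run the full analysis pipeline
#'
#' Orchestrates the stages in order: read QC (artefact filtering,
#' concatemer detection, primer labelling/trimming), mapping (built-in
#' seed mapper, or candidate alignments supplied from an external mapper
#' run in report-all mode), spanning-set selection, event annotation, and
#' clustering. Stage outputs and a JSON run manifest are written to
#' `out_dir` when given.
#'
#' @param reads A read tibble or a FASTQ path.
#' @param reference A [simulate_reference()] bundle, named character vector
#'   of contigs, or FASTA path.
#' @param primers A primer tibble or TSV path; defaults to the reference
#'   bundle's primers when available.
#' @param config A [fusion_config()].
#' @param alignments Optional: a candidate segment tibble or SAM/BAM path
#'   from an external mapper; the built-in mapper is skipped.
#' @param out_dir Optional output directory for BED files and the
#'   manifest.
#' @return A list with class `"fusion_run"`: `reads`, `segments`
#'   (annotated), `events` (per-read table), `clusters`, `summary`,
#'   `manifest`.
#' @export
run_pipeline <- function(reads, reference, primers = NULL,
                         config = fusion_config(), alignments = NULL,
                         out_dir = NULL) {
  if (is.character(reads) && length(reads) == 1L) {
    if (!file.exists(reads)) {
      stop("read filtering stage: input FASTQ not found: ", reads,
           call. = FALSE)
    }
    reads <- read_fastq(reads)
  }
  if (is.null(primers)) {
    if (inherits(reference, "fusion_reference")) {
      primers <- reference$primers
    } else {
      stop("primer identification stage: no primers supplied", call. = FALSE)
    }
  } else if (is.character(primers) && length(primers) == 1L) {
    primers <- read_primers(primers)
  }
  n_input <- nrow(reads)

  reads <- qc_reads(reads, primers, config)
  discards <- attr(reads, "discards")
  n_pass <- sum(reads$qc_status == "pass")

  candidates <- if (is.null(alignments)) {
    map_reads(reads, reference, config)
  } else if (is.character(alignments)) {
    read_candidate_alignments(alignments, match_score = config$match)
  } else {
    alignments
  }

  selected <- select_alignments(candidates, config)
  annotated <- annotate_events(selected)
  events <- event_table(annotated)
  clusters <- cluster_events(annotated, config)

  catalogue <- if (inherits(reference, "fusion_reference")) {
    reference$catalogue
  } else NULL
  summ <- summarise_events(annotated, catalogue)

  manifest <- list(
    tool = paste0("telofuse ", as.character(utils::packageVersion("telofuse"))),
    seed = config$rng_seed,
    config = unclass(config)[!vapply(config, is.null, logical(1))],
    counts = list(
      input_reads = n_input,
      qc_pass = n_pass,
      discarded_low_complexity =
        sum(reads$qc_status == "artifact_low_complexity"),
      discarded_concatemer = sum(reads$qc_status == "artifact_concatemer"),
      mapped_reads = length(unique(candidates$read_id)),
      fusion_reads = sum(events$is_fusion),
      clusterable_reads = nrow(clusters),
      clusters = length(unique(clusters$cluster_id))
    )
  )
  stopifnot(manifest$counts$input_reads ==
              manifest$counts$qc_pass +
              manifest$counts$discarded_low_complexity +
              manifest$counts$discarded_concatemer)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_alignment_bed(annotated, file.path(out_dir, "alignments.bed"))
    write_cluster_beds(annotated, clusters,
                       file.path(out_dir, "clusters.bed"),
                       file.path(out_dir, "singletons.bed"))
    disc_out <- dplyr::mutate(discards, dplyr::across(
      dplyr::everything(), ~ ifelse(is.na(.x), "False", as.character(.x))))
    readr::write_tsv(disc_out, file.path(out_dir, "discards.tsv"),
                     progress = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  structure(list(reads = reads, segments = annotated, events = events,
                 clusters = clusters, summary = summ, manifest = manifest),
            class = "fusion_run")
}

#' @export
print.fusion_run <- function(x, ...) {
  cts <- x$manifest$counts
  cat("<fusion_run>\n")
  cat("  reads: ", cts$input_reads, " in, ", cts$qc_pass, " pass QC (",
      cts$discarded_low_complexity, " low-complexity, ",
      cts$discarded_concatemer, " concatemer discarded)\n", sep = "")
  cat("  fusion reads: ", cts$fusion_reads, "; clusterable: ",
      cts$clusterable_reads, " in ", cts$clusters, " clusters\n", sep = "")
  invisible(x)
}
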