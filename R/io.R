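#' Read long reads from a FASTQ file
#'
#' Reads plain or gzip-compressed FASTQ into the package's read table. Each
#' read starts with a `pass` QC verdict, no primer labels, and a trimmed
#' interval covering the whole sequence (0-based half-open, in original read
#' coordinates).
#'
#' @param path Path to a FASTQ file (optionally gzipped).
#' @return A tibble with one row per read: `read_id`, `sequence`, `quality`,
#'   `qc_status`, `primer_start`, `primer_end`, `trim_start`, `trim_end`.
#' @examples
#' fq <- tempfile(fileext = ".fq")
#' writeLines(c("@r1", "ACGTACGT", "+", "IIIIIIII"), fq)
#' read_fastq(fq)
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  parsed <- tryCatch({
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    list(seq = as.character(x),
         qual = as.character(S4Vectors::mcols(x)$qualities),
         ids = sub("\\s.*$", "", names(x)))
  },
  error = function(e) {
    idx <- .locate_bad_fastq_record(path)
    stop("malformed FASTQ record",
         if (!is.na(idx)) paste0(" at index ", idx) else "",
         " in ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  if (length(parsed$seq) == 0L) {
    warning("empty FASTQ file: ", path, call. = FALSE)
    return(empty_reads())
  }
  new_reads(read_id = parsed$ids, sequence = unname(parsed$seq),
            quality = unname(parsed$qual))
}

# Diagnostic re-parse to report the index of the first broken FASTQ record.
.locate_bad_fastq_record <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  idx <- 0L
  repeat {
    rec <- readLines(con, n = 4L)
    if (length(rec) == 0L) return(NA_integer_)
    idx <- idx + 1L
    if (length(rec) < 4L || !startsWith(rec[1], "@") || !startsWith(rec[3], "+") ||
        nchar(rec[2]) != nchar(rec[4])) {
      return(idx)
    }
  }
}

new_reads <- function(read_id, sequence, quality = NA_character_) {
  stopifnot(all(nchar(sequence) > 0L))
  tibble::tibble(
    read_id = read_id,
    sequence = sequence,
    quality = quality,
    qc_status = "pass",
    primer_start = NA_character_,
    primer_end = NA_character_,
    trim_start = 0L,
    trim_end = nchar(sequence)
  )
}

empty_reads <- function() {
  new_reads(character(), character(), character())[0, ]
}

#' Extract the retained (trimmed) sequence of each read
#'
#' @param reads A read tibble (see [read_fastq()]).
#' @return Character vector of the sequences inside each read's trimmed
#'   interval.
#' @export
read_sequences <- function(reads) {
  substr(reads$sequence, reads$trim_start + 1L, reads$trim_end)
}

#' Write reads to FASTQ
#'
#' Writes the full (untrimmed) sequences; reads lacking quality strings get a
#' uniform placeholder quality.
#'
#' @param reads A read tibble.
#' @param path Output path (`.gz` for gzip).
#' @export
write_fastq <- function(reads, path) {
  qual <- ifelse(is.na(reads$quality),
                 strrep("I", nchar(reads$sequence)), reads$quality)
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id)),
    Biostrings::PhredQuality(qual)
  )
  Biostrings::writeQualityScaledXStringSet(x, path,
                                           compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Primer definitions
#'
#' A primer is identified on reads not by the bare primer sequence (18-26 nt,
#' too short for reliable alignment on noisy read ends) but by a 68-bp
#' alignment target: the primer followed by the reference flank expected
#' immediately downstream of it.
#'
#' @param name Primer name.
#' @param primer_seq Primer sequence (18-26 nt expected).
#' @param alignment_target 68-nt sequence beginning with `primer_seq`.
#' @return A one-row tibble (`primer_spec()`), or a tibble of all primers
#'   (`read_primers()`).
#' @export
primer_spec <- function(name, primer_seq, alignment_target) {
  primer_seq <- toupper(primer_seq)
  alignment_target <- toupper(alignment_target)
  if (nchar(alignment_target) != 68L) {
    stop("alignment_target of primer '", name, "' must be 68 nt, got ",
         nchar(alignment_target), call. = FALSE)
  }
  if (!startsWith(alignment_target, primer_seq)) {
    stop("primer_seq of '", name, "' is not a prefix of its alignment_target",
         call. = FALSE)
  }
  if (nchar(primer_seq) < 18L || nchar(primer_seq) > 26L) {
    warning("primer '", name, "' is ", nchar(primer_seq),
            " nt; 18-26 nt expected", call. = FALSE)
  }
  tibble::tibble(name = name, primer_seq = primer_seq,
                 alignment_target = alignment_target)
}

#' @rdname primer_spec
#' @param path Tab-separated file with columns `name`, `primer_seq`,
#'   `alignment_target`.
#' @export
read_primers <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  need <- c("name", "primer_seq", "alignment_target")
  if (!all(need %in% names(tb))) {
    stop("primer file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  purrr::pmap_dfr(tb[need], primer_spec)
}

#' @rdname primer_spec
#' @param primers A primer tibble.
#' @export
write_primers <- function(primers, path) {
  readr::write_tsv(primers, path, progress = FALSE)
  invisible(path)
}

#' Read candidate alignments from SAM/BAM
#'
#' Loads every mapped record (primary, secondary and supplementary) and
#' reconstructs query coordinates on the full-length read: soft and hard
#' clips are counted, and reverse-strand records are mirrored so that query
#' intervals of all segments of one read live on a single axis in the
#' original read orientation. All coordinates are 0-based half-open.
#'
#' Alignment scores are taken from the `AS` tag when present; otherwise a
#' score of `match_score` per aligned base is imputed.
#'
#' @param path A SAM (`.sam`) or BAM file. SAM input is converted on the fly.
#' @param match_score Per-base score used when no `AS` tag is present.
#' @return A segment tibble: `read_id`, `query_start`, `query_end`, `chrom`,
#'   `ref_start`, `ref_end`, `strand`, `score`, `aligned_bases`.
#' @export
read_candidate_alignments <- function(path, match_score = 2) {
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"),
    tag = "AS",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(rec$qname)
  if (n == 0L) return(empty_segments())
  if (anyNA(rec$cigar)) {
    stop("mapped record without CIGAR in ", path, call. = FALSE)
  }
  if (anyNA(rec$rname) || anyNA(rec$pos)) {
    stop("mapped record with unknown reference name or position in ", path,
         call. = FALSE)
  }
  ops <- GenomicAlignments::explodeCigarOps(rec$cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(rec$cigar)
  geom <- purrr::map2(ops, lens, .cigar_query_geometry)
  lead <- vapply(geom, `[[`, 0, "lead")
  span <- vapply(geom, `[[`, 0, "span")
  qlen <- vapply(geom, `[[`, 0, "qlen")
  ref_span <- GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar)
  aligned <- vapply(geom, `[[`, 0, "aligned")
  rev <- bitwAnd(rec$flag, 16L) != 0L
  qs <- ifelse(rev, qlen - (lead + span), lead)
  qe <- ifelse(rev, qlen - lead, lead + span)
  score <- rec$tag$AS
  if (is.null(score)) score <- rep(NA_real_, n)
  score <- ifelse(is.na(score), aligned * match_score, as.numeric(score))
  tibble::tibble(
    read_id = rec$qname,
    query_start = as.integer(qs),
    query_end = as.integer(qe),
    chrom = as.character(rec$rname),
    ref_start = rec$pos - 1L,
    ref_end = rec$pos - 1L + as.integer(ref_span),
    strand = ifelse(rev, "-", "+"),
    score = score,
    aligned_bases = as.integer(aligned)
  )
}

# Leading clip length, query span of aligned ops, total query length
# (including hard clips) and aligned-base count from exploded CIGAR ops.
.cigar_query_geometry <- function(op, len) {
  n <- length(op)
  clip <- op %in% c("S", "H")
  first_aln <- which(!clip)[1]
  if (is.na(first_aln)) stop("CIGAR with no aligned operation", call. = FALSE)
  last_aln <- max(which(!clip))
  consumes_query <- op %in% c("M", "I", "=", "X")
  list(
    lead = sum(len[seq_len(first_aln - 1L)][clip[seq_len(first_aln - 1L)]]),
    span = sum(len[first_aln:last_aln][consumes_query[first_aln:last_aln]]),
    qlen = sum(len[consumes_query | clip]),
    aligned = sum(len[op %in% c("M", "=", "X")])
  )
}

empty_segments <- function() {
  tibble::tibble(
    read_id = character(), query_start = integer(), query_end = integer(),
    chrom = character(), ref_start = integer(), ref_end = integer(),
    strand = character(), score = numeric(), aligned_bases = integer()
  )
}

.bed_alignment_cols <- c("chrom", "ref_start", "ref_end", "read_id", "score",
                         "strand", "query_start", "query_end", "role",
                         "junction_kind", "junction_size", "cluster_id")

#' Write / read alignment BED summaries
#'
#' One line per alignment segment, 0-based half-open, ordered by
#' (`read_id`, `query_start`). Beyond the six standard BED columns the file
#' carries the query interval, the segment role (`flank`/`insertion`), the
#' junction to the next segment of the same read, and (for clustered output)
#' the cluster assignment. A commented header line makes the file
#' self-describing; `read_alignment_bed()` round-trips it.
#'
#' @param segments An annotated segment tibble (see [annotate_events()]); the
#'   junction and cluster columns are optional and written as "." when absent.
#' @param path Output path.
#' @return `write_alignment_bed()` returns `path` invisibly;
#'   `read_alignment_bed()` returns the segment tibble.
#' @export
write_alignment_bed <- function(segments, path) {
  out <- tibble::as_tibble(segments)
  for (col in .bed_alignment_cols) {
    if (!col %in% names(out)) out[[col]] <- NA
  }
  out <- out[.bed_alignment_cols]
  out <- dplyr::arrange(out, .data$read_id, .data$query_start)
  fmt <- dplyr::mutate(out, dplyr::across(
    dplyr::everything(),
    ~ ifelse(is.na(.x), ".", as.character(.x))
  ))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(.bed_alignment_cols, collapse = "\t")), con)
  if (nrow(fmt)) {
    writeLines(do.call(paste, c(unname(as.list(fmt)), sep = "\t")), con)
  }
  invisible(path)
}

#' @rdname write_alignment_bed
#' @export
read_alignment_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) {
    out <- empty_segments()
    out$role <- character()
    out$junction_kind <- character()
    out$junction_size <- integer()
    out$cluster_id <- integer()
    return(out)
  }
  tb <- readr::read_tsv(I(lines), col_names = .bed_alignment_cols,
                        col_types = "ciicdciiccii", na = ".", progress = FALSE)
  tibble::as_tibble(tb)
}

#' @rdname write_alignment_bed
#' @param clusters A cluster assignment tibble (see [cluster_events()]) whose
#'   columns are joined onto `segments` by `read_id` before writing.
#' @export
write_cluster_bed <- function(segments, clusters, path) {
  ann <- dplyr::left_join(
    dplyr::select(segments, -dplyr::any_of("cluster_id")),
    dplyr::select(clusters, "read_id", "cluster_id"),
    by = "read_id"
  )
  write_alignment_bed(ann, path)
}
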