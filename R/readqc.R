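#' k-mer repetitiveness score
#'
#' Quantifies how repetitive a sequence is as `1 - distinct k-mers / total
#' k-mers`, clamped to `[0, 1]`. A maximally diverse sequence scores near 0;
#' a pure repeat (homopolymer, short tandem array) approaches 1, and the
#' score grows monotonically as a fixed unit is duplicated. Sequences
#' shorter than `k` score 0 by definition.
#'
#' @param sequence Character vector of nucleotide sequences.
#' @param k k-mer size.
#' @return Numeric vector of scores in `[0, 1]`.
#' @examples
#' repetitiveness_score(strrep("A", 200)) # ~1
#' @export
repetitiveness_score <- function(sequence, k = 8) {
  vapply(sequence, function(s) {
    n <- nchar(s)
    if (n < k) return(0)
    km <- substring(s, 1:(n - k + 1L), k:n)
    max(0, min(1, 1 - length(unique(km)) / length(km)))
  }, 0, USE.NAMES = FALSE)
}

#' Telomere-motif k-mer fraction
#'
#' Fraction of overlapping 6-mers of a sequence that are rotations of a
#' telomere repeat unit (by default `TTAGGG` and its reverse complement
#' `CCCTAA`). Used to exempt genuine telomere repeat arrays from the
#' low-complexity artefact filter.
#'
#' @param sequence Character vector.
#' @param motifs Telomere repeat units; every rotation of each counts.
#' @return Numeric vector of fractions in `[0, 1]`; sequences shorter than
#'   6 nt return 0.
#' @examples
#' telomere_kmer_fraction(strrep("TTAGGG", 10)) # 1
#' @export
telomere_kmer_fraction <- function(sequence, motifs = c("TTAGGG", "CCCTAA")) {
  rot <- unique(unlist(lapply(toupper(motifs), function(m) {
    n <- nchar(m)
    vapply(seq_len(n), function(i) {
      paste0(substr(m, i, n), substr(m, 1, i - 1L))
    }, "")
  })))
  k <- nchar(motifs[1])
  vapply(sequence, function(s) {
    n <- nchar(s)
    if (n < k) return(0)
    km <- substring(toupper(s), 1:(n - k + 1L), k:n)
    mean(km %in% rot)
  }, 0, USE.NAMES = FALSE)
}

#' Detect low-complexity (tandem repeat) blocks in a read
#'
#' Built-in masker: slides fixed-length windows along the sequence and flags
#' a window when, for some repeat period `p` in `1..max_period`, fewer than
#' `mismatch_frac` of positions differ from the position `p` bases ahead.
#' Overlapping flagged windows are merged into maximal blocks. Alternatively
#' an externally masked sequence (low-complexity tracts in lowercase) may be
#' supplied with `use_lowercase = TRUE`, in which case blocks are the
#' lowercase runs.
#'
#' @param sequence A single nucleotide sequence.
#' @param config A [fusion_config()] (supplies the repetitiveness k-mer size
#'   and telomere motif set for the per-block annotations).
#' @param max_period Largest tandem period considered.
#' @param window,step Window length and stride (bp).
#' @param mismatch_frac Maximum within-window mismatch fraction at the best
#'   period for the window to be called repetitive.
#' @param use_lowercase Treat lowercase runs in `sequence` as the blocks
#'   instead of running the built-in detector.
#' @return A tibble with one row per block: `start`, `end` (0-based
#'   half-open), `repetitiveness`, `telomere_fraction`.
#' @export
mask_low_complexity <- function(sequence, config = fusion_config(),
                                max_period = 24, window = 36, step = 12,
                                mismatch_frac = 0.2, use_lowercase = FALSE) {
  stopifnot(length(sequence) == 1L, nchar(sequence) > 0L)
  n <- nchar(sequence)
  empty <- tibble::tibble(start = integer(), end = integer(),
                          repetitiveness = numeric(),
                          telomere_fraction = numeric())
  if (use_lowercase) {
    m <- gregexpr("[acgtn]+", sequence)[[1]]
    if (m[1] == -1L) return(empty)
    starts <- as.integer(m) - 1L
    ends <- starts + attr(m, "match.length")
  } else {
    if (n < window) return(empty)
    x <- utf8ToInt(toupper(sequence))
    starts_grid <- seq(0L, n - window, by = step)
    flagged <- rep(FALSE, length(starts_grid))
    for (p in seq_len(min(max_period, window - 1L))) {
      neq <- as.integer(x[seq_len(n - p)] != x[(p + 1L):n])
      cs <- c(0L, cumsum(neq))
      ncmp <- window - p
      ok <- starts_grid + ncmp <= n - p
      mf <- rep(1, length(starts_grid))
      mf[ok] <- (cs[starts_grid[ok] + ncmp + 1L] - cs[starts_grid[ok] + 1L]) / ncmp
      flagged <- flagged | (mf < mismatch_frac)
    }
    if (!any(flagged)) return(empty)
    fs <- starts_grid[flagged]
    brk <- c(TRUE, diff(fs) > step)
    grp <- cumsum(brk)
    starts <- as.integer(tapply(fs, grp, min))
    ends <- as.integer(tapply(fs, grp, max) + window)
  }
  blocks <- substring(sequence, starts + 1L, ends)
  tibble::tibble(
    start = starts,
    end = pmin(ends, n),
    repetitiveness = repetitiveness_score(blocks, k = config$repetitiveness_k),
    telomere_fraction = telomere_kmer_fraction(blocks,
                                               motifs = config$telomere_motifs)
  )
}

#' Flag reads containing low-complexity sequencing artefacts
#'
#' A read is deemed an artefact and marked `artifact_low_complexity` when it
#' contains a low-complexity block longer than `min_block_len` whose
#' repetitiveness score exceeds `repetitiveness_cutoff` -- unless the block
#' is more than `telomere_kmer_fraction` telomere repeat motifs, which keeps
#' reads harbouring genuine telomere repeat arrays regardless of how
#' repetitive they are.
#'
#' @param reads A read tibble.
#' @param config A [fusion_config()].
#' @param ... Passed on to [mask_low_complexity()].
#' @return `reads` with `qc_status` updated, plus a `qc_blocks` list-column
#'   holding each read's block table.
#' @export
filter_artifacts <- function(reads, config = fusion_config(), ...) {
  blocks <- purrr::map(reads$sequence, mask_low_complexity, config = config, ...)
  bad <- purrr::map_lgl(blocks, function(b) {
    any(b$end - b$start > config$min_block_len &
          b$telomere_fraction <= config$telomere_kmer_fraction &
          b$repetitiveness > config$repetitiveness_cutoff)
  })
  reads$qc_status <- ifelse(reads$qc_status == "pass" & bad,
                            "artifact_low_complexity", reads$qc_status)
  reads$qc_blocks <- blocks
  reads
}

# Local alignment of one subject sequence against a set of windows.
# Returns score and 0-based [start, end) of the matched stretch per window.
.local_align <- function(windows, target, config) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = config$match, mismatch = config$mismatch, baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(windows),
    subject = Biostrings::DNAString(target),
    type = "local", substitutionMatrix = mat,
    gapOpening = config$gap_open, gapExtension = config$gap_extend)
  pr <- Biostrings::pattern(al)
  tibble::tibble(score = Biostrings::score(al),
                 start = BiocGenerics::start(pr) - 1L,
                 end = BiocGenerics::end(pr))
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Fast prescreen: which interior sequences share an exact seed-length word
# with any primer alignment target (either orientation)?
.primer_word_hits <- function(interiors, primers, word = 13L) {
  targets <- c(primers$alignment_target, .revcomp(primers$alignment_target))
  words <- unique(unlist(lapply(targets, function(t) {
    n <- nchar(t)
    if (n < word) return(character())
    substring(t, 1:(n - word + 1L), word:n)
  })))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(words))
  hits <- Biostrings::vwhichPDict(pd, Biostrings::DNAStringSet(interiors))
  lengths(hits) > 0L
}

#' Detect concatemeric reads
#'
#' A concatemer (two or more amplicons read as one molecule) betrays itself
#' by a PCR primer match in the interior of the read, away from both ends.
#' The interior (read minus an `end_window` at each side) is screened for
#' each primer's alignment target in both orientations; a local alignment
#' scoring at least `score_fraction` of the maximum possible score marks the
#' read `artifact_concatemer`. Reads too short to have an interior are never
#' concatemers.
#'
#' @param reads A read tibble (low-complexity filtering already applied).
#' @param primers A primer tibble ([read_primers()]).
#' @param config A [fusion_config()].
#' @return `reads` with `qc_status` updated.
#' @export
detect_concatemers <- function(reads, primers, config = fusion_config()) {
  w <- config$end_window
  len <- nchar(reads$sequence)
  eligible <- reads$qc_status == "pass" & len > 2L * w
  if (!any(eligible)) return(reads)
  interiors <- substr(reads$sequence[eligible], w + 1L, len[eligible] - w)
  cand <- .primer_word_hits(interiors, primers)
  hit <- rep(FALSE, length(interiors))
  if (any(cand)) {
    max_score <- config$match * nchar(primers$alignment_target)
    for (i in seq_len(nrow(primers))) {
      for (target in c(primers$alignment_target[i],
                       .revcomp(primers$alignment_target[i]))) {
        idx <- which(cand & !hit)
        if (!length(idx)) break
        sc <- .local_align(interiors[idx], target, config)$score
        hit[idx[sc >= config$score_fraction * max_score[i]]] <- TRUE
      }
    }
  }
  reads$qc_status[which(eligible)[hit]] <- "artifact_concatemer"
  reads
}

#' Label and trim reads by PCR primer
#'
#' Each end of the retained sequence is searched, within an `end_window`,
#' against every primer's 68-bp alignment target: the leading end in forward
#' orientation and the trailing end in reverse complement (amplicons are
#' sequenced from either strand, so the trailing end carries the reverse
#' complement of a target). The best match reaching `score_fraction` of the
#' maximum alignment score labels the end with the primer name and trims the
#' read to the start of the alignment (leading end) or its end (trailing
#' end). Ends without a qualifying match keep the absent marker (`NA`).
#' Windows are truncated at the read midpoint on very short reads, and the
#' operation is idempotent: re-labelling an already trimmed read changes
#' nothing.
#'
#' @inheritParams detect_concatemers
#' @param both_orientations Also search the leading end in reverse complement
#'   and the trailing end forward (off by default; the standard amplicon
#'   layout does not need it).
#' @return `reads` with `primer_start`, `primer_end`, `trim_start`,
#'   `trim_end` updated.
#' @export
label_primers <- function(reads, primers, config = fusion_config(),
                          both_orientations = FALSE) {
  if (!nrow(reads)) return(reads)
  idx <- which(reads$qc_status == "pass")
  if (!length(idx)) return(reads)
  seqs <- read_sequences(reads)[idx]
  len <- nchar(seqs)
  w <- pmin(config$end_window, ceiling(len / 2))
  win5 <- substr(seqs, 1L, w)
  win3 <- substr(seqs, len - w + 1L, len)
  max_score <- config$match * nchar(primers$alignment_target)

  best <- function(windows, orientations) {
    out <- tibble::tibble(name = NA_character_, score = -Inf,
                          start = NA_integer_, end = NA_integer_,
                          .rows = length(windows))
    for (i in seq_len(nrow(primers))) {
      for (orient in orientations) {
        target <- if (orient == "+") primers$alignment_target[i] else
          .revcomp(primers$alignment_target[i])
        al <- .local_align(windows, target, config)
        ok <- al$score >= config$score_fraction * max_score[i] &
          al$score > out$score
        out$name[ok] <- primers$name[i]
        out$score[ok] <- al$score[ok]
        out$start[ok] <- al$start[ok]
        out$end[ok] <- al$end[ok]
      }
    }
    out
  }
  b5 <- best(win5, if (both_orientations) c("+", "-") else "+")
  b3 <- best(win3, if (both_orientations) c("-", "+") else "-")

  hit5 <- !is.na(b5$name)
  hit3 <- !is.na(b3$name)
  reads$primer_start[idx] <- b5$name
  reads$primer_end[idx] <- b3$name
  ts <- reads$trim_start[idx]
  te <- reads$trim_end[idx]
  ts[hit5] <- ts[hit5] + b5$start[hit5]
  off3 <- len - w  # window 3' starts here (0-based, within retained seq)
  te[hit3] <- reads$trim_start[idx][hit3] + off3[hit3] + b3$end[hit3]
  reads$trim_start[idx] <- ts
  reads$trim_end[idx] <- te
  reads
}

#' Run the full read-QC stage
#'
#' Applies the low-complexity artefact filter, concatemer detection, and
#' primer labelling/trimming in order.
#'
#' @inheritParams detect_concatemers
#' @param ... Passed to [filter_artifacts()].
#' @return `reads` with QC verdicts, primer labels and trimmed intervals; a
#'   discard table is attached as attribute `"discards"` (columns `read_id`,
#'   `qc_status`, `block_start`, `block_end`, with the paper-style `"False"`
#'   absent markers materialised).
#' @export
qc_reads <- function(reads, primers, config = fusion_config(), ...) {
  reads <- filter_artifacts(reads, config, ...)
  reads <- detect_concatemers(reads, primers, config)
  reads <- label_primers(reads, primers, config)
  disc <- dplyr::filter(reads, .data$qc_status != "pass")
  block <- purrr::map(disc$qc_blocks %||% list(), function(b) {
    if (is.null(b) || !nrow(b)) tibble::tibble(start = NA_integer_,
                                               end = NA_integer_)
    else b[which.max(b$end - b$start), c("start", "end")]
  })
  discards <- tibble::tibble(
    read_id = disc$read_id,
    qc_status = disc$qc_status,
    block_start = purrr::map_int(block, ~ .x$start[1]),
    block_end = purrr::map_int(block, ~ .x$end[1])
  )
  attr(reads, "discards") <- discards
  reads
}

`%||%` <- function(a, b) if (is.null(a)) b else a
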