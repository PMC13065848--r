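#' Simulator configuration
#'
#' Study conditions for the synthetic fusion-event generator: insertion
#' lengths follow a gamma distribution with mean 900 bp and standard
#' deviation 1600 bp, insertion counts per event a Poisson with mean 5, and
#' per-event amplification (read counts) a gamma with mean 15 and standard
#' deviation 35. Gamma distributions are parameterised by moment matching
#' (`shape = (mean/sd)^2`, `scale = sd^2/mean`); lengths and read counts are
#' rounded to the nearest integer with a minimum of 1.
#'
#' @param n_events Number of fusion events to generate.
#' @param insertion_len_mean,insertion_len_sd Gamma moments for insertion
#'   length (bp).
#' @param insertion_count_mean Poisson mean of insertions per event (0 is
#'   allowed and yields a simple head-to-head fusion).
#' @param amplification_mean,amplification_sd Gamma moments for reads per
#'   event.
#' @param error_rate Total per-base error rate of the built-in read
#'   corruption model.
#' @param sub_frac,ins_frac,del_frac Relative weights of substitutions,
#'   insertions and deletions (nanopore-like 40/30/30 by default).
#' @param rng_seed Optional integer seed recorded for provenance; sampling
#'   itself uses R's RNG, so call `set.seed()` (or pass `--seed` to the CLI)
#'   before simulating.
#' @return A named list with class `"sim_config"`.
#' @export
sim_config <- function(n_events = 3000,
                       insertion_len_mean = 900,
                       insertion_len_sd = 1600,
                       insertion_count_mean = 5,
                       amplification_mean = 15,
                       amplification_sd = 35,
                       error_rate = 0.05,
                       sub_frac = 0.4,
                       ins_frac = 0.3,
                       del_frac = 0.3,
                       rng_seed = NULL) {
  stopifnot(n_events >= 1, insertion_len_mean > 0, insertion_len_sd > 0,
            insertion_count_mean > 0, amplification_mean > 0,
            amplification_sd > 0, error_rate >= 0, error_rate < 1)
  structure(list(
    n_events = n_events,
    insertion_len_mean = insertion_len_mean,
    insertion_len_sd = insertion_len_sd,
    insertion_count_mean = insertion_count_mean,
    amplification_mean = amplification_mean,
    amplification_sd = amplification_sd,
    error_rate = error_rate,
    sub_frac = sub_frac, ins_frac = ins_frac, del_frac = del_frac,
    rng_seed = rng_seed
  ), class = "sim_config")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build a miniature test reference
#'
#' Generates a deterministic (given the RNG state) reference bundle for
#' simulation and testing: random pseudo-chromosomes, sub-telomere contigs
#' whose unique sequence terminates in a telomere repeat array, decoy
#' plasmid / E. coli / mitochondrial contigs tagged in the origin catalogue,
#' and one PCR primer per sub-telomere with a 68-bp alignment target.
#'
#' @param n_chrom,chrom_len Number and length (bp) of pseudo-chromosomes.
#' @param n_subtel Number of sub-telomere contigs (and primers).
#' @param subtel_len Sub-telomere length including the telomere array.
#' @param telomere_repeats Number of terminal `TTAGGG` units per
#'   sub-telomere (at least 20 by construction).
#' @param primer_len Primer length (nt).
#' @return A list with class `"fusion_reference"`: `sequences` (named
#'   character vector), `catalogue` (tibble `chrom`, `origin`), `primers`
#'   (primer tibble), `subtelomeres` (contig names).
#' @examples
#' set.seed(1)
#' ref <- simulate_reference(n_chrom = 2, chrom_len = 5000)
#' ref$catalogue
#' @export
simulate_reference <- function(n_chrom = 8, chrom_len = 100000,
                               n_subtel = 3, subtel_len = 2000,
                               telomere_repeats = 25, primer_len = 20) {
  stopifnot(telomere_repeats >= 20)
  chroms <- setNames(
    vapply(seq_len(n_chrom), function(i) .random_dna(chrom_len), ""),
    paste0("chr", seq_len(n_chrom))
  )
  tel <- strrep("TTAGGG", telomere_repeats)
  sub_names <- paste0("subtel_", seq_len(n_subtel))
  subtels <- setNames(vapply(seq_len(n_subtel), function(i) {
    paste0(.random_dna(subtel_len - nchar(tel)), tel)
  }, ""), sub_names)
  decoys <- c(
    TALEN_L1 = .random_dna(5000),
    TALEN_R1 = .random_dna(5000),
    ECOLI_1 = .random_dna(20000),
    chrM = .random_dna(16000)
  )
  catalogue <- tibble::tibble(
    chrom = c(names(chroms), sub_names, names(decoys)),
    origin = c(rep("chromosomal", n_chrom + n_subtel),
               "external_plasmid", "external_plasmid",
               "external_ecoli", "mitochondrial")
  )
  primers <- purrr::map_dfr(sub_names, function(nm) {
    primer_spec(
      name = paste0("P_", nm),
      primer_seq = substr(subtels[[nm]], 1, primer_len),
      alignment_target = substr(subtels[[nm]], 1, 68)
    )
  })
  primers$subtelomere <- sub_names
  structure(list(
    sequences = c(chroms, subtels, decoys),
    catalogue = catalogue,
    primers = primers,
    subtelomeres = sub_names
  ), class = "fusion_reference")
}

#' @export
print.fusion_reference <- function(x, ...) {
  cat("<fusion_reference> ", length(x$sequences), " contigs, ",
      sum(nchar(x$sequences)), " bp; ", length(x$subtelomeres),
      " sub-telomeres / primers\n", sep = "")
  invisible(x)
}

#' Write a reference bundle to disk
#'
#' @param reference A [simulate_reference()] bundle.
#' @param dir Output directory; writes `reference.fa`, `catalogue.tsv`,
#'   `primers.tsv`.
#' @return The directory, invisibly.
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(reference$sequences),
    file.path(dir, "reference.fa"))
  readr::write_tsv(reference$catalogue, file.path(dir, "catalogue.tsv"),
                   progress = FALSE)
  write_primers(reference$primers[c("name", "primer_seq", "alignment_target")],
                file.path(dir, "primers.tsv"))
  invisible(dir)
}

#' Sample insertion lengths
#'
#' Gamma draws with moment-matched shape and scale, rounded to the nearest
#' integer with a floor of 1 bp.
#'
#' @param n Number of draws.
#' @param config A [sim_config()].
#' @return Integer vector of lengths (>= 1).
#' @export
sample_insertion_length <- function(n, config = sim_config()) {
  shape <- (config$insertion_len_mean / config$insertion_len_sd)^2
  scale <- config$insertion_len_sd^2 / config$insertion_len_mean
  pmax(1L, as.integer(round(rgamma(n, shape = shape, scale = scale))))
}

#' Sample per-event amplification levels
#'
#' @inheritParams sample_insertion_length
#' @return Integer vector of read counts (>= 1). The rounding floor biases
#'   the mean upwards by at most +0.5 reads at the default moments
#'   (shape ~ 0.18 puts a large mass below one read).
#' @export
sample_amplification <- function(n, config = sim_config()) {
  shape <- (config$amplification_mean / config$amplification_sd)^2
  scale <- config$amplification_sd^2 / config$amplification_mean
  pmax(1L, as.integer(round(rgamma(n, shape = shape, scale = scale))))
}

#' Generate synthetic fusion events
#'
#' Each event joins a left sub-telomere, a Poisson-distributed number of
#' insertions copied from uniformly random positions and strands of the
#' pseudo-chromosomes, and the reverse complement of a right sub-telomere
#' (so the two telomere arrays face each other head-to-head). Insertions
#' longer than their chromosome are resampled.
#'
#' @param reference A [simulate_reference()] bundle.
#' @param config A [sim_config()].
#' @return A truth tibble: `event_id`, `subtel_left`, `subtel_right`,
#'   `n_insertions`, `amplification`, `insertions` (list-column of tibbles
#'   `chrom`, `ref_start`, `ref_end`, `strand`, `size`), `sequence`.
#' @export
simulate_fusion_events <- function(reference, config = sim_config()) {
  chrom_names <- names(reference$sequences)[
    startsWith(names(reference$sequences), "chr") &
      names(reference$sequences) != "chrM"]
  chrom_len <- nchar(reference$sequences[chrom_names])
  n <- config$n_events
  counts <- rpois(n, config$insertion_count_mean)
  left <- sample(reference$subtelomeres, n, replace = TRUE)
  right <- sample(reference$subtelomeres, n, replace = TRUE)
  amp <- sample_amplification(n, config)

  total <- sum(counts)
  event_of <- rep(seq_len(n), counts)
  lens <- sample_insertion_length(total, config)
  chrom <- sample(chrom_names, total, replace = TRUE)
  repeat {
    bad <- lens > chrom_len[chrom]
    if (!any(bad)) break
    lens[bad] <- sample_insertion_length(sum(bad), config)
    chrom[bad] <- sample(chrom_names, sum(bad), replace = TRUE)
  }
  start <- as.integer(floor(runif(total, 0, chrom_len[chrom] - lens + 1)))
  strand <- sample(c("+", "-"), total, replace = TRUE)
  all_ins <- tibble::tibble(chrom = chrom, ref_start = start,
                            ref_end = start + lens, strand = strand,
                            size = lens)
  insertions <- unname(split(
    all_ins, factor(event_of, levels = seq_len(n))))

  piece <- substring(reference$sequences[chrom], start + 1L, start + lens)
  minus <- strand == "-"
  if (any(minus)) piece[minus] <- .revcomp(piece[minus])
  mids <- vapply(split(piece, factor(event_of, levels = seq_len(n))),
                 paste, "", collapse = "")
  rc_subtel <- setNames(.revcomp(reference$sequences[reference$subtelomeres]),
                        reference$subtelomeres)
  seqs <- paste0(unname(reference$sequences[left]), mids,
                 unname(rc_subtel[right]))

  tibble::tibble(
    event_id = sprintf("event%04d", seq_len(n)),
    subtel_left = left,
    subtel_right = right,
    n_insertions = counts,
    amplification = amp,
    insertions = insertions,
    sequence = seqs
  )
}

#' Truth-encoding read identifiers
#'
#' The simulator encodes each read's full ground truth in its identifier:
#' `event{k}|n={count}|{chrom}:{start}-{end}:{strand};...|read{j}` (0-based
#' half-open insertion coordinates; the coordinate block is empty for
#' insertion-free events). `decode_truth_ids()` inverts the encoding.
#'
#' @param event_id,insertions,read_index Components to encode.
#' @return `encode_truth_id()` a character scalar; `decode_truth_ids()` a
#'   tibble `read_id`, `event_id`, `n_insertions`, `insertions` (list-col).
#' @export
encode_truth_id <- function(event_id, insertions, read_index) {
  coords <- if (nrow(insertions)) {
    paste(sprintf("%s:%d-%d:%s", insertions$chrom, insertions$ref_start,
                  insertions$ref_end, insertions$strand), collapse = ";")
  } else ""
  sprintf("%s|n=%d|%s|read%d", event_id, nrow(insertions), coords, read_index)
}

#' @rdname encode_truth_id
#' @param read_ids Character vector of encoded identifiers.
#' @export
decode_truth_ids <- function(read_ids) {
  parts <- stringr::str_split(read_ids, stringr::fixed("|"))
  bad <- lengths(parts) != 4L
  if (any(bad)) {
    stop("not a truth-encoded read id: ", read_ids[bad][1], call. = FALSE)
  }
  purrr::map2_dfr(parts, read_ids, function(p, id) {
    n <- as.integer(sub("^n=", "", p[2]))
    ins <- if (nzchar(p[3])) {
      m <- stringr::str_match(
        strsplit(p[3], ";", fixed = TRUE)[[1]],
        "^(.+):(\\d+)-(\\d+):([+-])$")
      tibble::tibble(chrom = m[, 2],
                     ref_start = as.integer(m[, 3]),
                     ref_end = as.integer(m[, 4]),
                     strand = m[, 5],
                     size = as.integer(m[, 4]) - as.integer(m[, 3]))
    } else {
      tibble::tibble(chrom = character(), ref_start = integer(),
                     ref_end = integer(), strand = character(),
                     size = integer())
    }
    if (nrow(ins) != n) stop("inconsistent truth id: ", id, call. = FALSE)
    tibble::tibble(read_id = id, event_id = p[1], n_insertions = n,
                   insertions = list(ins))
  })
}

#' Simulate sequencing reads from fusion events
#'
#' Emits `amplification` reads per event, each a copy of the event sequence
#' (reverse-complemented for a random half, as amplicons are sequenced from
#' either strand) corrupted by the built-in error model: per-base errors at
#' `error_rate`, split between substitutions, insertions and deletions.
#' Read identifiers carry the full ground truth ([encode_truth_id()]); a
#' FASTQ produced by an external simulator that preserves the identifier
#' convention can be used as a drop-in anywhere downstream.
#'
#' @param truth A [simulate_fusion_events()] tibble.
#' @param config A [sim_config()].
#' @return A read tibble ([read_fastq()] layout).
#' @export
simulate_reads <- function(truth, config = sim_config()) {
  idx <- rep(seq_len(nrow(truth)), truth$amplification)
  read_index <- sequence(truth$amplification)
  ids <- purrr::map2_chr(idx, read_index, function(i, j) {
    encode_truth_id(truth$event_id[i], truth$insertions[[i]], j)
  })
  seqs <- truth$sequence[idx]
  flip <- runif(length(seqs)) < 0.5
  seqs[flip] <- .revcomp(seqs[flip])
  if (config$error_rate > 0) {
    seqs <- cpp_mutate_reads(seqs, config$error_rate, config$sub_frac,
                             config$ins_frac, config$del_frac)
  }
  new_reads(read_id = ids, sequence = seqs)
}

#' One-call simulation of a full test data set
#'
#' Convenience wrapper: builds a reference bundle, simulates events and
#' reads, and returns everything needed to run and benchmark the pipeline.
#'
#' @param config A [sim_config()].
#' @param ... Passed to [simulate_reference()].
#' @return A list: `reference`, `truth`, `reads`, `config`.
#' @export
simulate_dataset <- function(config = sim_config(), ...) {
  reference <- simulate_reference(...)
  truth <- simulate_fusion_events(reference, config)
  reads <- simulate_reads(truth, config)
  list(reference = reference, truth = truth, reads = reads, config = config)
}
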