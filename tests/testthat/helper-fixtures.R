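# Shared fixtures, built in code once per test run.

# small deterministic reference bundle for module tests
tiny_ref <- local({
  set.seed(101)
  simulate_reference(n_chrom = 2, chrom_len = 20000, n_subtel = 2,
                     subtel_len = 1200, telomere_repeats = 20)
})

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

make_reads <- function(sequences, ids = sprintf("r%03d", seq_along(sequences))) {
  tibble::tibble(
    read_id = ids,
    sequence = sequences,
    quality = NA_character_,
    qc_status = "pass",
    primer_start = NA_character_,
    primer_end = NA_character_,
    trim_start = 0L,
    trim_end = nchar(sequences)
  )
}

make_segment <- function(read_id = "r1", query_start = 0L, query_end = 100L,
                         chrom = "chr1", ref_start = 0L, ref_end = NULL,
                         strand = "+", score = NULL, aligned_bases = NULL) {
  if (is.null(ref_end)) ref_end <- ref_start + (query_end - query_start)
  if (is.null(aligned_bases)) aligned_bases <- query_end - query_start
  if (is.null(score)) score <- 2 * aligned_bases
  tibble::tibble(read_id = read_id,
                 query_start = as.integer(query_start),
                 query_end = as.integer(query_end),
                 chrom = chrom,
                 ref_start = as.integer(ref_start),
                 ref_end = as.integer(ref_end),
                 strand = strand, score = score,
                 aligned_bases = as.integer(aligned_bases))
}

# segments for one read laid out consecutively on the query, with given
# junction offsets (positive = microhomology, negative = gap)
make_chain <- function(read_id, lens, offsets = rep(0L, length(lens) - 1L),
                       chroms = rep("chr1", length(lens)),
                       ref_starts = seq(0L, by = 2000L,
                                        length.out = length(lens)),
                       strands = rep("+", length(lens))) {
  qs <- integer(length(lens)); qe <- integer(length(lens))
  cur <- 0L
  for (i in seq_along(lens)) {
    if (i > 1L) cur <- qe[i - 1L] - offsets[i - 1L]
    qs[i] <- cur
    qe[i] <- cur + lens[i]
  }
  purrr::pmap_dfr(
    list(qs, qe, chroms, ref_starts, strands),
    function(a, b, cm, rs, st) {
      make_segment(read_id, a, b, cm, rs, strand = st)
    })
}

write_sam <- function(records, ref_lengths = c(chr1 = 10000), path = NULL) {
  if (is.null(path)) path <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths), ref_lengths))
  writeLines(c(hdr, records), path)
  path
}

sam_record <- function(qname, flag, rname, pos, cigar, seq,
                       mapq = 60, tags = character()) {
  paste(c(qname, flag, rname, pos, mapq, cigar, "*", 0, 0, seq,
          strrep("I", nchar(seq)), tags), collapse = "\t")
}
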