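# Independent oracles used to freeze expected values.

# Exhaustive subset search for the spanning-set objective: enumerate every
# subset, order by query_start, check chain validity (strictly increasing
# starts and ends, consecutive overlap at most half the shorter segment),
# and score sum(score) - penalty * sum(consecutive overlaps).
brute_spanning <- function(cand, penalty = 2) {
  n <- nrow(cand)
  best_val <- -Inf
  best_rows <- integer()
  for (mask in seq_len(2^n) - 1L) {
    rows <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    if (!length(rows)) next
    sub <- cand[rows, ]
    sub <- sub[order(sub$query_start, sub$query_end), ]
    ok <- TRUE
    val <- sum(sub$score)
    if (nrow(sub) > 1L) {
      for (i in 2:nrow(sub)) {
        if (sub$query_start[i] <= sub$query_start[i - 1L] ||
            sub$query_end[i] <= sub$query_end[i - 1L]) { ok <- FALSE; break }
        ov <- max(0L, sub$query_end[i - 1L] - sub$query_start[i])
        len_i <- sub$query_end[i] - sub$query_start[i]
        len_p <- sub$query_end[i - 1L] - sub$query_start[i - 1L]
        if (2L * ov > min(len_i, len_p)) { ok <- FALSE; break }
        val <- val - penalty * ov
      }
    }
    if (ok && val > best_val) { best_val <- val; best_rows <- rows }
  }
  list(value = best_val, rows = best_rows)
}

spanning_objective <- function(chosen, penalty = 2) {
  chosen <- chosen[order(chosen$query_start), ]
  val <- sum(chosen$score)
  if (nrow(chosen) > 1L) {
    for (i in 2:nrow(chosen)) {
      val <- val - penalty *
        max(0L, chosen$query_end[i - 1L] - chosen$query_start[i])
    }
  }
  val
}

random_candidates <- function(n, read_len = 500L) {
  qs <- sample.int(read_len - 30L, n, replace = TRUE) - 1L
  width <- sample(20:200, n, replace = TRUE)
  qe <- pmin(qs + width, read_len)
  make_segment(rep("r1", n), qs, qe,
               chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
               ref_start = sample.int(5000L, n),
               strand = sample(c("+", "-"), n, replace = TRUE),
               score = round(runif(n, 10, 400), 3),
               aligned_bases = qe - qs)
}

# sliding-window count oracle for telomere 6-mer fractions
telomere_fraction_oracle <- function(seq, motifs = c("TTAGGG", "CCCTAA")) {
  rot <- unlist(lapply(motifs, function(m) {
    vapply(seq_len(nchar(m)), function(i) {
      paste0(substr(m, i, nchar(m)), substr(m, 1, i - 1L))
    }, "")
  }))
  n <- nchar(seq)
  hits <- 0L
  for (i in seq_len(n - 5L)) {
    if (substr(seq, i, i + 5L) %in% rot) hits <- hits + 1L
  }
  hits / (n - 5L)
}
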