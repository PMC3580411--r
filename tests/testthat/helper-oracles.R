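# Independent oracles and tiny fixture builders shared across tests.

# Naive O(n*L) sliding-window substring scan: compares every window of the
# read against the two literal patterns. Deliberately independent of the
# package's fixed-string search.
naive_motif_hits <- function(seqs, spec = motif_spec()) {
  seqs <- toupper(seqs)
  W <- nchar(spec$pattern_fwd)
  L <- max(nchar(seqs), 0L)
  hit <- rep(FALSE, length(seqs))
  if (L < W) return(hit)
  for (k in seq_len(L - W + 1L)) {
    win <- substring(seqs, k, k + W - 1L)
    hit <- hit | win == spec$pattern_fwd |
      (spec$both_strands & win == spec$pattern_rev)
  }
  hit
}

# Exact two-sided Mann-Whitney p by full enumeration of group labelings
# (valid for untied data only).
enum_ranksum_p <- function(x, y) {
  pool <- c(x, y)
  stopifnot(!anyDuplicated(pool))
  n1 <- length(x)
  M <- n1 * length(y)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pool), n1)
  u_all <- apply(combos, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  ulo <- min(u_obs, M - u_obs)
  mean(u_all <= ulo | u_all >= M - ulo)
}

# Minimal SAM writer: records are lists with qname, flag, seq, and an
# optional cigar (defaults to full-length match for mapped reads).
write_sam <- function(path, records, rname = "chr1", rlen = 10000L) {
  lines <- c(sprintf("@HD\tVN:1.6\tSO:unsorted"),
             sprintf("@SQ\tSN:%s\tLN:%d", rname, rlen))
  for (r in records) {
    mapped <- bitwAnd(r$flag, 4L) == 0L
    cigar <- if (!is.null(r$cigar)) r$cigar
             else if (mapped) paste0(nchar(r$seq), "M") else "*"
    lines <- c(lines, paste(
      r$qname, r$flag, if (mapped) rname else "*", if (mapped) 1L else 0L,
      if (mapped) 60L else 0L, cigar, "*", 0L, 0L, r$seq,
      strrep("I", nchar(r$seq)), sep = "\t"))
  }
  writeLines(lines, path)
  path
}

random_dna <- function(n, len, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}
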