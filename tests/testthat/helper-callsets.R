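# Shared fixture builders and independent oracles.

# Quick call set from key strings "contig:pos:ref:alt".
make_calls <- function(keys, sample_id = "s1", qual = 50, DP = 30L, QD = 10,
                       FS = 1) {
  if (length(keys) == 0) return(offbase:::empty_callset())
  parts <- strsplit(keys, ":", fixed = TRUE)
  tibble::tibble(
    sample_id = sample_id,
    contig = vapply(parts, `[`, "", 1),
    pos = as.integer(vapply(parts, `[`, "", 2)),
    ref = vapply(parts, `[`, "", 3),
    alt = vapply(parts, `[`, "", 4),
    qual = qual, DP = DP, QD = QD, FS = FS
  )
}

key_of <- function(cs) paste(cs$contig, cs$pos, cs$ref, cs$alt, sep = ":")

# Universe of distinct SNV keys for random-set experiments.
key_universe <- function(n = 300) {
  pos <- seq_len(n)
  ref <- rep(c("A", "C", "G", "T"), length.out = n)
  alt <- rep(c("G", "T", "A", "C"), length.out = n)
  paste("c1", pos, ref, alt, sep = ":")
}

random_callset <- function(universe, n, sample_id = "s1") {
  make_calls(sample(universe, n), sample_id = sample_id)
}

# Independent consensus oracle: explicit per-record membership loops, no joins.
bf_consensus <- function(a, b, c) {
  in_set <- function(row, cs) {
    any(cs$contig == row$contig & cs$pos == row$pos &
          cs$ref == row$ref & cs$alt == row$alt)
  }
  keep <- vapply(seq_len(nrow(a)), function(i) {
    row <- a[i, ]
    in_set(row, b) && in_set(row, c)
  }, logical(1))
  a[keep, , drop = FALSE]
}

# Apply a (padded) variant to a sequence; oracle for indel equivalence.
apply_variant <- function(seq, pos, ref, alt) {
  stopifnot(substr(seq, pos, pos + nchar(ref) - 1) == ref)
  paste0(substr(seq, 1, pos - 1), alt, substr(seq, pos + nchar(ref), nchar(seq)))
}

# Small deterministic reference for IO and cascade unit tests.
tiny_ref <- function() {
  c(c1 = "AACGTTTACGATCCGGATTACAGCGT", c2 = "GGGCATTTACGGATC")
}
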