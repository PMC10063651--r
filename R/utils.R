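# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# The 12 strandless substitution types, in fixed display order.
SUB_TYPES <- c(
  "A>C", "A>G", "A>T",
  "C>A", "C>G", "C>T",
  "G>A", "G>C", "G>T",
  "T>A", "T>C", "T>G"
)

KEY_COLS <- c("contig", "pos", "ref", "alt")

# Reverse complement of short DNA strings (vectorized).
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(
    strsplit(comp, "", fixed = TRUE),
    function(s) paste(rev(s), collapse = ""),
    character(1)
  )
}

# 1-based (VCF) to 0-based (BED) position: the single owner of the boundary.
pos1_to_pos0 <- function(pos) as.integer(pos) - 1L

variant_key <- function(df) {
  paste(df$contig, df$pos, df$ref, df$alt, sep = ":")
}

# Canonical empty call set with the full annotation column block.
empty_callset <- function(sample_id = character(0)) {
  tibble(
    sample_id = sample_id[0],
    contig = character(0), pos = integer(0),
    ref = character(0), alt = character(0),
    qual = double(0), DP = integer(0), QD = double(0), FS = double(0)
  )
}

assert_callset <- function(calls, arg = "calls") {
  if (!is.data.frame(calls)) {
    abort(sprintf("`%s` must be a data frame of variants", arg))
  }
  missing <- setdiff(c("sample_id", KEY_COLS), names(calls))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` lacks required column(s): %s", arg, paste(missing, collapse = ", ")
    ))
  }
  if (nrow(calls) > 0) {
    if (anyNA(calls$pos) || any(calls$pos < 1)) {
      abort(sprintf("`%s` has invalid positions (pos must be >= 1)", arg))
    }
    bad <- calls$ref == calls$alt
    if (any(bad)) {
      abort(sprintf("`%s` has records with ref == alt", arg))
    }
  }
  invisible(calls)
}

assert_reference <- function(ref, arg = "ref") {
  if (!is.character(ref) || is.null(names(ref)) || any(names(ref) == "")) {
    abort(sprintf("`%s` must be a named character vector of contig sequences", arg))
  }
  if (anyDuplicated(names(ref))) abort(sprintf("`%s` has duplicate contig names", arg))
  if (any(nchar(ref) == 0)) abort(sprintf("`%s` has empty contig sequences", arg))
  invisible(ref)
}

contig_base <- function(ref, contig, pos, len = 1L) {
  substr(ref[[contig]], pos, pos + len - 1L)
}

# Deterministic seeding wrapper: functions taking a `seed` argument call this
# once on entry so identical seeds reproduce identical outputs byte-for-byte.
seed_rng <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
      abort("`seed` must be a single integer")
    }
    set.seed(as.integer(seed))
  }
  invisible(seed)
}
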