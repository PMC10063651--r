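#' Define an amplicon target site
#'
#' Describes a sequenced amplicon, the protospacer it contains and the base
#' conversion to quantify. Protospacer positions are numbered 1..length from
#' the PAM-distal end (so "A6" is the sixth protospacer base).
#'
#' @param amplicon_seq Amplicon reference sequence.
#' @param protospacer_start 0-based offset of the protospacer within the
#'   amplicon.
#' @param protospacer_length Protospacer length (default 20).
#' @param conversion Length-2 character `c(from_base, to_base)`.
#' @param positions_of_interest Protospacer positions (1-based) to quantify.
#' @return A `target_site` object.
#' @export
target_site <- function(amplicon_seq, protospacer_start,
                        protospacer_length = 20, conversion = c("C", "T"),
                        positions_of_interest) {
  amplicon_seq <- str_to_upper(amplicon_seq)
  L <- nchar(amplicon_seq)
  if (protospacer_start < 0 ||
      protospacer_start + protospacer_length > L) {
    abort("protospacer must lie within the amplicon")
  }
  if (length(conversion) != 2 || conversion[1] == conversion[2] ||
      any(!conversion %in% DNA_BASES)) {
    abort("`conversion` must be two distinct bases c(from, to)")
  }
  if (any(positions_of_interest < 1 |
          positions_of_interest > protospacer_length)) {
    abort("positions_of_interest must be within 1..protospacer_length")
  }
  structure(
    list(amplicon_seq = amplicon_seq,
         protospacer_start = as.integer(protospacer_start),
         protospacer_length = as.integer(protospacer_length),
         conversion = conversion,
         positions_of_interest = as.integer(positions_of_interest)),
    class = "target_site"
  )
}

#' Read amplicon reads from FASTQ or plain text
#'
#' FASTQ qualities are ignored; plain text is one sequence per line.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"fastq"` or `"lines"`.
#' @return Character vector of uppercase reads.
#' @export
read_amplicon_reads <- function(path, format = c("auto", "fastq", "lines")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fastq|fq)$", path)) "fastq" else "lines"
  }
  if (format == "fastq") {
    reads <- as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
    str_to_upper(unname(reads))
  } else {
    lines <- readLines(path, warn = FALSE)
    str_to_upper(lines[nzchar(lines)])
  }
}

#' Per-position base counts over an amplicon
#'
#' Counts A/C/G/T at every amplicon position across retained reads. Reads
#' whose length differs from the amplicon, or whose mismatch count exceeds
#' the ceiling, are discarded and tallied (gapless read model: short PCR
#' amplicons, no alignment).
#'
#' @param reads Character vector of reads.
#' @param site A [target_site()].
#' @param max_mismatch Mismatch ceiling per read; default 20% of the
#'   amplicon length.
#' @return Tibble `position`, `ref_base`, `A`, `C`, `G`, `T`, `depth`, with
#'   attributes `n_retained`, `n_discarded_length`, `n_discarded_mismatch`.
#' @export
count_bases <- function(reads, site, max_mismatch = NULL) {
  stopifnot(inherits(site, "target_site"))
  L <- nchar(site$amplicon_seq)
  max_mismatch <- max_mismatch %||% ceiling(0.2 * L)
  reads <- str_to_upper(reads)
  len_ok <- nchar(reads) == L
  n_len_drop <- sum(!len_ok)
  reads <- reads[len_ok]
  amp <- strsplit(site$amplicon_seq, "", fixed = TRUE)[[1]]
  if (length(reads) == 0) {
    out <- tibble(position = seq_len(L), ref_base = amp,
                  A = 0L, C = 0L, G = 0L, T = 0L, depth = 0L)
    attr(out, "n_retained") <- 0L
    attr(out, "n_discarded_length") <- n_len_drop
    attr(out, "n_discarded_mismatch") <- 0L
    return(out)
  }
  mat <- do.call(rbind, strsplit(reads, "", fixed = TRUE))
  mm <- rowSums(mat != matrix(amp, nrow = nrow(mat), ncol = L, byrow = TRUE))
  keep <- mm <= max_mismatch
  n_mm_drop <- sum(!keep)
  mat <- mat[keep, , drop = FALSE]
  counts <- vapply(DNA_BASES, function(b) as.integer(colSums(mat == b)),
                   integer(L))
  out <- tibble(
    position = seq_len(L), ref_base = amp,
    A = counts[, "A"], C = counts[, "C"], G = counts[, "G"], T = counts[, "T"],
    depth = as.integer(rowSums(counts))
  )
  attr(out, "n_retained") <- nrow(mat)
  attr(out, "n_discarded_length") <- n_len_drop
  attr(out, "n_discarded_mismatch") <- n_mm_drop
  out
}

#' Base-editing efficiency at protospacer positions
#'
#' For each requested protospacer position, the percentage of retained reads
#' carrying the conversion product:
#' `100 * to_base count / retained reads`. The amplicon reference base at
#' each requested position must equal the conversion source.
#'
#' @param base_counts Output of [count_bases()].
#' @param site The matching [target_site()].
#' @return Tibble `protospacer_position`, `amplicon_position`, `ref_base`,
#'   `n_converted`, `n_total`, `efficiency` (percent).
#' @export
editing_efficiency <- function(base_counts, site) {
  stopifnot(inherits(site, "target_site"))
  n_total <- attr(base_counts, "n_retained")
  if (is.null(n_total)) abort("`base_counts` must come from count_bases()")
  amp_pos <- site$protospacer_start + site$positions_of_interest
  rows <- base_counts[match(amp_pos, base_counts$position), , drop = FALSE]
  bad <- which(rows$ref_base != site$conversion[1])
  if (length(bad) > 0) {
    abort(sprintf(
      "protospacer position %d: amplicon base '%s' is not the conversion source '%s'",
      site$positions_of_interest[bad[1]], rows$ref_base[bad[1]],
      site$conversion[1]
    ))
  }
  converted <- rows[[site$conversion[2]]]
  eff <- if (n_total > 0) 100 * converted / n_total else rep(NA_real_, nrow(rows))
  tibble(
    protospacer_position = site$positions_of_interest,
    amplicon_position = amp_pos,
    ref_base = rows$ref_base,
    n_converted = as.integer(converted),
    n_total = rep(as.integer(n_total), nrow(rows)),
    efficiency = eff
  )
}
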