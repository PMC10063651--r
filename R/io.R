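#' Read a reference genome from FASTA
#'
#' Loads every record of a FASTA file into a named character vector of
#' uppercase contig sequences, preserving file order. The alphabet is
#' restricted to `A/C/G/T/N`; any other residue, a duplicate contig name or
#' an empty record is a parse error.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector: contig name -> uppercase DNA sequence.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) abort(sprintf("malformed FASTA '%s': %s", path, conditionMessage(e)))
  )
  if (length(seqs) == 0) abort(sprintf("FASTA '%s' contains no records", path))
  out <- str_to_upper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(out))) {
    abort(sprintf("FASTA '%s': duplicate contig name '%s'",
                  path, names(out)[duplicated(names(out))][1]))
  }
  empty <- which(nchar(out) == 0)
  if (length(empty) > 0) {
    abort(sprintf("FASTA '%s': contig '%s' has an empty sequence",
                  path, names(out)[empty[1]]))
  }
  bad <- which(str_detect(out, "[^ACGTN]"))
  if (length(bad) > 0) {
    abort(sprintf("FASTA '%s': contig '%s' contains characters outside A/C/G/T/N",
                  path, names(out)[bad[1]]))
  }
  out
}

#' Write a reference genome to FASTA
#'
#' Canonical formatting: 70-column sequence lines, contigs in vector order.
#' A write/read cycle is the identity and a second write is byte-identical.
#'
#' @param ref Named character vector of contig sequences.
#' @param path Output path.
#' @param width Sequence line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ref, path, width = 70) {
  assert_reference(ref)
  lines <- unlist(imap(ref, function(seq, name) {
    n <- nchar(seq)
    starts <- seq.int(1L, n, by = width)
    c(paste0(">", name), substring(seq, starts, pmin(starts + width - 1L, n)))
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

# Extract one numeric INFO key from raw INFO strings; errors on absence or
# non-numeric payload (no silent coercion).
parse_info_field <- function(info, key, path) {
  m <- str_match(info, paste0("(?:^|;)", key, "=([^;]*)"))[, 2]
  if (anyNA(m)) {
    abort(sprintf("VCF '%s': INFO key '%s' missing on record %d",
                  path, key, which(is.na(m))[1]))
  }
  val <- suppressWarnings(as.numeric(m))
  if (anyNA(val)) {
    abort(sprintf("VCF '%s': non-numeric %s value '%s' on record %d",
                  path, key, m[is.na(val)][1], which(is.na(val))[1]))
  }
  val
}

#' Read a variant call set from VCF
#'
#' Reads the VCF v4.2 subset used throughout the package: the eight fixed
#' columns with INFO keys `DP`, `QD` and `FS`. Multiallelic `ALT` entries are
#' split into one record per alternate allele; `FILTER` is ignored (all
#' filtering in this package is explicit). Genotype columns are out of scope.
#'
#' @param path Path to a (plain-text) VCF file.
#' @param sample_id Sample label to attach; defaults to the file name stem.
#' @return A call-set tibble with columns `sample_id`, `contig`, `pos`,
#'   `ref`, `alt`, `qual`, `DP`, `QD`, `FS`.
#' @seealso [write_vcf()] for the canonical writer; a write/read cycle
#'   reproduces the call set key-for-key and annotation-for-annotation.
#' @export
read_vcf <- function(path, sample_id = NULL) {
  if (!file.exists(path)) abort(sprintf("VCF file not found: %s", path))
  sample_id <- sample_id %||% sub("\\.vcf$", "", basename(path))
  header <- grep("^#CHROM", readLines(path, warn = FALSE), value = TRUE)
  if (length(header) == 0) abort(sprintf("VCF '%s': missing #CHROM header line", path))
  cols <- strsplit(sub("^#", "", header[1]), "\t")[[1]]
  required <- c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  missing <- setdiff(required, cols)
  if (length(missing) > 0) {
    abort(sprintf("VCF '%s': missing required column(s) %s",
                  path, paste(missing, collapse = ", ")))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(empty_callset())
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos)) abort(sprintf("VCF '%s': non-integer POS", path))
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  out <- tibble(
    sample_id = sample_id,
    contig = fix$CHROM,
    pos = pos,
    ref = str_to_upper(fix$REF),
    alt = str_to_upper(fix$ALT),
    qual = qual,
    DP = as.integer(parse_info_field(fix$INFO, "DP", path)),
    QD = parse_info_field(fix$INFO, "QD", path),
    FS = parse_info_field(fix$INFO, "FS", path)
  )
  out <- separate_rows(out, "alt", sep = ",")
  if (any(out$ref == out$alt)) abort(sprintf("VCF '%s': record with REF == ALT", path))
  if (any(str_detect(out$ref, "[^ACGT]")) || any(str_detect(out$alt, "[^ACGT]"))) {
    abort(sprintf("VCF '%s': alleles outside A/C/G/T", path))
  }
  if (any(out$DP < 0)) abort(sprintf("VCF '%s': negative DP", path))
  if (any(out$FS < 0)) abort(sprintf("VCF '%s': negative FS", path))
  if (anyDuplicated(variant_key(out))) {
    abort(sprintf("VCF '%s': duplicate (contig,pos,ref,alt) key", path))
  }
  out
}

# Stable numeric formatting for VCF text: as.character() round-trips through
# as.numeric() exactly, so write -> read -> write is byte-identical.
fmt_vcf_num <- function(x) {
  ifelse(is.na(x), ".", as.character(x))
}

#' Write a call set to VCF
#'
#' Canonical dialect: `ID` and `FILTER` written as `.`, INFO limited to
#' `DP;QD;FS`, records sorted by (contig, pos, ref, alt). One record per
#' alternate allele (no multiallelic re-joining).
#'
#' @param calls Call-set tibble (see [read_vcf()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path) {
  assert_callset(calls)
  calls <- arrange(calls, .data$contig, .data$pos, .data$ref, .data$alt)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand phred score\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- if (nrow(calls) == 0) character(0) else {
    paste(
      calls$contig, calls$pos, ".", calls$ref, calls$alt,
      fmt_vcf_num(calls$qual), ".",
      paste0("DP=", fmt_vcf_num(calls$DP),
             ";QD=", fmt_vcf_num(calls$QD),
             ";FS=", fmt_vcf_num(calls$FS)),
      sep = "\t"
    )
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a region mask from BED
#'
#' BED3 (first three columns; extras ignored), 0-based half-open intervals,
#' loaded verbatim without merging. Overlapping intervals are allowed; the
#' mask supports membership testing only.
#'
#' @param path Path to a BED file.
#' @return Tibble with columns `contig`, `start`, `end`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (length(lines) == 0) {
    return(tibble(contig = character(0), start = integer(0), end = integer(0)))
  }
  fields <- str_split(lines, "\\s+")
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    abort(sprintf("BED '%s': line %d has fewer than 3 columns", path, short[1]))
  }
  start <- suppressWarnings(as.integer(map_chr(fields, 2)))
  end <- suppressWarnings(as.integer(map_chr(fields, 3)))
  if (anyNA(start) || anyNA(end)) {
    abort(sprintf("BED '%s': non-integer coordinate at line %d",
                  path, which(is.na(start) | is.na(end))[1]))
  }
  bad <- which(start >= end)
  if (length(bad) > 0) {
    abort(sprintf("BED '%s': start >= end at line %d", path, bad[1]))
  }
  if (any(start < 0)) abort(sprintf("BED '%s': negative start coordinate", path))
  tibble(contig = map_chr(fields, 1), start = start, end = end)
}

#' Write a region mask to BED3
#' @param mask Tibble with columns `contig`, `start`, `end` (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(mask, path) {
  writeLines(paste(mask$contig, mask$start, mask$end, sep = "\t"), path)
  invisible(path)
}

#' Read parent-offspring trios
#'
#' Whitespace-delimited text with a header line naming the columns
#' `offspring_id`, `father_id`, `mother_id`. The three ids within a trio must
#' be distinct; optionally every parent id must come from a known sample list.
#'
#' @param path Path to the pedigree file.
#' @param known_ids Optional character vector; if given, any parent id outside
#'   it is an error.
#' @return Tibble of trios.
#' @export
read_pedigree <- function(path, known_ids = NULL) {
  ped <- read_tsv(path, col_types = readr::cols(.default = "c"),
                  progress = FALSE, show_col_types = FALSE)
  if (ncol(ped) == 1) { # space-delimited fallback
    ped <- readr::read_table(path, col_types = readr::cols(.default = "c"),
                             progress = FALSE, show_col_types = FALSE)
  }
  required <- c("offspring_id", "father_id", "mother_id")
  missing <- setdiff(required, names(ped))
  if (length(missing) > 0) {
    abort(sprintf("pedigree '%s': missing column(s) %s",
                  path, paste(missing, collapse = ", ")))
  }
  ped <- as_tibble(ped[required])
  dup <- ped$offspring_id == ped$father_id | ped$offspring_id == ped$mother_id |
    ped$father_id == ped$mother_id
  if (any(dup)) {
    abort(sprintf("pedigree '%s': trio %d has non-distinct ids", path, which(dup)[1]))
  }
  if (!is.null(known_ids)) {
    unknown <- setdiff(c(ped$father_id, ped$mother_id), known_ids)
    if (length(unknown) > 0) {
      abort(sprintf("pedigree '%s': unknown parent id '%s'", path, unknown[1]))
    }
  }
  ped
}

#' Read a gene-by-tissue expression table
#'
#' Whitespace- or tab-delimited text with header `gene_id tissue fpkm`.
#' FPKM must be non-negative and each (gene, tissue) pair unique.
#'
#' @param path Path to the expression table.
#' @return Tibble with columns `gene_id`, `tissue`, `fpkm`.
#' @export
read_expression <- function(path) {
  tab <- readr::read_table(path, col_types = "ccd",
                           progress = FALSE, show_col_types = FALSE)
  required <- c("gene_id", "tissue", "fpkm")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(sprintf("expression table '%s': missing column(s) %s",
                  path, paste(missing, collapse = ", ")))
  }
  tab <- as_tibble(tab[required])
  if (anyNA(tab$fpkm)) abort(sprintf("expression table '%s': non-numeric fpkm", path))
  if (any(tab$fpkm < 0)) {
    abort(sprintf("expression table '%s': negative fpkm at row %d",
                  path, which(tab$fpkm < 0)[1]))
  }
  key <- paste(tab$gene_id, tab$tissue)
  if (anyDuplicated(key)) {
    abort(sprintf("expression table '%s': duplicate (gene_id, tissue) row '%s'",
                  path, key[duplicated(key)][1]))
  }
  tab
}
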