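#' Classify substitutions into the 12 strandless types
#'
#' Labels each SNV `"R>A"` from its ref/alt alleles exactly as recorded:
#' C>T and G>A are kept distinct (no pyrimidine collapsing — that happens
#' only inside motif analysis, see [orient_pyrimidine()]).
#'
#' @param ref,alt Single-base allele vectors.
#' @return Character vector of types (one of the 12).
#' @export
classify_substitution <- function(ref, alt) {
  if (any(nchar(ref) != 1 | nchar(alt) != 1)) {
    abort("classify_substitution() is defined for SNVs only (1-bp alleles)")
  }
  if (any(ref == alt)) abort("ref and alt must differ")
  if (any(!ref %in% DNA_BASES) || any(!alt %in% DNA_BASES)) {
    abort("alleles must be A/C/G/T")
  }
  paste0(ref, ">", alt)
}

#' 12-type mutation spectrum
#'
#' Counts and percentages of the 12 substitution types among the SNVs of a
#' call set. Indels are dropped with a logged count (attribute
#' `n_indels_dropped`). Percentages are `100 * count / total`; on an empty
#' input all counts are zero and percentages are `NA`.
#'
#' @param calls Call-set tibble.
#' @return Tibble with columns `type`, `count`, `percentage` (12 rows, fixed
#'   order).
#' @export
spectrum_table <- function(calls) {
  assert_callset(calls)
  is_snv <- nchar(calls$ref) == 1 & nchar(calls$alt) == 1
  n_dropped <- sum(!is_snv)
  snvs <- calls[is_snv, , drop = FALSE]
  types <- if (nrow(snvs) > 0) {
    classify_substitution(snvs$ref, snvs$alt)
  } else character(0)
  counts <- table(factor(types, levels = SUB_TYPES))
  total <- sum(counts)
  out <- tibble(
    type = SUB_TYPES,
    count = as.integer(counts),
    percentage = if (total > 0) 100 * as.integer(counts) / total else NA_real_
  )
  attr(out, "n_indels_dropped") <- n_dropped
  out
}

#' Extract trinucleotide (or wider) reference context
#'
#' Returns the `(2*flank+1)`-mer of the reference genome centered on each
#' SNV position. The center base is the reference allele (the pre-edit
#' base), never the alternate. Variants within `flank` of a contig edge are
#' an error — no N-padding.
#'
#' @param calls Call-set tibble of SNVs.
#' @param ref Reference genome.
#' @param flank Bases on each side (1 gives the 3-bp context).
#' @return Character vector of contexts, one per record.
#' @export
extract_context <- function(calls, ref, flank = 1) {
  assert_callset(calls)
  assert_reference(ref)
  if (nrow(calls) == 0) return(character(0))
  if (any(nchar(calls$ref) != 1 | nchar(calls$alt) != 1)) {
    abort("context extraction is defined for SNVs only")
  }
  unknown <- setdiff(unique(calls$contig), names(ref))
  if (length(unknown) > 0) abort(sprintf("contig '%s' absent from reference", unknown[1]))
  lens <- nchar(ref)[calls$contig]
  bad <- which(calls$pos - flank < 1 | calls$pos + flank > lens)
  if (length(bad) > 0) {
    abort(sprintf("variant %s:%d lies within %d bp of the contig edge",
                  calls$contig[bad[1]], calls$pos[bad[1]], flank))
  }
  ctx <- substr(ref[calls$contig], calls$pos - flank, calls$pos + flank)
  center <- substr(ctx, flank + 1, flank + 1)
  mism <- which(center != calls$ref)
  if (length(mism) > 0) {
    abort(sprintf("reference mismatch at %s:%d ('%s' vs genome '%s')",
                  calls$contig[mism[1]], calls$pos[mism[1]],
                  calls$ref[mism[1]], center[mism[1]]))
  }
  unname(ctx)
}

#' Orient substitutions and contexts to the pyrimidine strand
#'
#' Purine-centered events (ref G or A) are replaced by their reverse-
#' complement type and context; pyrimidine-centered events pass through.
#' This pools C>T with G>A (etc.) under a single motif, and is involutive on
#' the purine side: applying it twice equals applying it once.
#'
#' @param type Substitution types (`"C>T"` style).
#' @param context Matching odd-length reference contexts.
#' @return Tibble with columns `type` and `context`, oriented.
#' @export
orient_pyrimidine <- function(type, context) {
  if (length(type) != length(context)) abort("`type` and `context` lengths differ")
  if (length(type) == 0) return(tibble(type = character(0), context = character(0)))
  L <- unique(nchar(context))
  if (length(L) != 1 || L %% 2 == 0) {
    abort("contexts must share one odd length")
  }
  center <- substr(context, L %/% 2 + 1, L %/% 2 + 1)
  if (any(center != substr(type, 1, 1))) {
    i <- which(center != substr(type, 1, 1))[1]
    abort(sprintf("context center '%s' does not match type '%s'", center[i], type[i]))
  }
  purine <- substr(type, 1, 1) %in% c("A", "G")
  out_type <- type
  out_ctx <- context
  if (any(purine)) {
    out_type[purine] <- paste0(
      chartr("ACGT", "TGCA", substr(type[purine], 1, 1)), ">",
      chartr("ACGT", "TGCA", substr(type[purine], 3, 3))
    )
    out_ctx[purine] <- revcomp(context[purine])
  }
  tibble(type = out_type, context = out_ctx)
}

#' Build a context position weight matrix with information content
#'
#' Column base frequencies (no pseudocount) over equal-length contexts, with
#' per-position information content in bits against a uniform background:
#' `IC_j = 2 + sum_b f_jb * log2(f_jb)` (with `0 * log 0 := 0`), so a
#' single-letter column scores 2 bits and a uniform column 0.
#'
#' @param contexts Character vector of equal-length contexts (n >= 1).
#' @return A `context_pwm` object: list with `freq` (4 x L matrix, rows
#'   A/C/G/T), `ic` (length-L bits), `n`, `L`.
#' @export
build_pwm <- function(contexts) {
  if (length(contexts) < 1) abort("at least one context is required")
  L <- unique(nchar(contexts))
  if (length(L) != 1) abort("contexts must have equal lengths")
  mat <- do.call(rbind, strsplit(contexts, "", fixed = TRUE))
  freq <- vapply(seq_len(L), function(j) {
    tab <- table(factor(mat[, j], levels = DNA_BASES))
    as.numeric(tab) / length(contexts)
  }, numeric(4))
  rownames(freq) <- DNA_BASES
  colnames(freq) <- seq_len(L)
  plogp <- freq * log2(freq)
  plogp[freq == 0] <- 0
  ic <- 2 + colSums(plogp)
  structure(list(freq = freq, ic = unname(ic), n = length(contexts), L = L),
            class = "context_pwm")
}

#' @export
print.context_pwm <- function(x, ...) {
  cat(sprintf("Context PWM: %d positions from %d contexts\n", x$L, x$n))
  print(round(x$freq, 3))
  cat("IC (bits):", paste(round(x$ic, 3), collapse = " "), "\n")
  invisible(x)
}

#' @describeIn build_pwm Tidy the PWM into a long tibble
#'   (`position`, `base`, `freq`, `ic`).
#' @param x A `context_pwm`.
#' @param ... Unused.
#' @method tidy context_pwm
#' @export
tidy.context_pwm <- function(x, ...) {
  tibble(
    position = rep(seq_len(x$L), each = 4),
    base = rep(DNA_BASES, x$L),
    freq = as.numeric(x$freq),
    ic = rep(x$ic, each = 4)
  )
}

#' WCW motif enrichment statistics
#'
#' For pyrimidine-oriented, C-centered trinucleotide contexts, computes the
#' observed fraction matching W-C-W (W = A or T), the background WCW
#' fraction among all C- or G-centered trinucleotides of the unmasked
#' reference (G-centered sites evaluated on the reverse complement), and a
#' one-sided exact binomial p-value for enrichment above background.
#'
#' @param oriented_contexts Pyrimidine-oriented trinucleotide contexts
#'   (center C); non-C-centered entries are ignored, and an error is raised
#'   if none remain.
#' @param ref Reference genome supplying the background tally.
#' @param mask Optional region mask; masked center positions are excluded
#'   from the background.
#' @return One-row tibble: `n_contexts`, `n_wcw`, `wcw_fraction`,
#'   `background_fraction`, `enrichment_p`.
#' @export
wcw_statistics <- function(oriented_contexts, ref, mask = NULL) {
  keep <- nchar(oriented_contexts) == 3 &
    substr(oriented_contexts, 2, 2) == "C"
  ctx <- oriented_contexts[keep]
  if (length(ctx) == 0) abort("no C-centered trinucleotide contexts supplied")
  is_wcw <- str_detect(ctx, "^[AT]C[AT]$")
  assert_reference(ref)
  gi <- genome_index(ref)
  chars <- strsplit(paste(unname(ref), collapse = ""), "", fixed = TRUE)[[1]]
  usable <- !blocked_vector(ref, gi, panel = NULL, mask = mask)
  centers <- which((chars == "C" | chars == "G") & usable)
  flank_w <- chars[centers - 1L] %in% c("A", "T") &
    chars[centers + 1L] %in% c("A", "T")
  background <- mean(flank_w)
  p <- binom.test(sum(is_wcw), length(ctx), p = background,
                  alternative = "greater")$p.value
  tibble(
    n_contexts = length(ctx), n_wcw = sum(is_wcw),
    wcw_fraction = mean(is_wcw), background_fraction = background,
    enrichment_p = p
  )
}

#' Construct a toy gene model table
#'
#' Minimal CDS-only gene models: one row per CDS interval, 0-based half-open
#' coordinates, strand-aware reading frame anchored at the CDS start. The
#' summed CDS length of each gene must be divisible by 3 and intervals must
#' be sorted and non-overlapping.
#'
#' @param gene_id,contig,strand,start,end Parallel vectors (one element per
#'   CDS interval).
#' @return Validated gene-model tibble.
#' @export
gene_model <- function(gene_id, contig, strand, start, end) {
  gm <- tibble(gene_id = gene_id, contig = contig, strand = strand,
               start = as.integer(start), end = as.integer(end))
  validate_gene_models(gm)
  gm
}

validate_gene_models <- function(gm) {
  if (any(!gm$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  if (any(gm$start >= gm$end)) abort("gene model: CDS start must be < end")
  for (g in unique(gm$gene_id)) {
    iv <- gm[gm$gene_id == g, , drop = FALSE]
    iv <- iv[order(iv$start), ]
    if (sum(iv$end - iv$start) %% 3 != 0) {
      abort(sprintf("gene '%s': CDS length not divisible by 3", g))
    }
    if (nrow(iv) > 1 && any(iv$start[-1] < iv$end[-nrow(iv)])) {
      abort(sprintf("gene '%s': overlapping CDS intervals", g))
    }
  }
  invisible(gm)
}

# Spliced CDS sequence (already reverse-complemented for minus strand) and a
# map from genomic 0-based position to CDS coordinate.
spliced_cds <- function(gm_gene, ref) {
  iv <- gm_gene[order(gm_gene$start), , drop = FALSE]
  seqs <- substring(ref[[iv$contig[1]]], iv$start + 1L, iv$end)
  fwd <- paste(seqs, collapse = "")
  if (iv$strand[1] == "+") fwd else revcomp(fwd)
}

cds_offset <- function(gm_gene, pos0) {
  iv <- gm_gene[order(gm_gene$start), , drop = FALSE]
  total <- sum(iv$end - iv$start)
  prior <- c(0, cumsum(iv$end - iv$start))[seq_len(nrow(iv))]
  k <- which(pos0 >= iv$start & pos0 < iv$end)
  if (length(k) == 0) return(NA_integer_)
  fwd_off <- prior[k] + (pos0 - iv$start[k])
  if (iv$strand[1] == "+") as.integer(fwd_off) else as.integer(total - 1L - fwd_off)
}

CONSEQUENCE_SEVERITY <- c(stop_gained = 1, missense = 2, synonymous = 3,
                          noncoding = 4)

#' Annotate coding consequences of SNVs
#'
#' For each SNV inside a CDS, translates the affected codon before and after
#' the substitution (strand-aware, standard nuclear code) and classifies the
#' change as `stop_gained`, `missense` or `synonymous`; variants outside all
#' CDS are `noncoding`. When a variant hits overlapping genes, all
#' consequences are reported, most severe first.
#'
#' @param calls Call-set tibble of SNVs.
#' @param gene_models Gene-model tibble from [gene_model()].
#' @param ref Reference genome.
#' @return Tibble with one row per (variant, gene) pair: key columns plus
#'   `gene_id`, `consequence`, `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`.
#' @export
annotate_consequence <- function(calls, gene_models, ref) {
  assert_callset(calls)
  validate_gene_models(gene_models)
  assert_reference(ref)
  if (nrow(calls) > 0 && any(nchar(calls$ref) != 1 | nchar(calls$alt) != 1)) {
    abort("consequence annotation is defined for SNVs only")
  }
  code <- Biostrings::GENETIC_CODE
  by_gene <- split(gene_models, gene_models$gene_id)
  cds_seq <- map(by_gene, spliced_cds, ref = ref)
  rows <- map(seq_len(nrow(calls)), function(i) {
    pos0 <- pos1_to_pos0(calls$pos[i])
    hits <- list()
    for (g in names(by_gene)) {
      gm <- by_gene[[g]]
      if (gm$contig[1] != calls$contig[i]) next
      off <- cds_offset(gm, pos0)
      if (is.na(off)) next
      seq <- cds_seq[[g]]
      minus <- gm$strand[1] == "-"
      ref_base <- if (minus) chartr("ACGT", "TGCA", calls$ref[i]) else calls$ref[i]
      alt_base <- if (minus) chartr("ACGT", "TGCA", calls$alt[i]) else calls$alt[i]
      if (substr(seq, off + 1L, off + 1L) != ref_base) {
        abort(sprintf("gene '%s': CDS base disagrees with variant ref at %s:%d",
                      g, calls$contig[i], calls$pos[i]))
      }
      codon_i <- off %/% 3L
      within <- off %% 3L
      ref_codon <- substr(seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
      alt_codon <- ref_codon
      substr(alt_codon, within + 1L, within + 1L) <- alt_base
      ref_aa <- unname(code[ref_codon])
      alt_aa <- unname(code[alt_codon])
      consequence <- if (alt_aa == "*" && ref_aa != "*") {
        "stop_gained"
      } else if (alt_aa == ref_aa) {
        "synonymous"
      } else {
        "missense"
      }
      hits[[length(hits) + 1]] <- tibble(
        contig = calls$contig[i], pos = calls$pos[i],
        ref = calls$ref[i], alt = calls$alt[i],
        gene_id = g, consequence = consequence,
        ref_codon = ref_codon, alt_codon = alt_codon,
        ref_aa = ref_aa, alt_aa = alt_aa
      )
    }
    if (length(hits) == 0) {
      tibble(
        contig = calls$contig[i], pos = calls$pos[i],
        ref = calls$ref[i], alt = calls$alt[i],
        gene_id = NA_character_, consequence = "noncoding",
        ref_codon = NA_character_, alt_codon = NA_character_,
        ref_aa = NA_character_, alt_aa = NA_character_
      )
    } else {
      out <- list_rbind(hits)
      out[order(CONSEQUENCE_SEVERITY[out$consequence]), , drop = FALSE]
    }
  })
  list_rbind(rows)
}
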