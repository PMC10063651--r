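#' Left-normalize variants against a reference
#'
#' Shifts indels to their leftmost equivalent VCF (padded) representation and
#' trims redundant shared bases; SNVs pass through unchanged. Normalization is
#' idempotent, and two equivalent placements of the same indel normalize to an
#' identical (contig, pos, ref, alt) key — the matching key used by the whole
#' cascade.
#'
#' @param calls Call-set tibble.
#' @param ref Reference genome (named character vector, see [read_fasta()]).
#' @return The call set with normalized `pos`, `ref`, `alt`.
#' @export
left_normalize <- function(calls, ref) {
  assert_callset(calls)
  assert_reference(ref)
  if (nrow(calls) == 0) return(calls)
  unknown <- setdiff(unique(calls$contig), names(ref))
  if (length(unknown) > 0) {
    abort(sprintf("contig '%s' absent from reference", unknown[1]))
  }
  obs <- substr(ref[calls$contig], calls$pos, calls$pos + nchar(calls$ref) - 1L)
  bad <- which(obs != calls$ref)
  if (length(bad) > 0) {
    abort(sprintf(
      "ref allele mismatch at %s:%d (call '%s', genome '%s')",
      calls$contig[bad[1]], calls$pos[bad[1]], calls$ref[bad[1]], obs[bad[1]]
    ))
  }
  is_snv <- nchar(calls$ref) == 1 & nchar(calls$alt) == 1
  if (all(is_snv)) return(calls)
  idx <- which(!is_snv)
  norm <- map(idx, function(i) {
    normalize_one(ref[[calls$contig[i]]], calls$pos[i], calls$ref[i], calls$alt[i])
  })
  calls$pos[idx] <- map_int(norm, "pos")
  calls$ref[idx] <- map_chr(norm, "ref")
  calls$alt[idx] <- map_chr(norm, "alt")
  calls
}

# Scalar left-normalization on one contig sequence (standard shift/trim
# algorithm over padded alleles).
normalize_one <- function(seq, pos, ref, alt) {
  repeat {
    # strip a shared trailing base; if an allele empties, extend left
    while (nchar(ref) > 0 && nchar(alt) > 0 &&
           substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
    }
    if (nchar(ref) > 0 && nchar(alt) > 0) break
    if (pos == 1L) abort("cannot left-normalize: allele runs off contig start")
    pos <- pos - 1L
    pad <- substr(seq, pos, pos)
    ref <- paste0(pad, ref)
    alt <- paste0(pad, alt)
  }
  # strip shared leading bases beyond the single padding base
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

#' Three-caller consensus
#'
#' Keeps exactly the variants reported by all three callers for the same
#' sample — the multi-algorithm consensus that suppresses caller-specific
#' false positives. Matching is the exact (contig, pos, ref, alt) key, so
#' call sets should be left-normalized first. Quality annotations on the
#' consensus records are taken from the first caller.
#'
#' @param callset_1,callset_2,callset_3 Call-set tibbles from three callers,
#'   all for the same sample.
#' @return Call-set tibble (subset of `callset_1`'s rows), sorted by key.
#' @export
consensus_calls <- function(callset_1, callset_2, callset_3) {
  assert_callset(callset_1, "callset_1")
  assert_callset(callset_2, "callset_2")
  assert_callset(callset_3, "callset_3")
  ids <- unique(c(callset_1$sample_id, callset_2$sample_id, callset_3$sample_id))
  if (length(ids) > 1) {
    abort(sprintf("call sets come from different samples: %s",
                  paste(ids, collapse = ", ")))
  }
  out <- callset_1 |>
    semi_join(callset_2, by = KEY_COLS) |>
    semi_join(callset_3, by = KEY_COLS) |>
    arrange(.data$contig, .data$pos, .data$ref, .data$alt)
  out
}

#' Subtract one call set from another
#'
#' Set difference by (contig, pos, ref, alt); annotations of the surviving
#' records are untouched. Used for reference-sample (WT) subtraction,
#' same-organ RNA subtraction, DNA cross-filtering and parental subtraction.
#'
#' @param calls Call-set tibble.
#' @param reference_calls Call-set tibble whose keys are removed from `calls`.
#' @return Filtered call set.
#' @export
subtract_callset <- function(calls, reference_calls) {
  assert_callset(calls)
  assert_callset(reference_calls, "reference_calls")
  anti_join(calls, reference_calls, by = KEY_COLS)
}

#' Remove variants present in a known-sites panel
#'
#' Drops exact (contig, pos, ref, alt) matches against a dbSNP-like panel of
#' common variants. A panel entry with the same position but a different
#' alternate allele does not match.
#'
#' @param calls Call-set tibble.
#' @param panel Tibble with columns `contig`, `pos`, `ref`, `alt`.
#' @return Filtered call set.
#' @export
filter_known_sites <- function(calls, panel) {
  assert_callset(calls)
  anti_join(calls, panel, by = KEY_COLS)
}

#' Remove variants falling in masked regions
#'
#' Drops any variant whose 1-based position, converted to 0-based, lies inside
#' a mask interval (0-based half-open, repeat/high-complexity regions).
#'
#' @param calls Call-set tibble.
#' @param mask Tibble with columns `contig`, `start`, `end`.
#' @return Filtered call set.
#' @export
filter_regions <- function(calls, mask) {
  assert_callset(calls)
  if (nrow(calls) == 0 || nrow(mask) == 0) return(calls)
  pos0 <- pos1_to_pos0(calls$pos)
  hit <- rep(FALSE, nrow(calls))
  for (ctg in unique(mask$contig)) {
    on_ctg <- calls$contig == ctg
    if (!any(on_ctg)) next
    iv <- mask[mask$contig == ctg, , drop = FALSE]
    p <- pos0[on_ctg]
    inside <- rep(FALSE, length(p))
    for (k in seq_len(nrow(iv))) {
      inside <- inside | (p >= iv$start[k] & p < iv$end[k])
    }
    hit[on_ctg] <- inside
  }
  calls[!hit, , drop = FALSE]
}

#' Remove variants shared within a group
#'
#' Any key present in the call sets of two or more individuals of the same
#' group is removed from every individual — the germline-leakage filter for
#' animals expressing the same editor. Keys private to one individual are
#' kept.
#'
#' @param callsets_by_individual Named list of call-set tibbles, one per
#'   individual, all from the same group.
#' @return Named list of filtered call sets (same names and order).
#' @export
filter_group_shared <- function(callsets_by_individual) {
  stopifnot(is.list(callsets_by_individual))
  walk_groups <- unlist(map(callsets_by_individual, function(cs) {
    if ("group" %in% names(cs)) unique(cs$group) else character(0)
  }))
  if (length(unique(walk_groups)) > 1) {
    abort(sprintf("mixed group labels in group-shared filter: %s",
                  paste(unique(walk_groups), collapse = ", ")))
  }
  if (length(callsets_by_individual) < 2) return(callsets_by_individual)
  keys <- map(callsets_by_individual, function(cs) unique(variant_key(cs)))
  tab <- table(unlist(keys, use.names = FALSE))
  shared <- names(tab)[tab >= 2]
  map(callsets_by_individual, function(cs) {
    cs[!(variant_key(cs) %in% shared), , drop = FALSE]
  })
}

#' Trio de novo variants
#'
#' Variants of the offspring present in neither parent, i.e. two successive
#' subtractions (the order of the parental subtractions is irrelevant).
#'
#' @param offspring_calls,father_calls,mother_calls Call-set tibbles keyed
#'   identically (left-normalized).
#' @return Call set of candidate de novo variants.
#' @export
trio_de_novo <- function(offspring_calls, father_calls, mother_calls) {
  offspring_calls |>
    subtract_callset(father_calls) |>
    subtract_callset(mother_calls)
}

#' RNA hard filters
#'
#' Applies the standard GATK-style hard thresholds for RNA variant calls:
#' records with depth below 20, quality score below 30, quality-by-depth
#' below 2 or Fisher-strand score above 30 are removed; everything else is
#' kept (all four inequalities are strict on the removal side, so DP = 20,
#' qual = 30, QD = 2 and FS = 30 all pass).
#'
#' @param calls Call-set tibble with `DP`, `qual`, `QD`, `FS` on every record.
#' @return Filtered call set.
#' @export
rna_hard_filter <- function(calls) {
  assert_callset(calls)
  if (nrow(calls) == 0) return(calls)
  need <- c("DP", "qual", "QD", "FS")
  for (col in need) {
    if (!col %in% names(calls) || anyNA(calls[[col]])) {
      i <- if (col %in% names(calls)) which(is.na(calls[[col]]))[1] else 1L
      abort(sprintf("record %s:%d %s>%s lacks annotation '%s'",
                    calls$contig[i], calls$pos[i], calls$ref[i], calls$alt[i], col))
    }
  }
  calls[calls$DP >= 20 & calls$qual >= 30 & calls$QD >= 2 & calls$FS <= 30, ,
        drop = FALSE]
}

audit_row <- function(sample_id, stage, n_in, n_out) {
  tibble(sample_id = sample_id, stage = stage,
         n_in = as.integer(n_in), n_out = as.integer(n_out))
}

#' Run the DNA variant-identification cascade
#'
#' Per sample: left-normalize the three caller outputs, intersect them
#' (consensus), subtract the WT reference sample, remove known-site (dbSNP-
#' like) matches and masked-region variants, remove keys shared between
#' individuals of the same group, and — for offspring with a pedigree entry —
#' subtract both parents' consensus calls to obtain de novo variants. A
#' per-stage audit table (records in/out) accompanies the result.
#'
#' @param samples Named list: sample id -> list of three call-set tibbles
#'   (one per caller).
#' @param ref Reference genome.
#' @param wt Optional WT reference: either a single call-set tibble or a list
#'   of three caller outputs (then consensused first).
#' @param panel Optional known-sites tibble (`contig`, `pos`, `ref`, `alt`).
#' @param mask Optional region mask tibble (`contig`, `start`, `end`).
#' @param groups Optional named character vector sample id -> group label;
#'   the group-shared filter runs within each group of size >= 2.
#' @param pedigree Optional trio tibble (`offspring_id`, `father_id`,
#'   `mother_id`); parents must be samples of this run.
#' @return List with elements `calls` (named list of final call sets) and
#'   `audit` (tibble with columns `sample_id`, `stage`, `n_in`, `n_out`).
#' @export
run_dna_cascade <- function(samples, ref, wt = NULL, panel = NULL, mask = NULL,
                            groups = NULL, pedigree = NULL) {
  if (!is.list(samples) || is.null(names(samples))) {
    abort("`samples` must be a named list of per-caller call-set lists")
  }
  if (!is.null(pedigree)) {
    need <- setdiff(unique(c(pedigree$father_id, pedigree$mother_id,
                             pedigree$offspring_id)), names(samples))
    if (length(need) > 0) {
      abort(sprintf("pedigree id '%s' has no call sets in this run", need[1]))
    }
  }
  audit <- list()
  log_stage <- function(id, stage, n_in, n_out) {
    audit[[length(audit) + 1]] <<- audit_row(id, stage, n_in, n_out)
  }

  wt_calls <- NULL
  if (!is.null(wt)) {
    wt_calls <- if (is.data.frame(wt)) {
      left_normalize(wt, ref)
    } else {
      do.call(consensus_calls, unname(map(wt, left_normalize, ref = ref)))
    }
  }

  consensus <- imap(samples, function(callers, id) {
    if (length(callers) != 3) {
      abort(sprintf("sample '%s': DNA cascade requires exactly 3 caller call sets", id))
    }
    normed <- unname(map(callers, left_normalize, ref = ref))
    n_in <- sum(map_int(normed, nrow))
    out <- do.call(consensus_calls, normed)
    log_stage(id, "consensus", n_in, nrow(out))
    out
  })

  filtered <- imap(consensus, function(cs, id) {
    if (!is.null(wt_calls)) {
      n_in <- nrow(cs)
      cs <- subtract_callset(cs, wt_calls)
      log_stage(id, "subtract_wt", n_in, nrow(cs))
    }
    if (!is.null(panel)) {
      n_in <- nrow(cs)
      cs <- filter_known_sites(cs, panel)
      log_stage(id, "known_sites", n_in, nrow(cs))
    }
    if (!is.null(mask)) {
      n_in <- nrow(cs)
      cs <- filter_regions(cs, mask)
      log_stage(id, "regions", n_in, nrow(cs))
    }
    cs
  })

  if (!is.null(groups)) {
    for (grp in unique(groups)) {
      members <- intersect(names(filtered), names(groups)[groups == grp])
      if (length(members) < 2) next
      n_in <- map_int(filtered[members], nrow)
      filtered[members] <- filter_group_shared(filtered[members])
      for (id in members) {
        log_stage(id, "group_shared", n_in[[id]], nrow(filtered[[id]]))
      }
    }
  }

  if (!is.null(pedigree)) {
    for (k in seq_len(nrow(pedigree))) {
      o <- pedigree$offspring_id[k]
      n_in <- nrow(filtered[[o]])
      filtered[[o]] <- trio_de_novo(
        filtered[[o]], consensus[[pedigree$father_id[k]]],
        consensus[[pedigree$mother_id[k]]]
      )
      log_stage(o, "parental_subtraction", n_in, nrow(filtered[[o]]))
    }
  }

  list(calls = filtered, audit = list_rbind(audit))
}

#' Run the RNA variant-identification cascade
#'
#' Per sample (single-caller RNA call sets): left-normalize, apply the RNA
#' hard filters ([rna_hard_filter()]), subtract the same-organ WT call set,
#' remove known-site and masked-region variants, and subtract the matched
#' DNA call set (to rule out genetic background) when one is supplied.
#'
#' @param samples Named list: sample id -> call-set tibble.
#' @param ref Reference genome, or `NULL` to skip left-normalization (valid
#'   for SNV-only call sets, e.g. transcript-space simulations).
#' @param wt Optional named list or single tibble of same-organ WT RNA calls;
#'   a named list is matched to samples by name, a single tibble applies to
#'   all samples.
#' @param panel,mask As in [run_dna_cascade()].
#' @param dna Optional named list of matched DNA call sets per sample.
#' @return List with elements `calls` and `audit` as in [run_dna_cascade()].
#' @export
run_rna_cascade <- function(samples, ref = NULL, wt = NULL, panel = NULL,
                            mask = NULL, dna = NULL) {
  if (!is.list(samples) || is.null(names(samples))) {
    abort("`samples` must be a named list of call-set tibbles")
  }
  maybe_norm <- function(cs) {
    if (is.null(ref)) {
      if (any(nchar(cs$ref) != 1 | nchar(cs$alt) != 1)) {
        abort("indel call sets require `ref` for left-normalization")
      }
      cs
    } else {
      left_normalize(cs, ref)
    }
  }
  audit <- list()
  log_stage <- function(id, stage, n_in, n_out) {
    audit[[length(audit) + 1]] <<- audit_row(id, stage, n_in, n_out)
  }
  calls <- imap(samples, function(cs, id) {
    cs <- maybe_norm(cs)
    n_in <- nrow(cs)
    cs <- rna_hard_filter(cs)
    log_stage(id, "hard_filter", n_in, nrow(cs))
    wt_cs <- if (is.data.frame(wt)) wt else wt[[id]]
    if (!is.null(wt_cs)) {
      n_in <- nrow(cs)
      cs <- subtract_callset(cs, maybe_norm(wt_cs))
      log_stage(id, "subtract_wt", n_in, nrow(cs))
    }
    if (!is.null(panel)) {
      n_in <- nrow(cs)
      cs <- filter_known_sites(cs, panel)
      log_stage(id, "known_sites", n_in, nrow(cs))
    }
    if (!is.null(mask)) {
      n_in <- nrow(cs)
      cs <- filter_regions(cs, mask)
      log_stage(id, "regions", n_in, nrow(cs))
    }
    if (!is.null(dna) && !is.null(dna[[id]])) {
      n_in <- nrow(cs)
      cs <- subtract_callset(cs, maybe_norm(dna[[id]]))
      log_stage(id, "subtract_dna", n_in, nrow(cs))
    }
    cs
  })
  list(calls = calls, audit = list_rbind(audit))
}
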