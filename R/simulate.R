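#' Deaminase substitution-signature model
#'
#' Describes how planted events are drawn: a probability over the 12
#' strandless substitution types, a relative sampling weight for the WCW
#' trinucleotide context (W = A or T) of cytosine-centered events — evaluated
#' on the reverse complement for guanine-centered events, so one motif covers
#' both C>T and G>A — and the probability that an event is a 1-bp indel
#' rather than an SNV.
#'
#' @param type_probs Named probability vector over the 12 types
#'   (`"A>C"` ... `"T>G"`); must sum to 1.
#' @param context_weight Relative weight (>= 1) of WCW-context placement for
#'   C/G-centered events; 1 means no context preference.
#' @param indel_prob Probability in `[0, 1)` that a planted event is a 1-bp
#'   insertion or deletion.
#' @return A `signature_model` object.
#' @seealso [signature_preset()] for ready-made editor-like signatures.
#' @export
signature_model <- function(type_probs, context_weight = 1, indel_prob = 0) {
  if (is.null(names(type_probs)) || !setequal(names(type_probs), SUB_TYPES)) {
    abort("`type_probs` must be named with the 12 substitution types")
  }
  type_probs <- type_probs[SUB_TYPES]
  if (any(type_probs < 0) || abs(sum(type_probs) - 1) > 1e-9) {
    abort("`type_probs` must be non-negative and sum to 1 (tolerance 1e-9)")
  }
  if (!is.numeric(context_weight) || context_weight < 1) {
    abort("`context_weight` must be >= 1")
  }
  if (indel_prob < 0 || indel_prob >= 1) abort("`indel_prob` must be in [0, 1)")
  structure(
    list(type_probs = type_probs, context_weight = context_weight,
         indel_prob = indel_prob),
    class = "signature_model"
  )
}

#' Editor-like signature presets
#'
#' Convenience signatures for simulations. `"BE3"` concentrates mass on
#' C>T/G>A with a WCW context preference (cytidine-deaminase-like);
#' `"ABE"` on A>G/T>C with no context preference (adenine-deaminase-like);
#' `"background"` is uniform over the 12 types. The exact numbers are
#' simulation defaults, not estimates of any particular enzyme.
#'
#' @param name One of `"BE3"`, `"ABE"`, `"background"`.
#' @param context_weight Override of the preset's WCW weight.
#' @param indel_prob Probability of planting a 1-bp indel.
#' @return A [signature_model()].
#' @export
signature_preset <- function(name = c("BE3", "ABE", "background"),
                             context_weight = NULL, indel_prob = 0) {
  name <- match.arg(name)
  p <- setNames(rep(0, 12), SUB_TYPES)
  if (name == "BE3") {
    p[c("C>T", "G>A")] <- 0.40
    p[setdiff(SUB_TYPES, c("C>T", "G>A"))] <- 0.20 / 10
    w <- context_weight %||% 6
  } else if (name == "ABE") {
    p[c("A>G", "T>C")] <- 0.40
    p[setdiff(SUB_TYPES, c("A>G", "T>C"))] <- 0.20 / 10
    w <- context_weight %||% 1
  } else {
    p[] <- 1 / 12
    w <- context_weight %||% 1
  }
  signature_model(p, context_weight = w, indel_prob = indel_prob)
}

#' Caller error model
#'
#' Statistical stand-in for three independent somatic variant callers at the
#' call-set level: per-caller false-negative probabilities, per-accessible-
#' base false-positive rates, and the distributions of the quality
#' annotations attached to every emitted record (depth Poisson around the
#' study-like 36x mean; qual/QD/FS uniform over configured ranges). A
#' configurable fraction of records is given a deliberately filter-failing
#' annotation so that hard-filter boundaries can be exercised.
#'
#' @param fn Length-3 numeric, per-caller false-negative probability in
#'   `[0, 1)`.
#' @param fp Length-1 or length-3 numeric, per-caller false-positive rate per
#'   accessible base.
#' @param mean_depth Mean of the Poisson read-depth annotation (> 0).
#' @param qual_range,qd_range,fs_range Ranges for uniform sampling of the
#'   qual, QD and FS annotations.
#' @param filter_fail_rate Fraction of records whose annotation is replaced
#'   by one violating a randomly chosen RNA hard filter.
#' @return A `caller_error_model` object.
#' @export
caller_error_model <- function(fn = c(0, 0, 0), fp = 0, mean_depth = 36,
                               qual_range = c(30, 90), qd_range = c(2, 30),
                               fs_range = c(0, 30), filter_fail_rate = 0) {
  if (length(fn) != 3) abort("`fn` must have length 3 (three callers)")
  if (any(fn < 0 | fn >= 1)) abort("`fn` values must be in [0, 1)")
  fp <- rep_len(fp, 3)
  if (any(fp < 0)) abort("`fp` values must be >= 0")
  if (mean_depth <= 0) abort("`mean_depth` must be > 0")
  if (filter_fail_rate < 0 || filter_fail_rate > 1) {
    abort("`filter_fail_rate` must be in [0, 1]")
  }
  structure(
    list(fn = fn, fp = fp, mean_depth = mean_depth, qual_range = qual_range,
         qd_range = qd_range, fs_range = fs_range,
         filter_fail_rate = filter_fail_rate),
    class = "caller_error_model"
  )
}

# Draw qual/DP/QD/FS blocks for n records; filter-failing records get one
# violated threshold chosen uniformly among the four.
sample_annotations <- function(n, em) {
  ann <- tibble(
    qual = round(runif(n, em$qual_range[1], em$qual_range[2]), 2),
    DP = as.integer(rpois(n, em$mean_depth)),
    QD = round(runif(n, em$qd_range[1], em$qd_range[2]), 2),
    FS = round(runif(n, em$fs_range[1], em$fs_range[2]), 2)
  )
  if (em$filter_fail_rate > 0 && n > 0) {
    fail <- runif(n) < em$filter_fail_rate
    which_rule <- sample.int(4, n, replace = TRUE)
    ann$DP[fail & which_rule == 1] <- as.integer(
      sample(5:19, sum(fail & which_rule == 1), replace = TRUE))
    ann$qual[fail & which_rule == 2] <- round(
      runif(sum(fail & which_rule == 2), 0, 29.9), 2)
    ann$QD[fail & which_rule == 3] <- round(
      runif(sum(fail & which_rule == 3), 0, 1.9), 2)
    ann$FS[fail & which_rule == 4] <- round(
      runif(sum(fail & which_rule == 4), 30.1, 60), 2)
  }
  ann
}

#' Generate a synthetic reference genome, repeat mask and known-sites panel
#'
#' Builds a multi-contig random genome at a target GC content, a
#' non-overlapping block mask covering approximately `mask_fraction` of each
#' contig (repeat/high-complexity stand-in), and a dbSNP-like panel of common
#' variant sites whose reference alleles match the genome. Deterministic for
#' a fixed seed.
#'
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig (>= 1000 bp).
#' @param gc_fraction Target GC content in `[0, 1)`.
#' @param mask_fraction Fraction of each contig to mask, in `[0, 1)`.
#' @param n_known_sites Number of panel sites across the genome.
#' @param seed Integer seed.
#' @param mask_block Mask block size in bp.
#' @return List with elements `reference` (named character vector), `mask`
#'   (BED-convention tibble) and `panel` (tibble `contig`, `pos`, `ref`,
#'   `alt`).
#' @export
generate_reference <- function(n_contigs = 2, contig_length = 100000,
                               gc_fraction = 0.42, mask_fraction = 0.05,
                               n_known_sites = 500, seed = NULL,
                               mask_block = 1000) {
  if (contig_length < 1000) abort("`contig_length` must be >= 1000")
  if (gc_fraction < 0 || gc_fraction >= 1) abort("`gc_fraction` must be in [0, 1)")
  if (mask_fraction < 0 || mask_fraction >= 1) abort("`mask_fraction` must be in [0, 1)")
  if (n_contigs < 1) abort("`n_contigs` must be >= 1")
  seed_rng(seed)
  base_probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
                  G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  contigs <- paste0("ctg", seq_len(n_contigs))
  reference <- setNames(vapply(contigs, function(ctg) {
    paste(sample(DNA_BASES, contig_length, replace = TRUE, prob = base_probs),
          collapse = "")
  }, character(1)), contigs)

  n_blocks <- contig_length %/% mask_block
  k_blocks <- round(mask_fraction * n_blocks)
  mask <- list_rbind(map(contigs, function(ctg) {
    if (k_blocks == 0) {
      return(tibble(contig = character(0), start = integer(0), end = integer(0)))
    }
    picked <- sort(sample.int(n_blocks, k_blocks))
    tibble(contig = ctg,
           start = as.integer((picked - 1L) * mask_block),
           end = as.integer(picked * mask_block))
  }))

  per_contig <- diff(round(seq(0, n_known_sites, length.out = n_contigs + 1)))
  panel <- list_rbind(map2(contigs, per_contig, function(ctg, k) {
    if (k == 0) {
      return(tibble(contig = character(0), pos = integer(0),
                    ref = character(0), alt = character(0)))
    }
    pos <- sort(sample.int(contig_length, k))
    refb <- substring(reference[[ctg]], pos, pos)
    alt <- map_chr(refb, function(b) sample(setdiff(DNA_BASES, b), 1))
    tibble(contig = ctg, pos = as.integer(pos), ref = refb, alt = alt)
  }))
  list(reference = reference, mask = mask, panel = panel)
}

#' Simulate Mendelian trio germline call sets
#'
#' Parents (founders) receive independent genotypes at every panel site with
#' alternate-allele frequency `het_rate` per allele; each offspring inherits
#' one allele drawn at random from each parent (Mendelian transmission). A
#' variant enters a sample's call set when the sample carries at least one
#' alternate allele. Quality annotations are left unset — attach them with
#' [simulate_caller_outputs()].
#'
#' @param ref Reference genome (checked against the panel).
#' @param panel Known-sites tibble from [generate_reference()].
#' @param pedigree Trio tibble (`offspring_id`, `father_id`, `mother_id`);
#'   parents must be founders (not offspring of another trio here).
#' @param het_rate Alternate-allele frequency per parental allele, in (0, 1].
#' @param seed Integer seed.
#' @return List with `callsets` (named list of call-set tibbles) and
#'   `genotypes` (tibble `sample_id`, `contig`, `pos`, `ref`, `alt`, `a1`,
#'   `a2` with 0/1 allele indicators).
#' @export
simulate_trio_germline <- function(ref, panel, pedigree, het_rate = 0.5,
                                   seed = NULL) {
  assert_reference(ref)
  if (het_rate <= 0 || het_rate > 1) abort("`het_rate` must be in (0, 1]")
  offspring <- pedigree$offspring_id
  founders <- unique(c(pedigree$father_id, pedigree$mother_id))
  clash <- intersect(founders, offspring)
  if (length(clash) > 0) {
    abort(sprintf("sample '%s' is both parent and offspring; founders only", clash[1]))
  }
  bad_ctg <- setdiff(unique(panel$contig), names(ref))
  if (length(bad_ctg) > 0) abort(sprintf("panel contig '%s' absent from reference", bad_ctg[1]))
  seed_rng(seed)
  s <- nrow(panel)
  geno <- list()
  for (f in founders) {
    geno[[f]] <- cbind(a1 = rbinom(s, 1, het_rate), a2 = rbinom(s, 1, het_rate))
  }
  for (k in seq_len(nrow(pedigree))) {
    fa <- geno[[pedigree$father_id[k]]]
    mo <- geno[[pedigree$mother_id[k]]]
    pick_f <- rbinom(s, 1, 0.5) + 1L
    pick_m <- rbinom(s, 1, 0.5) + 1L
    geno[[pedigree$offspring_id[k]]] <- cbind(
      a1 = fa[cbind(seq_len(s), pick_f)],
      a2 = mo[cbind(seq_len(s), pick_m)]
    )
  }
  genotypes <- list_rbind(imap(geno, function(g, id) {
    tibble(sample_id = id, contig = panel$contig, pos = panel$pos,
           ref = panel$ref, alt = panel$alt, a1 = g[, 1], a2 = g[, 2])
  }))
  callsets <- map(geno, function(g) {
    carrier <- g[, 1] + g[, 2] > 0
    tibble(
      sample_id = NA_character_,
      contig = panel$contig[carrier], pos = panel$pos[carrier],
      ref = panel$ref[carrier], alt = panel$alt[carrier],
      qual = NA_real_, DP = NA_integer_, QD = NA_real_, FS = NA_real_
    )
  })
  callsets <- imap(callsets, function(cs, id) { cs$sample_id <- id; cs })
  list(callsets = callsets, genotypes = genotypes)
}

# Genome bookkeeping for event placement: global linear index over contigs.
genome_index <- function(ref) {
  lens <- nchar(ref)
  offsets <- c(0, cumsum(as.numeric(lens)))[seq_along(lens)]
  names(offsets) <- names(ref)
  list(lens = lens, offsets = offsets, total = sum(as.numeric(lens)))
}

global_to_local <- function(gidx, gi) {
  ctg_i <- findInterval(gidx - 0.5, c(gi$offsets, gi$total))
  tibble(contig = names(gi$offsets)[ctg_i],
         pos = as.integer(gidx - gi$offsets[ctg_i]))
}

blocked_vector <- function(ref, gi, panel = NULL, mask = NULL) {
  blocked <- logical(gi$total)
  # contig edges carry no trinucleotide context
  for (ctg in names(ref)) {
    off <- gi$offsets[[ctg]]
    blocked[off + 1L] <- TRUE
    blocked[off + gi$lens[[ctg]]] <- TRUE
  }
  if (!is.null(panel) && nrow(panel) > 0) {
    keep <- panel$contig %in% names(ref)
    blocked[gi$offsets[panel$contig[keep]] + panel$pos[keep]] <- TRUE
  }
  if (!is.null(mask) && nrow(mask) > 0) {
    for (k in seq_len(nrow(mask))) {
      if (!mask$contig[k] %in% names(ref)) next
      off <- gi$offsets[[mask$contig[k]]]
      blocked[(off + mask$start[k] + 1L):(off + mask$end[k])] <- TRUE
    }
  }
  blocked
}

#' Plant de novo events with a deaminase signature
#'
#' Places exactly `n_events` substitutions (and, with probability
#' `indel_prob`, 1-bp indels) on the genome. Substitution types follow the
#' signature's `type_probs`; for C- or G-centered events, candidate sites
#' whose pyrimidine-oriented trinucleotide context is WCW are accepted with
#' relative weight `context_weight`. Events avoid panel sites, masked
#' regions, contig edges and each other. Indels are planted in
#' homopolymer-free context so their normalized representation is unique.
#'
#' @param ref Reference genome.
#' @param signature A [signature_model()].
#' @param n_events Number of events to plant (>= 0).
#' @param seed Integer seed.
#' @param panel,mask Optional sites/regions to avoid.
#' @param sample_id Sample label for the returned call set.
#' @param label Truth label attached to every event (e.g. `"editor"`).
#' @param max_rounds Bounded-retry limit before declaring the genome too
#'   small.
#' @return Call-set tibble with an extra `label` column.
#' @export
plant_de_novo <- function(ref, signature, n_events, seed = NULL, panel = NULL,
                          mask = NULL, sample_id = "sample", label = "editor",
                          max_rounds = 1000) {
  assert_reference(ref)
  if (!inherits(signature, "signature_model")) {
    abort("`signature` must be a signature_model")
  }
  if (n_events < 0) abort("`n_events` must be >= 0")
  seed_rng(seed)
  out0 <- empty_callset()
  out0$label <- character(0)
  if (n_events == 0) { out0$sample_id <- character(0); return(out0) }

  gi <- genome_index(ref)
  blocked <- blocked_vector(ref, gi, panel, mask)
  chars <- strsplit(paste(unname(ref), collapse = ""), "", fixed = TRUE)[[1]]
  w <- signature$context_weight

  is_indel <- runif(n_events) < signature$indel_prob
  n_snv <- sum(!is_indel)
  types <- sample(SUB_TYPES, n_snv, replace = TRUE, prob = signature$type_probs)

  placed_idx <- integer(0)
  placed_type <- character(0)
  for (b in DNA_BASES) {
    need <- sum(substr(types, 1, 1) == b)
    if (need == 0) next
    pool <- which(chars == b)
    got <- integer(0)
    rounds <- 0L
    while (length(got) < need) {
      rounds <- rounds + 1L
      if (rounds > max_rounds || length(pool) == 0) {
        abort("genome too small to place the requested events (retry limit)")
      }
      cand <- pool[sample.int(length(pool), min(4L * (need - length(got)) + 16L,
                                                length(pool)))]
      cand <- cand[!blocked[cand]]
      cand <- setdiff(cand, got)
      if (length(cand) == 0) next
      if (b %in% c("C", "G") && w > 1) {
        wcw <- chars[cand - 1L] %in% c("A", "T") & chars[cand + 1L] %in% c("A", "T")
        keep <- wcw | (runif(length(cand)) < 1 / w)
        cand <- cand[keep]
      }
      cand <- unique(cand)
      take <- head(cand, need - length(got))
      got <- c(got, take)
      blocked[take] <- TRUE
    }
    placed_idx <- c(placed_idx, got)
    placed_type <- c(placed_type, types[substr(types, 1, 1) == b])
  }
  loc <- global_to_local(placed_idx, gi)
  snvs <- tibble(
    sample_id = sample_id,
    contig = loc$contig, pos = loc$pos,
    ref = substr(placed_type, 1, 1), alt = substr(placed_type, 3, 3),
    qual = NA_real_, DP = NA_integer_, QD = NA_real_, FS = NA_real_,
    label = label
  )

  n_ind <- sum(is_indel)
  indels <- NULL
  if (n_ind > 0) {
    got <- integer(0)
    rounds <- 0L
    while (length(got) < n_ind) {
      rounds <- rounds + 1L
      if (rounds > max_rounds) {
        abort("genome too small to place the requested indels (retry limit)")
      }
      cand <- sample.int(gi$total, 4L * (n_ind - length(got)) + 16L, replace = TRUE)
      cand <- cand[!blocked[cand] & cand > 1 & cand < gi$total]
      cand <- cand[!blocked[cand - 1L] &
                     chars[cand - 1L] != chars[cand] &
                     chars[cand] != chars[cand + 1L]]
      cand <- unique(setdiff(cand, got))
      take <- head(cand, n_ind - length(got))
      got <- c(got, take)
      blocked[take] <- TRUE
      blocked[take - 1L] <- TRUE
    }
    del <- runif(n_ind) < 0.5
    loc_anchor <- global_to_local(got - 1L, gi)
    ins_base <- map_chr(got, function(g) {
      # exclude the anchor and following base so the padded representation
      # is already left-normalized
      sample(setdiff(DNA_BASES, c(chars[g - 1L], chars[g])), 1)
    })
    indels <- tibble(
      sample_id = sample_id,
      contig = loc_anchor$contig, pos = loc_anchor$pos,
      ref = ifelse(del, paste0(chars[got - 1L], chars[got]), chars[got - 1L]),
      alt = ifelse(del, chars[got - 1L], paste0(chars[got - 1L], ins_base)),
      qual = NA_real_, DP = NA_integer_, QD = NA_real_, FS = NA_real_,
      label = label
    )
  }
  out <- bind_rows(snvs, indels) |>
    arrange(.data$contig, .data$pos, .data$ref, .data$alt)
  out
}

#' Simulate three imperfect caller outputs
#'
#' Each caller reports every true call independently with probability
#' `1 - fn[c]`, plus a Poisson number of false-positive calls at fresh
#' positions (rate `fp[c]` per accessible, unmasked base). Every emitted
#' record carries qual/DP/QD/FS annotations drawn from the error model.
#'
#' @param true_calls Call-set tibble of true variants (one sample).
#' @param error_model A [caller_error_model()].
#' @param ref Reference genome.
#' @param seed Integer seed.
#' @param mask Optional mask excluded from the accessible-base count and from
#'   false-positive placement.
#' @return Named list of three call-set tibbles (`caller1..3`). False calls
#'   carry `label = "false_positive"` when the input has a `label` column.
#' @export
simulate_caller_outputs <- function(true_calls, error_model, ref, seed = NULL,
                                    mask = NULL) {
  assert_callset(true_calls, "true_calls")
  if (!inherits(error_model, "caller_error_model")) {
    abort("`error_model` must be a caller_error_model")
  }
  assert_reference(ref)
  seed_rng(seed)
  gi <- genome_index(ref)
  blocked <- blocked_vector(ref, gi, panel = true_calls[KEY_COLS], mask = mask)
  masked_bases <- if (is.null(mask) || nrow(mask) == 0) 0 else {
    sum(map_dbl(split(mask, mask$contig), function(iv) {
      iv <- iv[order(iv$start), ]
      covered <- 0; cur_s <- -1; cur_e <- -1
      for (k in seq_len(nrow(iv))) {
        if (iv$start[k] > cur_e) {
          covered <- covered + max(cur_e - cur_s, 0); cur_s <- iv$start[k]; cur_e <- iv$end[k]
        } else cur_e <- max(cur_e, iv$end[k])
      }
      covered + max(cur_e - cur_s, 0)
    }))
  }
  accessible <- gi$total - masked_bases
  chars <- strsplit(paste(unname(ref), collapse = ""), "", fixed = TRUE)[[1]]
  em <- error_model
  has_label <- "label" %in% names(true_calls)
  out <- map(1:3, function(c_idx) {
    keep <- runif(nrow(true_calls)) >= em$fn[c_idx]
    tp <- true_calls[keep, , drop = FALSE]
    ann <- sample_annotations(nrow(tp), em)
    tp$qual <- ann$qual; tp$DP <- ann$DP; tp$QD <- ann$QD; tp$FS <- ann$FS
    n_fp <- rpois(1, em$fp[c_idx] * accessible)
    fp <- NULL
    if (n_fp > 0) {
      idx <- integer(0)
      while (length(idx) < n_fp) {
        cand <- sample.int(gi$total, 2L * (n_fp - length(idx)) + 8L, replace = TRUE)
        cand <- unique(cand[!blocked[cand]])
        idx <- c(idx, head(setdiff(cand, idx), n_fp - length(idx)))
      }
      loc <- global_to_local(idx, gi)
      refb <- chars[idx]
      ann <- sample_annotations(n_fp, em)
      fp <- tibble(
        sample_id = unique(true_calls$sample_id)[1] %||% "sample",
        contig = loc$contig, pos = loc$pos, ref = refb,
        alt = map_chr(refb, function(b) sample(setdiff(DNA_BASES, b), 1)),
        qual = ann$qual, DP = ann$DP, QD = ann$QD, FS = ann$FS
      )
      if (has_label) fp$label <- "false_positive"
    }
    bind_rows(tp, fp) |> arrange(.data$contig, .data$pos, .data$ref, .data$alt)
  })
  setNames(out, paste0("caller", 1:3))
}

#' Simulate expression-scaled RNA SNVs
#'
#' Per gene and tissue the SNV count is Poisson with mean
#' `rate_coefficient * fpkm * editor_fpkm(tissue)` — the generative model
#' behind an editor-expression-dependent RNA off-target load. Variants are
#' placed in transcript space (contig = gene id) with substitution types
#' drawn from the signature (recorded in cDNA space: a C>U edit appears as
#' C>T), a synthetic trinucleotide context honouring the signature's WCW
#' weight, and annotations drawn from the error model.
#'
#' @param expression Tibble `gene_id`, `tissue`, `fpkm` (see
#'   [read_expression()]).
#' @param editor_fpkm Named numeric vector tissue -> editor FPKM, or tibble
#'   with columns `tissue`, `editor_fpkm`.
#' @param signature A [signature_model()] (indel probability ignored: RNA
#'   events are SNVs).
#' @param rate_coefficient Non-negative scale of the Poisson mean.
#' @param seed Integer seed.
#' @param gene_length Nominal transcript length bounding variant positions.
#' @param error_model A [caller_error_model()] for the annotations.
#' @return Named list (by tissue) of call-set tibbles with an extra `tissue`
#'   column and a `context` column holding the synthetic trinucleotide
#'   context.
#' @export
simulate_rna_snvs <- function(expression, editor_fpkm, signature,
                              rate_coefficient, seed = NULL,
                              gene_length = 1000,
                              error_model = caller_error_model()) {
  if (rate_coefficient < 0) abort("`rate_coefficient` must be >= 0")
  if (is.data.frame(editor_fpkm)) {
    editor_fpkm <- setNames(editor_fpkm$editor_fpkm, editor_fpkm$tissue)
  }
  missing_t <- setdiff(unique(expression$tissue), names(editor_fpkm))
  if (length(missing_t) > 0) {
    abort(sprintf("no editor_fpkm for tissue '%s'", missing_t[1]))
  }
  seed_rng(seed)
  em <- error_model
  w <- signature$context_weight
  tissues <- unique(expression$tissue)
  out <- map(tissues, function(t) {
    rows <- expression[expression$tissue == t, , drop = FALSE]
    lambda <- rate_coefficient * rows$fpkm * editor_fpkm[[t]]
    n_per_gene <- rpois(nrow(rows), lambda)
    n_per_gene <- pmin(n_per_gene, gene_length)
    total <- sum(n_per_gene)
    if (total == 0) {
      cs <- empty_callset()
      cs$tissue <- character(0)
      cs$context <- character(0)
      return(cs)
    }
    gene <- rep(rows$gene_id, n_per_gene)
    pos <- unlist(map(n_per_gene[n_per_gene > 0], function(n) {
      sort(sample.int(gene_length, n))
    }), use.names = FALSE)
    types <- sample(SUB_TYPES, total, replace = TRUE, prob = signature$type_probs)
    refb <- substr(types, 1, 1)
    left <- sample(DNA_BASES, total, replace = TRUE)
    right <- sample(DNA_BASES, total, replace = TRUE)
    if (w > 1) {
      # re-draw non-WCW flanks of C/G-centered events until accepted at 1/w
      redo <- refb %in% c("C", "G") &
        !(left %in% c("A", "T") & right %in% c("A", "T")) &
        runif(total) >= 1 / w
      while (any(redo)) {
        left[redo] <- sample(DNA_BASES, sum(redo), replace = TRUE)
        right[redo] <- sample(DNA_BASES, sum(redo), replace = TRUE)
        redo <- redo &
          !(left %in% c("A", "T") & right %in% c("A", "T")) &
          runif(total) >= 1 / w
      }
    }
    ann <- sample_annotations(total, em)
    tibble(
      sample_id = t, contig = gene, pos = as.integer(pos),
      ref = refb, alt = substr(types, 3, 3),
      qual = ann$qual, DP = ann$DP, QD = ann$QD, FS = ann$FS,
      tissue = t, context = paste0(left, refb, right)
    ) |>
      distinct(.data$contig, .data$pos, .data$ref, .data$alt, .keep_all = TRUE)
  })
  setNames(out, tissues)
}

#' Simulate amplicon reads with per-position conversion
#'
#' Each read independently converts each target base with its per-position
#' rate (e.g. C-to-T at protospacer cytosines), then acquires uniform
#' sequencing errors at `error_rate` per base. Reads are gapless copies of
#' the amplicon.
#'
#' @param amplicon_seq Amplicon reference sequence.
#' @param target_positions 1-based amplicon positions subject to conversion.
#' @param conversion Length-2 character, `c(from_base, to_base)`.
#' @param per_position_rates Conversion probability per target position
#'   (recycled to length of `target_positions`).
#' @param n_reads Number of reads.
#' @param error_rate Per-base sequencing error probability.
#' @param seed Integer seed.
#' @return Character vector of reads.
#' @export
simulate_amplicon_reads <- function(amplicon_seq, target_positions, conversion,
                                    per_position_rates, n_reads,
                                    error_rate = 0, seed = NULL) {
  amplicon_seq <- str_to_upper(amplicon_seq)
  L <- nchar(amplicon_seq)
  if (any(target_positions < 1 | target_positions > L)) {
    abort("target positions must lie inside the amplicon")
  }
  rates <- rep_len(per_position_rates, length(target_positions))
  if (any(rates < 0 | rates > 1) || error_rate < 0 || error_rate > 1) {
    abort("rates must be in [0, 1]")
  }
  refb <- substring(amplicon_seq, target_positions, target_positions)
  if (any(refb != conversion[1])) {
    abort(sprintf(
      "amplicon base at position %d is '%s', not the conversion source '%s'",
      target_positions[which(refb != conversion[1])[1]],
      refb[refb != conversion[1]][1], conversion[1]
    ))
  }
  seed_rng(seed)
  mat <- matrix(rep(strsplit(amplicon_seq, "", fixed = TRUE)[[1]],
                    each = n_reads), nrow = n_reads)
  for (k in seq_along(target_positions)) {
    hit <- runif(n_reads) < rates[k]
    mat[hit, target_positions[k]] <- conversion[2]
  }
  if (error_rate > 0) {
    err <- which(matrix(runif(n_reads * L) < error_rate, nrow = n_reads))
    if (length(err) > 0) {
      mat[err] <- vapply(mat[err], function(b) sample(setdiff(DNA_BASES, b), 1),
                         character(1))
    }
  }
  apply(mat, 1, paste, collapse = "")
}
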