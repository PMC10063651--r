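test_that("substitution classification keeps all 12 types distinct", {
  pairs <- expand.grid(ref = c("A", "C", "G", "T"), alt = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  labels <- classify_substitution(pairs$ref, pairs$alt)
  expect_length(unique(labels), 12)
  expect_true("G>A" %in% labels) # not collapsed onto C>T
  expect_error(classify_substitution("AC", "A"), "SNVs only")
})

test_that("spectrum tables count and percentage correctly", {
  cs <- make_calls(c("c1:1:C:T", "c1:2:C:T", "c1:3:C:T", "c1:4:A:G"))
  spec <- spectrum_table(cs)
  expect_equal(spec$percentage[spec$type == "C>T"], 75)
  expect_equal(spec$percentage[spec$type == "A>G"], 25)
  # empty input: zero counts, undefined percentages
  spec0 <- spectrum_table(offbase:::empty_callset())
  expect_true(all(spec0$count == 0))
  expect_true(all(is.na(spec0$percentage)))
  # indels are dropped with a logged count
  with_indel <- dplyr::bind_rows(cs, make_calls("c1:9:AT:A"))
  spec2 <- spectrum_table(with_indel)
  expect_equal(attr(spec2, "n_indels_dropped"), 1)
  expect_equal(sum(spec2$count), 4)
  # percentages always sum to 100 on random SNVs
  set.seed(30)
  rnd <- random_callset(key_universe(300), 250)
  expect_equal(sum(spectrum_table(rnd)$percentage), 100, tolerance = 1e-9)
})

test_that("context extraction is reference-centered and edge-safe", {
  ref <- c(c1 = "AACGT")
  cs <- make_calls("c1:3:C:G")
  expect_equal(extract_context(cs, ref), "ACG")
  expect_error(extract_context(make_calls("c1:1:A:G"), ref), "edge")
  # center base equals the recorded ref allele, checked against the genome
  expect_error(extract_context(make_calls("c1:3:T:G"), ref), "mismatch")
  # wider window
  expect_equal(extract_context(cs, ref, flank = 2), "AACGT")
})

test_that("pyrimidine orientation reverse-complements purine events", {
  out <- orient_pyrimidine("G>A", "CGT")
  expect_equal(out$type, "C>T")
  expect_equal(out$context, "ACG")
  unchanged <- orient_pyrimidine("C>T", "ACA")
  expect_equal(unchanged$context, "ACA")
  # counts preserved and idempotent on its output
  types <- c("G>A", "C>T", "A>C", "T>G")
  ctxs <- c("AGT", "ACA", "CAT", "GTC")
  o1 <- orient_pyrimidine(types, ctxs)
  expect_equal(nrow(o1), 4)
  o2 <- orient_pyrimidine(o1$type, o1$context)
  expect_identical(o1, o2)
  expect_error(orient_pyrimidine("C>T", "AGA"), "does not match")
})

test_that("PWM frequencies and information content follow the entropy formula", {
  pwm <- build_pwm(rep("ACA", 4))
  expect_equal(pwm$ic, c(2, 2, 2))
  expect_equal(colSums(pwm$freq), c(`1` = 1, `2` = 1, `3` = 1))
  # uniform column has zero information
  pwm0 <- build_pwm(c("ACA", "CCA", "GCA", "TCA"))
  expect_equal(pwm0$ic[1], 0)
  expect_equal(pwm0$ic[2], 2)
  # 75/25 two-letter column: 2 - H(0.75, 0.25) bits
  pwm2 <- build_pwm(c("ACA", "ACA", "ACA", "TCA"))
  expected <- 2 + 0.75 * log2(0.75) + 0.25 * log2(0.25)
  expect_equal(pwm2$ic[1], expected, tolerance = 1e-9)
  expect_equal(round(expected, 4), 1.1887)
  expect_error(build_pwm(c("ACA", "ACAT")), "equal lengths")
})

test_that("WCW statistics measure observed and background fractions", {
  ref <- c(c1 = paste(rep("ACAG", 250), collapse = "")) # rich in C contexts
  out <- wcw_statistics(c("ACA", "TCT", "GCG"), ref)
  expect_equal(out$wcw_fraction, 2 / 3)
  expect_error(wcw_statistics(c("AGA"), ref), "no C-centered")
  # null case: observed at (or below) background is not enriched
  chars <- strsplit(ref[[1]], "")[[1]]
  cg <- which(chars %in% c("C", "G")); cg <- cg[cg > 1 & cg < length(chars)]
  bg <- mean(chars[cg - 1] %in% c("A", "T") & chars[cg + 1] %in% c("A", "T"))
  n <- 40
  n_w <- round(bg * n)
  ctxs <- c(rep("ACA", n_w), rep("GCG", n - n_w))
  null_out <- wcw_statistics(ctxs, ref)
  expect_gte(null_out$enrichment_p, 0.3)
})

test_that("coding consequences match the standard code on both strands", {
  # forward gene: codons ATG CGA CTG GCA TAA
  cds <- "ATGCGACTGGCATAA"
  ref <- c(c1 = paste0("TTTTT", cds, "TTTTT"))
  gm_fwd <- gene_model("gf", "c1", "+", 5, 5 + nchar(cds))
  # reverse gene on a contig carrying the reverse complement of the same CDS
  ref2 <- c(c2 = paste0("AAAAA",
                        offbase:::revcomp(cds),
                        "AAAAA"))
  gm_rev <- gene_model("gr", "c2", "-", 5, 5 + nchar(cds))

  check_both <- function(pos_in_cds, ref_b, alt_b, expected) {
    # forward strand: genomic == CDS coordinates
    v_f <- make_calls(sprintf("c1:%d:%s:%s", 5 + pos_in_cds, ref_b, alt_b))
    out_f <- annotate_consequence(v_f, gm_fwd, ref)
    expect_equal(out_f$consequence, expected)
    # reverse strand: genomic position mirrors, alleles complement
    gpos <- 5 + nchar(cds) - pos_in_cds + 1
    v_r <- make_calls(sprintf("c2:%d:%s:%s", gpos,
                              chartr("ACGT", "TGCA", ref_b),
                              chartr("ACGT", "TGCA", alt_b)))
    out_r <- annotate_consequence(v_r, gm_rev, ref2)
    expect_equal(out_r$consequence, expected)
  }
  # CGA -> TGA (Arg -> Stop) via C>T at codon 2 position 1 (CDS position 4)
  check_both(4, "C", "T", "stop_gained")
  # CTG -> TTG (Leu -> Leu) via C>T at CDS position 7
  check_both(7, "C", "T", "synonymous")
  # GCA -> ACA (Ala -> Thr) via G>A at CDS position 10
  check_both(10, "G", "A", "missense")
  # outside any CDS
  out <- annotate_consequence(make_calls("c1:2:T:A"), gm_fwd, ref)
  expect_equal(out$consequence, "noncoding")
  # invalid model: CDS length not divisible by 3
  expect_error(gene_model("bad", "c1", "+", 5, 9), "divisible by 3")
})

test_that("overlapping genes report all consequences, most severe first", {
  cds <- "ATGCGACTGGCATAA"
  ref <- c(c1 = paste0("TTTTT", cds, "TTTTT"))
  gm <- dplyr::bind_rows(
    gene_model("g1", "c1", "+", 5, 5 + nchar(cds)),
    gene_model("g2", "c1", "+", 6, 15) # shifted frame over the same span
  )
  # CDS pos 4 of g1: CGA -> TGA (stop); CDS pos 3 of g2: TGC -> TGT (silent)
  v <- make_calls("c1:9:C:T")
  out <- annotate_consequence(v, gm, ref)
  expect_equal(nrow(out), 2)
  expect_equal(out$consequence, c("stop_gained", "synonymous"))
  expect_equal(out$gene_id, c("g1", "g2"))
})
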