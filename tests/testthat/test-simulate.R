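test_that("reference generation is deterministic and hits its targets", {
  g1 <- generate_reference(n_contigs = 2, contig_length = 50000,
                           gc_fraction = 0.5, mask_fraction = 0.05,
                           n_known_sites = 200, seed = 1)
  g2 <- generate_reference(n_contigs = 2, contig_length = 50000,
                           gc_fraction = 0.5, mask_fraction = 0.05,
                           n_known_sites = 200, seed = 1)
  expect_identical(g1, g2)
  # panel ref alleles match the genome
  expect_true(all(
    substr(g1$reference[g1$panel$contig], g1$panel$pos, g1$panel$pos) ==
      g1$panel$ref
  ))
  # empirical GC within the binomial 3-sigma band at 1 Mb
  big <- generate_reference(n_contigs = 1, contig_length = 1000000,
                            gc_fraction = 0.5, mask_fraction = 0,
                            n_known_sites = 0, seed = 2)
  gc <- mean(strsplit(big$reference[[1]], "")[[1]] %in% c("G", "C"))
  expect_gt(gc, 0.49)
  expect_lt(gc, 0.51)
  expect_equal(nrow(big$mask), 0)
  # mask coverage close to the requested fraction
  cov <- sum(g1$mask$end - g1$mask$start) / sum(nchar(g1$reference))
  expect_equal(cov, 0.05, tolerance = 0.3)
  expect_error(generate_reference(contig_length = 10), "contig_length")
})

test_that("trio germline genotypes are Mendelian", {
  g <- generate_reference(n_contigs = 1, contig_length = 20000,
                          gc_fraction = 0.4, mask_fraction = 0,
                          n_known_sites = 2000, seed = 3)
  ped <- tibble::tibble(offspring_id = "o1", father_id = "f1", mother_id = "m1")
  trio <- simulate_trio_germline(g$reference, g$panel, ped, het_rate = 0.5,
                                 seed = 4)
  geno <- tidyr::pivot_wider(
    trio$genotypes,
    id_cols = c("contig", "pos"),
    names_from = "sample_id",
    values_from = c("a1", "a2")
  )
  fa <- geno$a1_f1 + geno$a2_f1
  mo <- geno$a1_m1 + geno$a2_m1
  # exhaustive consistency: a homozygous parent fully determines the
  # transmitted allele
  expect_true(all((fa != 0 | geno$a1_o1 == 0) & (fa != 2 | geno$a1_o1 == 1)))
  expect_true(all((mo != 0 | geno$a2_o1 == 0) & (mo != 2 | geno$a2_o1 == 1)))
  # both parents hom-ref: offspring never carries the variant
  hom_ref <- fa == 0 & mo == 0
  expect_true(all(geno$a1_o1[hom_ref] + geno$a2_o1[hom_ref] == 0))
  off_keys <- key_of(trio$callsets$o1)
  hom_ref_keys <- paste(geno$contig[hom_ref], geno$pos[hom_ref],
                        g$panel$ref[match(geno$pos[hom_ref], g$panel$pos)],
                        g$panel$alt[match(geno$pos[hom_ref], g$panel$pos)],
                        sep = ":")
  expect_length(intersect(off_keys, hom_ref_keys), 0)
  # father hom-alt, mother hom-ref: offspring always carries it
  fa_hom <- fa == 2 & mo == 0
  expect_true(all(geno$a1_o1[fa_hom] == 1))
  # father het, mother hom-ref: transmission ~ Binomial(n, 1/2) within 3 sigma
  het <- fa == 1 & mo == 0
  n <- sum(het)
  expect_gt(n, 200)
  frac <- mean(geno$a1_o1[het])
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
})

test_that("planted events follow the requested signature exactly when degenerate", {
  g <- generate_reference(n_contigs = 1, contig_length = 30000,
                          gc_fraction = 0.5, mask_fraction = 0.05,
                          n_known_sites = 100, seed = 5)
  expect_equal(nrow(plant_de_novo(g$reference, signature_preset("background"),
                                  0, seed = 6)), 0)
  probs <- stats::setNames(rep(0, 12), offbase:::SUB_TYPES)
  probs["C>T"] <- 1
  sig <- signature_model(probs, context_weight = 1)
  dn <- plant_de_novo(g$reference, sig, 200, seed = 7, panel = g$panel,
                      mask = g$mask)
  expect_equal(nrow(dn), 200)
  expect_true(all(dn$ref == "C" & dn$alt == "T"))
  # avoids panel keys, masked positions and itself
  expect_length(intersect(paste(dn$contig, dn$pos),
                          paste(g$panel$contig, g$panel$pos)), 0)
  expect_equal(nrow(filter_regions(dn, g$mask)), 200)
  expect_false(anyDuplicated(paste(dn$contig, dn$pos)) > 0)
  # determinism
  dn2 <- plant_de_novo(g$reference, sig, 200, seed = 7, panel = g$panel,
                       mask = g$mask)
  expect_identical(dn, dn2)
})

test_that("WCW context weighting matches the acceptance-sampling expectation", {
  g <- generate_reference(n_contigs = 1, contig_length = 400000,
                          gc_fraction = 0.5, mask_fraction = 0,
                          n_known_sites = 0, seed = 8)
  probs <- stats::setNames(rep(0, 12), offbase:::SUB_TYPES)
  probs["C>T"] <- 0.5
  probs["G>A"] <- 0.5
  w <- 5
  sig <- signature_model(probs, context_weight = w)
  dn <- plant_de_novo(g$reference, sig, 2000, seed = 9)
  ctx <- extract_context(dn, g$reference)
  oriented <- orient_pyrimidine(classify_substitution(dn$ref, dn$alt), ctx)
  obs <- mean(grepl("^[AT]C[AT]$", oriented$context))
  # genomic WCW fraction among C/G-centered trinucleotides
  chars <- strsplit(g$reference[[1]], "")[[1]]
  cg <- which(chars %in% c("C", "G"))
  cg <- cg[cg > 1 & cg < length(chars)]
  f <- mean(chars[cg - 1] %in% c("A", "T") & chars[cg + 1] %in% c("A", "T"))
  expected <- w * f / (w * f + (1 - f))
  expect_lt(abs(obs - expected), 3 * sqrt(expected * (1 - expected) / 2000))
})

test_that("planted type spectra converge to type_probs (chi-square GOF)", {
  g <- generate_reference(n_contigs = 1, contig_length = 500000,
                          gc_fraction = 0.42, mask_fraction = 0,
                          n_known_sites = 0, seed = 10)
  sig <- signature_preset("BE3")
  dn <- plant_de_novo(g$reference, sig, 5000, seed = 11)
  counts <- table(factor(classify_substitution(dn$ref, dn$alt),
                         levels = offbase:::SUB_TYPES))
  gof <- suppressWarnings(
    stats::chisq.test(as.integer(counts), p = sig$type_probs)
  )
  expect_gt(gof$p.value, 0.001)
})

test_that("caller outputs honour the error model", {
  g <- generate_reference(n_contigs = 1, contig_length = 100000,
                          gc_fraction = 0.45, mask_fraction = 0,
                          n_known_sites = 0, seed = 12)
  truth <- plant_de_novo(g$reference, signature_preset("background"), 1000,
                         seed = 13)
  # zero error: each caller equals truth exactly (keys and count)
  clean <- simulate_caller_outputs(truth, caller_error_model(), g$reference,
                                   seed = 14)
  for (cs in clean) expect_setequal(key_of(cs), key_of(truth))
  # false positives never collide with true calls
  noisy <- simulate_caller_outputs(
    truth, caller_error_model(fn = c(0.05, 0.10, 0.05), fp = 2e-5),
    g$reference, seed = 15
  )
  fn <- c(0.05, 0.10, 0.05)
  for (k in 1:3) {
    cs <- noisy[[k]]
    fp_keys <- setdiff(key_of(cs), key_of(truth))
    fp_pos <- sub("^([^:]+:[0-9]+):.*$", "\\1", fp_keys)
    truth_pos <- paste(truth$contig, truth$pos, sep = ":")
    expect_length(intersect(fp_pos, truth_pos), 0)
    recall <- mean(key_of(truth) %in% key_of(cs))
    expect_lt(abs(recall - (1 - fn[k])),
              3 * sqrt(fn[k] * (1 - fn[k]) / 1000))
  }
  # annotations present on every record
  expect_false(anyNA(noisy[[1]]$DP))
  expect_false(anyNA(noisy[[1]]$FS))
})

test_that("RNA SNV counts scale with expression and editor level", {
  expr <- tidyr::expand_grid(gene_id = sprintf("g%02d", 1:50),
                             tissue = c("muscle", "liver"))
  expr$fpkm <- rep(10, nrow(expr))
  sig <- signature_preset("BE3")
  # zero rate: empty everywhere
  empty <- simulate_rna_snvs(expr, c(muscle = 50, liver = 10), sig, 0, seed = 16)
  expect_true(all(purrr::map_int(empty, nrow) == 0))
  # Poisson mean linearity in editor expression: lambda doubles when the
  # editor level doubles; totals within 3 sigma of their means
  r <- 0.002
  one <- simulate_rna_snvs(expr, c(muscle = 30, liver = 30), sig, r, seed = 17)
  two <- simulate_rna_snvs(expr, c(muscle = 60, liver = 60), sig, r, seed = 18)
  lam1 <- r * 10 * 30 * 50
  n1 <- sum(purrr::map_int(one, nrow))
  n2 <- sum(purrr::map_int(two, nrow))
  expect_lt(abs(n1 - 2 * lam1), 3 * sqrt(2 * lam1))
  expect_lt(abs(n2 - 4 * lam1), 3 * sqrt(4 * lam1))
  # cDNA-space types come from the signature (C>T dominant for a CBE)
  pooled <- dplyr::bind_rows(one)
  expect_gt(mean(paste0(pooled$ref, ">", pooled$alt) %in% c("C>T", "G>A")), 0.6)
})

test_that("amplicon read simulation converts at the planted rate", {
  amp <- paste(rep(c("A", "C", "G", "T"), 25), collapse = "")
  # rate 1, no errors: every read converted at the target
  reads <- simulate_amplicon_reads(amp, 2, c("C", "T"), 1, 50, 0, seed = 19)
  expect_true(all(substr(reads, 2, 2) == "T"))
  # rate 0, no errors: reads identical to the amplicon
  reads0 <- simulate_amplicon_reads(amp, 2, c("C", "T"), 0, 50, 0, seed = 20)
  expect_true(all(reads0 == amp))
  # binomial 3-sigma at rate 0.2 with 10000 reads
  reads2 <- simulate_amplicon_reads(amp, 6, c("C", "T"), 0.2, 10000, 0, seed = 21)
  obs <- mean(substr(reads2, 6, 6) == "T")
  expect_lt(abs(obs - 0.2), 3 * sqrt(0.2 * 0.8 / 10000))
  # conversion source must match the amplicon base
  expect_error(simulate_amplicon_reads(amp, 1, c("C", "T"), 0.5, 10, 0, 22),
               "conversion source")
})
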