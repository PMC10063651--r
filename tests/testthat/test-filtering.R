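test_that("left_normalize leaves SNVs alone and validates the ref allele", {
  ref <- tiny_ref()
  snv <- make_calls("c1:3:C:T")
  expect_identical(left_normalize(snv, ref), snv)
  bad <- make_calls("c1:3:G:T")
  expect_error(left_normalize(bad, ref), "mismatch")
})

test_that("equivalent homopolymer indel placements normalize to one key", {
  # 10-bp toy with a C homopolymer: deleting any C gives the same sequence
  seq <- "AACCCCGTTA"
  ref <- c(c1 = seq)
  # all padded single-C deletions inside the run
  placements <- purrr::map(3:6, function(p) {
    tibble::tibble(sample_id = "s", contig = "c1", pos = p - 1L,
                   ref = substr(seq, p - 1, p), alt = substr(seq, p - 1, p - 1),
                   qual = 1, DP = 1L, QD = 1, FS = 1)
  })
  # oracle: all placements yield the same edited sequence
  edited <- purrr::map_chr(placements, function(v) {
    apply_variant(seq, v$pos, v$ref, v$alt)
  })
  expect_length(unique(edited), 1)
  keys <- purrr::map_chr(placements, function(v) key_of(left_normalize(v, ref)))
  expect_length(unique(keys), 1)
})

test_that("left_normalize is idempotent on random indels", {
  set.seed(11)
  genome <- c(g = paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                        collapse = ""))
  n <- 500
  pos <- sample(10:1990, n, replace = TRUE)
  is_del <- runif(n) < 0.5
  calls <- tibble::tibble(
    sample_id = "s", contig = "g", pos = as.integer(pos),
    ref = ifelse(is_del, substring(genome, pos, pos + 1),
                 substring(genome, pos, pos)),
    alt = ifelse(is_del, substring(genome, pos, pos),
                 paste0(substring(genome, pos, pos),
                        sample(c("A", "C", "G", "T"), n, replace = TRUE))),
    qual = 1, DP = 1L, QD = 1, FS = 1
  )
  calls <- calls[calls$ref != calls$alt, ]
  once <- left_normalize(calls, genome)
  twice <- left_normalize(once, genome)
  expect_identical(once, twice)
})

test_that("consensus is the three-way intersection with caller-1 annotations", {
  a <- make_calls(c("c1:1:A:G", "c1:2:C:T", "c1:3:G:A"), qual = 99)
  b <- make_calls(c("c1:2:C:T", "c1:3:G:A", "c1:4:T:C"), qual = 10)
  c3 <- make_calls(c("c1:2:C:T", "c1:3:G:A", "c1:5:A:C"), qual = 20)
  out <- consensus_calls(a, b, c3)
  expect_setequal(key_of(out), c("c1:2:C:T", "c1:3:G:A"))
  expect_true(all(out$qual == 99)) # annotations from caller 1

  # same position, different alt: no spurious consensus
  a2 <- make_calls("c1:7:C:T")
  b2 <- make_calls("c1:7:C:A")
  expect_equal(nrow(consensus_calls(a2, b2, a2)), 0)

  expect_error(
    consensus_calls(a, make_calls("c1:2:C:T", sample_id = "other"), c3),
    "different samples"
  )
})

test_that("consensus equals the brute-force intersection oracle", {
  set.seed(99)
  universe <- key_universe(300)
  for (i in 1:100) {
    sizes <- sample(0:500, 3, replace = TRUE)
    sets <- purrr::map(sizes, function(n) {
      random_callset(universe, min(n, length(universe)))
    })
    fast <- consensus_calls(sets[[1]], sets[[2]], sets[[3]])
    slow <- bf_consensus(sets[[1]], sets[[2]], sets[[3]])
    expect_setequal(key_of(fast), key_of(slow))
  }
})

test_that("subtraction and key filters follow set algebra", {
  ab <- make_calls(c("c1:1:A:G", "c1:2:C:T"))
  b <- make_calls("c1:2:C:T", sample_id = "wt")
  expect_equal(key_of(subtract_callset(ab, b)), "c1:1:A:G")
  expect_identical(subtract_callset(ab, offbase:::empty_callset()), ab)
  expect_equal(nrow(subtract_callset(ab, ab)), 0)

  # panel filter matches the exact key only
  panel <- tibble::tibble(contig = "c1", pos = 2L, ref = "C", alt = "G")
  expect_equal(nrow(filter_known_sites(ab, panel)), 2)
  panel$alt <- "T"
  expect_equal(key_of(filter_known_sites(ab, panel)), "c1:1:A:G")
})

test_that("group-shared filter removes keys present in >= 2 individuals", {
  i1 <- make_calls(c("c1:1:A:G", "c1:2:C:T"), sample_id = "i1")
  i2 <- make_calls(c("c1:2:C:T", "c1:3:G:A"), sample_id = "i2")
  i3 <- make_calls(c("c1:2:C:T", "c1:9:T:A"), sample_id = "i3")
  out <- filter_group_shared(list(i1 = i1, i2 = i2, i3 = i3))
  expect_equal(key_of(out$i1), "c1:1:A:G")
  expect_equal(key_of(out$i2), "c1:3:G:A")
  expect_equal(key_of(out$i3), "c1:9:T:A")
  # single individual untouched
  expect_identical(filter_group_shared(list(i1 = i1)), list(i1 = i1))
  # mixed group labels rejected
  i1$group <- "BE3"; i2$group <- "GFP"
  expect_error(filter_group_shared(list(i1 = i1, i2 = i2)), "mixed group")
})

test_that("trio de novo calling is parental set subtraction and commutes", {
  off <- make_calls(c("c1:1:A:G", "c1:2:C:T", "c1:3:G:A"), sample_id = "o")
  fa <- make_calls("c1:1:A:G", sample_id = "f")
  mo <- make_calls("c1:3:G:A", sample_id = "m")
  expect_equal(key_of(trio_de_novo(off, fa, mo)), "c1:2:C:T")
  expect_equal(nrow(trio_de_novo(fa, fa, mo)), 0)
  expect_identical(
    key_of(trio_de_novo(off, fa, mo)),
    key_of(trio_de_novo(off, mo, fa))
  )
})

test_that("RNA hard filters keep DP>=20, qual>=30, QD>=2, FS<=30", {
  base <- make_calls("c1:1:A:G", qual = 50, DP = 30L, QD = 10, FS = 1)
  tweak <- function(col, val) { x <- base; x[[col]] <- val; x }
  expect_equal(nrow(rna_hard_filter(tweak("DP", 19L))), 0)
  expect_equal(nrow(rna_hard_filter(tweak("DP", 20L))), 1)
  expect_equal(nrow(rna_hard_filter(tweak("qual", 29.99))), 0)
  expect_equal(nrow(rna_hard_filter(tweak("qual", 30))), 1)
  expect_equal(nrow(rna_hard_filter(tweak("QD", 1.99))), 0)
  expect_equal(nrow(rna_hard_filter(tweak("QD", 2))), 1)
  expect_equal(nrow(rna_hard_filter(tweak("FS", 30))), 1)
  expect_equal(nrow(rna_hard_filter(tweak("FS", 30.01))), 0)
  expect_error(rna_hard_filter(tweak("QD", NA_real_)), "QD")
})

test_that("every filter is a contraction and idempotent", {
  set.seed(5)
  cs <- random_callset(key_universe(300), 120)
  panel <- tibble::tibble(contig = "c1", pos = 1:50, ref = "A", alt = "G")
  mask <- tibble::tibble(contig = "c1", start = c(10L, 100L), end = c(40L, 160L))
  wt <- random_callset(key_universe(300), 60, sample_id = "s1")
  filters <- list(
    function(x) filter_known_sites(x, panel),
    function(x) filter_regions(x, mask),
    function(x) subtract_callset(x, wt),
    function(x) rna_hard_filter(x)
  )
  for (f in filters) {
    out <- f(cs)
    expect_true(all(key_of(out) %in% key_of(cs)))
    expect_identical(f(out), out)
  }
})

test_that("subtraction-style filters commute in any order", {
  set.seed(6)
  cs <- random_callset(key_universe(300), 150)
  panel <- tibble::tibble(contig = "c1", pos = seq(1, 299, by = 3), ref = "A", alt = "G")
  mask <- tibble::tibble(contig = "c1", start = c(0L, 200L), end = c(60L, 260L))
  wt <- random_callset(key_universe(300), 80, sample_id = "s1")
  steps <- list(
    wt = function(x) subtract_callset(x, wt),
    panel = function(x) filter_known_sites(x, panel),
    mask = function(x) filter_regions(x, mask)
  )
  results <- purrr::map(
    list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)),
    function(ord) {
      out <- cs
      for (k in ord) out <- steps[[k]](out)
      sort(key_of(out))
    }
  )
  for (r in results[-1]) expect_identical(r, results[[1]])
})

test_that("the DNA cascade recovers planted de novo truth without caller error", {
  g <- generate_reference(n_contigs = 2, contig_length = 20000,
                          gc_fraction = 0.45, mask_fraction = 0.05,
                          n_known_sites = 150, seed = 21)
  ped <- tibble::tibble(offspring_id = "o1", father_id = "f1", mother_id = "m1")
  trio <- simulate_trio_germline(g$reference, g$panel, ped, het_rate = 0.5,
                                 seed = 22)
  dn <- plant_de_novo(g$reference, signature_preset("BE3", indel_prob = 0.1),
                      50, seed = 23, panel = g$panel, mask = g$mask,
                      sample_id = "o1")
  truth <- dplyr::bind_rows(trio$callsets$o1, dn[names(trio$callsets$o1)])
  em <- caller_error_model() # zero errors
  samples <- list(
    o1 = simulate_caller_outputs(truth, em, g$reference, seed = 24, mask = g$mask),
    f1 = simulate_caller_outputs(trio$callsets$f1, em, g$reference, seed = 25, mask = g$mask),
    m1 = simulate_caller_outputs(trio$callsets$m1, em, g$reference, seed = 26, mask = g$mask)
  )
  res <- run_dna_cascade(samples, g$reference, panel = g$panel, mask = g$mask,
                         pedigree = ped)
  expect_setequal(key_of(res$calls$o1), key_of(dn))
  # audit: every stage only removes records
  expect_true(all(res$audit$n_out <= res$audit$n_in))
})

test_that("the RNA cascade applies hard filter, WT subtraction and DNA cross-filter", {
  rna <- make_calls(c("g1:10:C:T", "g1:20:C:T", "g2:5:A:G", "g2:7:G:A"),
                    sample_id = "muscle")
  rna$DP <- c(30L, 10L, 30L, 30L) # second record fails depth
  wt <- make_calls("g2:5:A:G", sample_id = "muscle")
  dna <- list(muscle = make_calls("g2:7:G:A", sample_id = "muscle"))
  res <- run_rna_cascade(list(muscle = rna), ref = NULL, wt = wt, dna = dna)
  expect_equal(key_of(res$calls$muscle), "g1:10:C:T")
  expect_equal(
    res$audit$stage,
    c("hard_filter", "subtract_wt", "subtract_dna")
  )
  expect_true(all(res$audit$n_out <= res$audit$n_in))
})
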