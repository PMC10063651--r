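# End-to-end orchestration: simulate -> cascade -> analyze -> report.

default_config_template <- function() {
  list(
    seed = NULL, # required, no default
    outdir = "offbase_run",
    simulate = list(
      n_contigs = 4L,
      contig_length = 250000L,
      gc_fraction = 0.42,
      mask_fraction = 0.05,
      n_known_sites = 2000L,
      het_rate = 0.5,
      mean_depth = 36,
      caller_fn = c(0.02, 0.02, 0.02),
      caller_fp = 1e-7,
      groups = list(
        list(name = "BE3", preset = "BE3", n_trios = 2L, n_de_novo = 150L),
        list(name = "GFP", preset = "background", n_trios = 2L, n_de_novo = 30L)
      ),
      rna = list(
        tissues = list(muscle = 60, heart = 40, liver = 20, kidney = 15,
                       spleen = 10, lung = 8, brain = 5, testis = 3),
        n_genes = 150L,
        gene_length = 1000L,
        rate_coefficient = 2e-4,
        wt_editor_fpkm = 1,
        preset = "BE3"
      ),
      amplicon = list(
        length = 120L,
        protospacer_start = 50L,
        conversion = c("A", "G"),
        positions = c(3L, 4L, 6L),
        rates = c(0.06, 0.08, 0.105),
        n_reads = 5000L,
        error_rate = 0.001
      )
    ),
    analyze = list(
      phenotype = list(
        wt_mean = 34.4,
        wt_sem = 4.7,
        weights = list(BE3_a = 60.3, BE3_b = 49.1, BE3_c = 45.6, BE3_d = 34.3,
                       GFP_a = 34.4, GFP_b = 36.2)
      ),
      integration = list(BE3_a = c("single", "single", "biallelic", "single"),
                         GFP_a = c("single", "biallelic", "single"))
    ),
    report = list(digits = 6L)
  )
}

# Keys whose children are free-form maps (validated by value, not by name).
FREE_MAP_PATHS <- c("simulate.rna.tissues", "analyze.phenotype.weights",
                    "analyze.integration")

merge_config <- function(defaults, user, path = character(0)) {
  if (!is.list(user)) return(user)
  here <- paste(path, collapse = ".")
  if (here %in% FREE_MAP_PATHS || here == "simulate.groups") {
    return(user)
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key '%s'",
                  paste(c(path, unknown[1]), collapse = ".")))
  }
  out <- defaults
  for (k in names(user)) {
    out[[k]] <- if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      merge_config(defaults[[k]], user[[k]], c(path, k))
    } else {
      user[[k]]
    }
  }
  out
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults, rejects unknown keys, checks types and ranges, and
#' requires an explicit integer seed. The normalized configuration is echoed
#' into the run manifest by [run_pipeline()].
#'
#' @param config Path to a YAML config file, or an equivalent nested list.
#' @return Normalized config list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a YAML mapping or a list")
  cfg <- merge_config(default_config_template(), config)
  if (is.null(cfg$seed)) abort("config missing required key 'seed'")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 ||
      cfg$seed != round(cfg$seed)) {
    abort("'seed' must be a single integer")
  }
  cfg$seed <- as.integer(cfg$seed)
  sim <- cfg$simulate
  if (sim$contig_length < 1000) abort("simulate.contig_length must be >= 1000")
  if (sim$n_contigs < 1) abort("simulate.n_contigs must be >= 1")
  if (sim$gc_fraction < 0 || sim$gc_fraction >= 1) {
    abort("simulate.gc_fraction must be in [0, 1)")
  }
  if (sim$mask_fraction < 0 || sim$mask_fraction >= 1) {
    abort("simulate.mask_fraction must be in [0, 1)")
  }
  if (length(sim$caller_fn) != 3 || any(sim$caller_fn < 0 | sim$caller_fn >= 1)) {
    abort("simulate.caller_fn must be three values in [0, 1)")
  }
  if (any(sim$caller_fp < 0)) abort("simulate.caller_fp must be >= 0")
  if (sim$het_rate <= 0 || sim$het_rate > 1) abort("simulate.het_rate must be in (0, 1]")
  for (g in sim$groups) {
    known <- c("name", "preset", "n_trios", "n_de_novo")
    unknown <- setdiff(names(g), known)
    if (length(unknown) > 0) {
      abort(sprintf("unknown config key 'simulate.groups.%s'", unknown[1]))
    }
    if (is.null(g$name) || is.null(g$preset)) {
      abort("each simulate.groups entry needs 'name' and 'preset'")
    }
    if ((g$n_trios %||% 1) < 1) abort("simulate.groups.n_trios must be >= 1")
    if ((g$n_de_novo %||% 0) < 0) abort("simulate.groups.n_de_novo must be >= 0")
  }
  if (sim$rna$rate_coefficient < 0) {
    abort("simulate.rna.rate_coefficient must be >= 0")
  }
  amp <- sim$amplicon
  if (any(amp$rates < 0 | amp$rates > 1) || amp$error_rate < 0 ||
      amp$error_rate > 1) {
    abort("simulate.amplicon rates must be in [0, 1]")
  }
  ph <- cfg$analyze$phenotype
  if (ph$wt_sem < 0) abort("analyze.phenotype.wt_sem must be >= 0")
  if (length(ph$weights) > 0 && any(unlist(ph$weights) <= 0)) {
    abort("analyze.phenotype.weights must be > 0")
  }
  cfg
}

round_numerics <- function(df, digits) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

write_report_table <- function(df, path, hash, seed, digits = 6) {
  df <- round_numerics(as_tibble(df), digits)
  writeLines(sprintf("# offbase config_hash=%s seed=%d", hash, seed), path)
  suppressMessages(write_tsv(df, path, append = TRUE, col_names = TRUE))
  invisible(path)
}

# Toy CDS-only gene models at fixed offsets on the simulated genome.
toy_gene_models <- function(ref) {
  ctgs <- names(ref)
  len <- nchar(ref[[1]])
  anchors <- pmin(c(0.1, 0.4, 0.7) * len, len - 400)
  gm <- list_rbind(imap(setNames(anchors, c("geneA", "geneB", "geneC")),
    function(a, g) {
      tibble(gene_id = g, contig = ctgs[1],
             strand = if (g == "geneB") "-" else "+",
             start = as.integer(a), end = as.integer(a + 300))
    }))
  if (length(ctgs) > 1) {
    gm <- bind_rows(gm, tibble(gene_id = "geneD", contig = ctgs[2],
                               strand = "-", start = 5000L, end = 5300L))
  }
  validate_gene_models(gm)
  gm
}

#' Run the full simulate-cascade-analyze-report pipeline
#'
#' Executes the whole study design at desk scale from one configuration:
#' simulates the reference, trios, editor-signature de novo events, caller
#' outputs, expression-scaled RNA SNVs and amplicon reads; runs the DNA and
#' RNA cascades with per-stage audit tables; and writes every result table
#' (SNV counts, spectra, PWM/WCW motif statistics, shared-ratio matrix,
#' expression regression and deciles, coding consequences, phenotype
#' classification, copy numbers, editing efficiency) plus per-sample VCFs
#' and a machine-readable run manifest. Identical configurations produce
#' byte-identical output directories.
#'
#' @param config Path to a YAML config or a config list (see
#'   [validate_config()]).
#' @param outdir Output directory (overrides the config's `outdir`).
#' @param seed Optional seed override.
#' @return The output directory path, invisibly.
#' @export
run_pipeline <- function(config, outdir = NULL, seed = NULL) {
  cfg <- validate_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  outdir <- outdir %||% cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (sub in c("dna", "rna", "tables")) {
    dir.create(file.path(outdir, sub), showWarnings = FALSE)
  }
  hash <- rlang::hash(cfg)
  s <- cfg$seed
  digits <- cfg$report$digits
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      writeLines(sprintf("stage=%s\nerror=%s", name, conditionMessage(e)),
                 file.path(outdir, "FAILED"))
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  sim <- cfg$simulate

  genome <- stage("simulate_reference", {
    generate_reference(
      n_contigs = sim$n_contigs, contig_length = sim$contig_length,
      gc_fraction = sim$gc_fraction, mask_fraction = sim$mask_fraction,
      n_known_sites = sim$n_known_sites, seed = s + 11L
    )
  })
  write_fasta(genome$reference, file.path(outdir, "reference.fa"))
  write_bed(genome$mask, file.path(outdir, "mask.bed"))

  error_model <- caller_error_model(fn = sim$caller_fn, fp = sim$caller_fp,
                                    mean_depth = sim$mean_depth)

  # --- DNA arm: trios, planted de novo events, caller outputs, cascade ----
  dna <- stage("simulate_dna", {
    all_samples <- list(); groups_vec <- character(0)
    pedigrees <- list(); truth <- list()
    idx <- 0L
    for (g in sim$groups) {
      ped <- tibble(
        offspring_id = paste0(g$name, "_o", seq_len(g$n_trios)),
        father_id = paste0(g$name, "_f", seq_len(g$n_trios)),
        mother_id = paste0(g$name, "_m", seq_len(g$n_trios))
      )
      trio <- simulate_trio_germline(genome$reference, genome$panel, ped,
                                     het_rate = sim$het_rate,
                                     seed = s + 100L + idx)
      signature <- signature_preset(g$preset)
      for (sid in names(trio$callsets)) {
        idx <- idx + 1L
        truth_calls <- trio$callsets[[sid]]
        if (sid %in% ped$offspring_id && g$n_de_novo > 0) {
          dn <- plant_de_novo(genome$reference, signature, g$n_de_novo,
                              seed = s + 200L + idx, panel = genome$panel,
                              mask = genome$mask, sample_id = sid)
          truth[[sid]] <- dn
          truth_calls <- bind_rows(truth_calls, dn[names(truth_calls)])
        }
        all_samples[[sid]] <- simulate_caller_outputs(
          truth_calls, error_model, genome$reference,
          seed = s + 300L + idx, mask = genome$mask
        )
        groups_vec[sid] <- g$name
      }
      pedigrees[[g$name]] <- ped
    }
    wt_truth <- simulate_trio_germline(
      genome$reference, genome$panel,
      tibble(offspring_id = "WT_o", father_id = "WT_f", mother_id = "WT_m"),
      het_rate = sim$het_rate, seed = s + 99L
    )
    wt_callers <- simulate_caller_outputs(wt_truth$callsets$WT_o, error_model,
                                          genome$reference, seed = s + 399L,
                                          mask = genome$mask)
    list(samples = all_samples, groups = groups_vec,
         pedigree = list_rbind(pedigrees), truth = truth, wt = wt_callers)
  })

  for (sid in names(dna$samples)) {
    for (k in 1:3) {
      write_vcf(dna$samples[[sid]][[k]],
                file.path(outdir, "dna", sprintf("%s.caller%d.vcf", sid, k)))
    }
  }

  dna_res <- stage("dna_cascade", {
    run_dna_cascade(dna$samples, genome$reference, wt = dna$wt,
                    panel = genome$panel, mask = genome$mask,
                    groups = dna$groups, pedigree = dna$pedigree)
  })
  for (sid in names(dna_res$calls)) {
    write_vcf(dna_res$calls[[sid]],
              file.path(outdir, "dna", sprintf("%s.final.vcf", sid)))
  }
  write_report_table(dna_res$audit, file.path(outdir, "tables", "dna_audit.tsv"),
                     hash, s, digits)
  truth_tbl <- list_rbind(unname(dna$truth))
  write_report_table(truth_tbl,
                     file.path(outdir, "tables", "truth_de_novo.tsv"),
                     hash, s, digits)

  offspring_ids <- dna$pedigree$offspring_id
  dna_counts <- tibble(
    sample_id = offspring_ids,
    group = unname(dna$groups[offspring_ids]),
    n_snv = map_int(dna_res$calls[offspring_ids], function(cs) {
      sum(nchar(cs$ref) == 1 & nchar(cs$alt) == 1)
    }),
    n_indel = map_int(dna_res$calls[offspring_ids], function(cs) {
      sum(nchar(cs$ref) != 1 | nchar(cs$alt) != 1)
    })
  )
  write_report_table(dna_counts,
                     file.path(outdir, "tables", "dna_snv_counts.tsv"),
                     hash, s, digits)

  stage("dna_signature", {
    for (g in sim$groups) {
      members <- offspring_ids[dna$groups[offspring_ids] == g$name]
      pooled <- list_rbind(unname(dna_res$calls[members]))
      spec <- spectrum_table(pooled)
      write_report_table(
        spec, file.path(outdir, "tables", sprintf("dna_spectrum_%s.tsv", g$name)),
        hash, s, digits
      )
      snvs <- pooled[nchar(pooled$ref) == 1 & nchar(pooled$alt) == 1, ]
      if (nrow(snvs) < 10) next
      ctx <- extract_context(snvs, genome$reference)
      oriented <- orient_pyrimidine(
        classify_substitution(snvs$ref, snvs$alt), ctx
      )
      pwm <- build_pwm(oriented$context)
      write_report_table(
        tidy(pwm),
        file.path(outdir, "tables", sprintf("dna_pwm_%s.tsv", g$name)),
        hash, s, digits
      )
      c_centered <- oriented$context[substr(oriented$context, 2, 2) == "C"]
      if (length(c_centered) > 0) {
        write_report_table(
          wcw_statistics(c_centered, genome$reference, genome$mask),
          file.path(outdir, "tables", sprintf("dna_wcw_%s.tsv", g$name)),
          hash, s, digits
        )
      }
    }
  })

  # --- RNA arm: expression-scaled SNVs, cascade, association statistics ---
  rna <- stage("simulate_rna", {
    rs <- sim$rna
    seed_rng(s + 400L)
    base_fpkm <- round(exp(rnorm(rs$n_genes, 2, 1.2)), 3)
    genes <- sprintf("gene%03d", seq_len(rs$n_genes))
    expression <- tidyr::expand_grid(gene_id = genes,
                                     tissue = names(rs$tissues)) |>
      mutate(fpkm = rep(base_fpkm, each = length(rs$tissues)))
    editor <- unlist(rs$tissues)
    calls <- simulate_rna_snvs(expression, editor, signature_preset(rs$preset),
                               rs$rate_coefficient, seed = s + 410L,
                               gene_length = rs$gene_length,
                               error_model = error_model)
    wt_calls <- simulate_rna_snvs(
      expression, setNames(rep(rs$wt_editor_fpkm, length(editor)), names(editor)),
      signature_preset("background"), rs$rate_coefficient, seed = s + 420L,
      gene_length = rs$gene_length, error_model = error_model
    )
    list(expression = expression, editor = editor, calls = calls, wt = wt_calls)
  })
  write_report_table(rna$expression, file.path(outdir, "tables", "expression.tsv"),
                     hash, s, digits)

  rna_res <- stage("rna_cascade", {
    run_rna_cascade(rna$calls, ref = NULL, wt = rna$wt)
  })
  for (t in names(rna_res$calls)) {
    write_vcf(rna_res$calls[[t]], file.path(outdir, "rna", sprintf("%s.vcf", t)))
  }
  write_report_table(rna_res$audit, file.path(outdir, "tables", "rna_audit.tsv"),
                     hash, s, digits)

  stage("rna_analysis", {
    counts <- tibble(
      tissue = names(rna_res$calls),
      editor_fpkm = unname(rna$editor[names(rna_res$calls)]),
      snv_count = map_int(rna_res$calls, nrow)
    )
    write_report_table(counts, file.path(outdir, "tables", "rna_snv_counts.tsv"),
                       hash, s, digits)
    fit <- snv_expression_regression(counts)
    write_report_table(
      tibble(slope = fit$slope, intercept = fit$intercept,
             r_squared = fit$r_squared, n = fit$n, undefined = fit$undefined),
      file.path(outdir, "tables", "rna_regression.tsv"), hash, s, digits
    )
    muscle <- rna_res$calls[[which.max(rna$editor[names(rna_res$calls)])]]
    gene_fpkm <- rna$expression |>
      filter(.data$tissue == names(which.max(rna$editor))) |>
      select("gene_id", "fpkm")
    per_gene <- muscle |> count(gene_id = .data$contig, name = "n_snv")
    deciles <- expression_decile_counts(gene_fpkm, per_gene)
    write_report_table(deciles, file.path(outdir, "tables", "rna_deciles.tsv"),
                       hash, s, digits)
    shared <- shared_ratio_matrix(rna_res$calls)
    write_report_table(
      as_tibble(shared, rownames = "sample"),
      file.path(outdir, "tables", "rna_shared_ratio.tsv"), hash, s, digits
    )
    pooled <- list_rbind(unname(rna_res$calls))
    write_report_table(spectrum_table(pooled),
                       file.path(outdir, "tables", "rna_spectrum.tsv"),
                       hash, s, digits)
    if (nrow(pooled) >= 10 && "context" %in% names(pooled)) {
      oriented <- orient_pyrimidine(
        classify_substitution(pooled$ref, pooled$alt), pooled$context
      )
      write_report_table(tidy(build_pwm(oriented$context)),
                         file.path(outdir, "tables", "rna_pwm.tsv"),
                         hash, s, digits)
      c_centered <- oriented$context[substr(oriented$context, 2, 2) == "C"]
      if (length(c_centered) > 0) {
        write_report_table(
          wcw_statistics(c_centered, genome$reference, genome$mask),
          file.path(outdir, "tables", "rna_wcw.tsv"), hash, s, digits
        )
      }
    }
  })

  # --- consequence, phenotype, copy-number and amplicon summaries ---------
  stage("consequence", {
    gm <- toy_gene_models(genome$reference)
    pooled <- list_rbind(unname(dna_res$calls[offspring_ids]))
    snvs <- pooled[nchar(pooled$ref) == 1 & nchar(pooled$alt) == 1, ]
    cons <- annotate_consequence(snvs, gm, genome$reference)
    write_report_table(count(cons, .data$consequence),
                       file.path(outdir, "tables", "consequence_summary.tsv"),
                       hash, s, digits)
    write_report_table(filter(cons, .data$consequence != "noncoding"),
                       file.path(outdir, "tables", "consequence_hits.tsv"),
                       hash, s, digits)
  })

  stage("phenotype", {
    ph <- cfg$analyze$phenotype
    thr <- phenotype_thresholds(ph$wt_mean, ph$wt_sem)
    w <- unlist(ph$weights)
    tab <- tibble(
      sample_id = names(w), weight_g = unname(w),
      upper_g = thr$upper, lower_g = thr$lower,
      phenotype = classify_phenotype(unname(w), thr)
    )
    write_report_table(tab, file.path(outdir, "tables", "phenotype.tsv"),
                       hash, s, digits)
    cn <- tibble(
      sample_id = names(cfg$analyze$integration),
      copy_number = map_int(cfg$analyze$integration, copy_number)
    )
    write_report_table(cn, file.path(outdir, "tables", "copy_number.tsv"),
                       hash, s, digits)
  })

  stage("amplicon", {
    amp <- sim$amplicon
    seed_rng(s + 500L)
    # amplicon sequence with the conversion source planted at the requested
    # protospacer positions
    seq <- sample(DNA_BASES, amp$length, replace = TRUE)
    targets <- amp$protospacer_start + amp$positions
    seq[targets] <- amp$conversion[1]
    amplicon <- paste(seq, collapse = "")
    reads <- simulate_amplicon_reads(amplicon, targets, amp$conversion,
                                     amp$rates, amp$n_reads,
                                     error_rate = amp$error_rate,
                                     seed = s + 510L)
    site <- target_site(amplicon, amp$protospacer_start,
                        conversion = amp$conversion,
                        positions_of_interest = amp$positions)
    bc <- count_bases(reads, site)
    eff <- editing_efficiency(bc, site)
    write_report_table(eff,
                       file.path(outdir, "tables", "amplicon_efficiency.tsv"),
                       hash, s, digits)
  })

  manifest <- list(
    config_hash = hash,
    seed = s,
    package = "offbase",
    package_version = as.character(packageVersion("offbase")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = cfg
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
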