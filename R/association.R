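#' Shared-SNV ratio matrix
#'
#' Cell (i, j) is the number of variant keys shared between samples i and j
#' divided by the number of variants in sample i (the row sample), so the
#' matrix is row-normalized and not symmetric in general; the diagonal is 1.
#' Rows for empty samples are flagged `NaN`.
#'
#' @param callsets Named list (>= 2) of call-set tibbles.
#' @return Square numeric matrix in input sample order.
#' @export
shared_ratio_matrix <- function(callsets) {
  if (!is.list(callsets) || length(callsets) < 2) {
    abort("`callsets` must be a named list of at least 2 call sets")
  }
  keys <- map(callsets, function(cs) unique(variant_key(cs)))
  n <- length(keys)
  m <- matrix(NA_real_, n, n, dimnames = list(names(callsets), names(callsets)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- length(intersect(keys[[i]], keys[[j]])) / length(keys[[i]])
    }
  }
  m
}

#' Fraction of variants shared with other samples of a group
#'
#' For each sample, the fraction of its variant keys present in at least one
#' other sample of the group ("shared by more than one sample"), plus the
#' group mean.
#'
#' @param callsets Named list (>= 2) of call-set tibbles.
#' @return List with `per_sample` (named numeric) and `mean`.
#' @export
shared_fraction <- function(callsets) {
  if (!is.list(callsets) || length(callsets) < 2) {
    abort("`callsets` must be a named list of at least 2 call sets")
  }
  keys <- map(callsets, function(cs) unique(variant_key(cs)))
  per_sample <- map_dbl(seq_along(keys), function(i) {
    others <- unique(unlist(keys[-i], use.names = FALSE))
    if (length(keys[[i]]) == 0) return(NaN)
    mean(keys[[i]] %in% others)
  })
  names(per_sample) <- names(callsets)
  list(per_sample = per_sample, mean = mean(per_sample, na.rm = TRUE))
}

#' Ordinary least-squares fit of SNV count on editor expression
#'
#' Fits `snv_count ~ editor_fpkm` by closed-form normal equations and
#' reports slope, intercept and the coefficient of determination — the
#' association between per-tissue RNA SNV load and editor expression. A
#' zero-variance predictor yields a flagged undefined fit.
#'
#' @param data Data frame with columns `editor_fpkm` and `snv_count` (one
#'   row per tissue or sample; n >= 3).
#' @return An `snv_assoc` object with [tidy()], [glance()] and `autoplot()`
#'   methods.
#' @export
snv_expression_regression <- function(data) {
  if (!all(c("editor_fpkm", "snv_count") %in% names(data))) {
    abort("`data` needs columns `editor_fpkm` and `snv_count`")
  }
  x <- as.numeric(data$editor_fpkm)
  y <- as.numeric(data$snv_count)
  n <- length(x)
  if (n < 3) abort("at least 3 points are required")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) {
    fit <- list(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
                n = n, undefined = TRUE, data = tibble(editor_fpkm = x, snv_count = y))
    return(structure(fit, class = "snv_assoc"))
  }
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - sum((y - fitted)^2) / sst
  structure(
    list(slope = slope, intercept = intercept, r_squared = r2, n = n,
         undefined = FALSE, data = tibble(editor_fpkm = x, snv_count = y)),
    class = "snv_assoc"
  )
}

#' @export
print.snv_assoc <- function(x, ...) {
  if (x$undefined) {
    cat("SNV-expression fit: undefined (zero predictor variance), n =", x$n, "\n")
  } else {
    cat(sprintf("SNV-expression fit: slope %.4g, intercept %.4g, R^2 %.3f, n %d\n",
                x$slope, x$intercept, x$r_squared, x$n))
  }
  invisible(x)
}

#' @describeIn snv_expression_regression Coefficient table.
#' @param x An `snv_assoc` fit.
#' @param ... Unused.
#' @method tidy snv_assoc
#' @export
tidy.snv_assoc <- function(x, ...) {
  tibble(term = c("(Intercept)", "editor_fpkm"),
         estimate = c(x$intercept, x$slope))
}

#' @describeIn snv_expression_regression One-row model summary.
#' @method glance snv_assoc
#' @export
glance.snv_assoc <- function(x, ...) {
  tibble(r.squared = x$r_squared, n = x$n, undefined = x$undefined)
}

#' @describeIn snv_expression_regression Scatter plot with the fitted line.
#' @param object An `snv_assoc` fit.
#' @method autoplot snv_assoc
#' @export
autoplot.snv_assoc <- function(object, ...) {
  p <- ggplot(object$data, aes(x = .data$editor_fpkm, y = .data$snv_count)) +
    geom_point() +
    labs(x = "Editor expression (FPKM)", y = "RNA SNV count")
  if (!object$undefined) {
    p <- p + geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = 2)
  }
  p
}

#' Expression-decile SNV counts
#'
#' Sorts genes by FPKM ascending (ties broken by gene id, stable), splits
#' them into `n_bins` near-equal sets (any remainder spread one gene each to
#' the top bins) and totals SNVs per bin — the "more expression, more RNA
#' SNVs" summary.
#'
#' @param gene_fpkm Tibble `gene_id`, `fpkm` (one tissue).
#' @param per_gene_snv_counts Tibble `gene_id`, `n_snv`; genes absent here
#'   count 0.
#' @param n_bins Number of expression bins (default 10).
#' @return Tibble per bin: `bin`, `n_genes`, `fpkm_min`, `fpkm_max`,
#'   `total_snvs`, `mean_snvs`.
#' @export
expression_decile_counts <- function(gene_fpkm, per_gene_snv_counts,
                                     n_bins = 10) {
  if (nrow(gene_fpkm) < n_bins) {
    abort(sprintf("at least %d genes are required for %d bins", n_bins, n_bins))
  }
  if (anyDuplicated(gene_fpkm$gene_id)) abort("duplicate gene_id in `gene_fpkm`")
  df <- gene_fpkm |>
    left_join(per_gene_snv_counts, by = "gene_id") |>
    mutate(n_snv = replace_na(.data$n_snv, 0L)) |>
    arrange(.data$fpkm, .data$gene_id)
  g <- nrow(df)
  base <- g %/% n_bins
  rem <- g %% n_bins
  sizes <- rep(base, n_bins)
  if (rem > 0) sizes[(n_bins - rem + 1):n_bins] <- base + 1L
  df$bin <- rep(seq_len(n_bins), times = sizes)
  df |>
    group_by(.data$bin) |>
    summarise(
      n_genes = n(),
      fpkm_min = min(.data$fpkm), fpkm_max = max(.data$fpkm),
      total_snvs = sum(.data$n_snv), mean_snvs = mean(.data$n_snv),
      .groups = "drop"
    )
}

#' Body-weight phenotype thresholds
#'
#' Upper and lower cutoffs at the control-group mean plus/minus three
#' standard errors: obesity above `mean + 3 SEM`, developmental delay below
#' `mean - 3 SEM`.
#'
#' @param wt_mean Control (WT/GFP) group mean body weight in grams.
#' @param wt_sem Standard error of that mean, in grams (>= 0).
#' @return List with `wt_mean`, `wt_sem`, `upper`, `lower`.
#' @export
phenotype_thresholds <- function(wt_mean, wt_sem) {
  if (wt_sem < 0) abort("`wt_sem` must be >= 0")
  list(wt_mean = wt_mean, wt_sem = wt_sem,
       upper = wt_mean + 3 * wt_sem, lower = wt_mean - 3 * wt_sem)
}

#' Classify body-weight phenotypes
#'
#' `obese` iff weight strictly exceeds the upper threshold,
#' `developmental_delay` iff strictly below the lower threshold, otherwise
#' `normal` (weights exactly at a threshold are normal).
#'
#' @param weight Body weight(s) in grams (> 0).
#' @param thresholds A [phenotype_thresholds()] list.
#' @return Character vector of classifications.
#' @export
classify_phenotype <- function(weight, thresholds) {
  if (any(weight <= 0)) abort("`weight` must be > 0")
  dplyr::case_when(
    weight > thresholds$upper ~ "obese",
    weight < thresholds$lower ~ "developmental_delay",
    .default = "normal"
  )
}

#' Transgene copy number from integration-site zygosity
#'
#' Sums one copy per single-allele integration site and two per biallelic
#' site.
#'
#' @param integration_sites Character vector with values `"single"` or
#'   `"biallelic"`.
#' @return Integer copy number.
#' @export
copy_number <- function(integration_sites) {
  if (length(integration_sites) == 0) return(0L)
  bad <- setdiff(unique(integration_sites), c("single", "biallelic"))
  if (length(bad) > 0) abort(sprintf("unknown zygosity label '%s'", bad[1]))
  sum(ifelse(integration_sites == "biallelic", 2L, 1L))
}
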