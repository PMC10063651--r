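# ggplot2 views of the main result types. Rendering is isolated from
# computation: every plot function consumes an already-computed table.

#' Bar chart of a 12-type mutation spectrum
#' @param spectrum Output of [spectrum_table()].
#' @param percentage Plot percentages (default) or raw counts.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum, percentage = TRUE) {
  yvar <- if (percentage) "percentage" else "count"
  ggplot(spectrum, aes(x = factor(.data$type, levels = SUB_TYPES),
                       y = .data[[yvar]])) +
    geom_col(fill = "grey30") +
    labs(x = "Substitution type",
         y = if (percentage) "Percentage of SNVs" else "SNV count") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Sequence-logo style view of a context PWM
#'
#' Letters at each position scaled by `IC * frequency` (bits), the standard
#' information-content logo layout.
#'
#' @param object A `context_pwm` from [build_pwm()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot context_pwm
#' @export
autoplot.context_pwm <- function(object, ...) {
  df <- tidy(object) |>
    mutate(height = .data$freq * .data$ic) |>
    filter(.data$height > 0) |>
    arrange(.data$position, .data$height) |>
    group_by(.data$position) |>
    mutate(ymax = cumsum(.data$height), ymin = .data$ymax - .data$height) |>
    ungroup()
  ggplot(df) +
    geom_rect(aes(xmin = .data$position - 0.45, xmax = .data$position + 0.45,
                  ymin = .data$ymin, ymax = .data$ymax, fill = .data$base),
              alpha = 0.25) +
    geom_text(aes(x = .data$position, y = (.data$ymin + .data$ymax) / 2,
                  label = .data$base, size = .data$height, colour = .data$base),
              fontface = "bold", show.legend = FALSE) +
    scale_size_continuous(range = c(2, 10)) +
    scale_x_continuous(breaks = seq_len(object$L)) +
    labs(x = "Position", y = "Information content (bits)") +
    guides(fill = "none") +
    theme_minimal()
}

#' Heatmap of a shared-SNV ratio matrix
#' @param m Matrix from [shared_ratio_matrix()].
#' @return A ggplot object.
#' @export
plot_shared_ratio <- function(m) {
  df <- as_tibble(m, rownames = "row_sample") |>
    pivot_longer(-"row_sample", names_to = "col_sample", values_to = "ratio") |>
    mutate(row_sample = factor(.data$row_sample, levels = rev(rownames(m))),
           col_sample = factor(.data$col_sample, levels = colnames(m)))
  ggplot(df, aes(x = .data$col_sample, y = .data$row_sample,
                 fill = .data$ratio)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", .data$ratio)), size = 3) +
    scale_fill_gradient(low = "white", high = "firebrick", limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "Shared ratio") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Bar chart of expression-decile SNV totals
#' @param deciles Output of [expression_decile_counts()].
#' @return A ggplot object.
#' @export
plot_decile_counts <- function(deciles) {
  ggplot(deciles, aes(x = factor(.data$bin), y = .data$mean_snvs)) +
    geom_col(fill = "steelblue") +
    labs(x = "Expression decile (low to high FPKM)",
         y = "Mean RNA SNVs per gene") +
    theme_minimal()
}
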